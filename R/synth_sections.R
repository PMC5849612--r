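#' Specify a synthetic bone cross section with analytic ground truth
#'
#' Describes a disc, annulus, or elliptical ring to be rasterized by
#' [make_section()]. All closed-form section properties follow from the
#' parameters, so generated rasters serve as oracles for the geometry
#' engine.
#'
#' @param shape `"disc"`, `"annulus"` or `"elliptical_ring"`. A disc is an
#'   ellipse with no lumen; an annulus a circular ring.
#' @param outer length-2 numeric, outer semi-axes `(a, b)` in pixels (for
#'   disc/annulus give equal values or a single number).
#' @param inner inner semi-axes in pixels, strictly inside `outer`;
#'   `NULL` for a disc.
#' @param rotation_deg counterclockwise rotation of the `a` semi-axis from
#'   +x, degrees.
#' @param pixel_size mm per pixel edge.
#' @param pores optional list `(count, radius, seed)`: circular vascular
#'   canals of radius `radius` px planted at deterministic, disjoint,
#'   interior positions in the cortex.
#' @param margin background border around the shape, px.
#' @return A list of class `section_spec`.
#' @export
section_spec <- function(shape = c("disc", "annulus", "elliptical_ring"),
                         outer, inner = NULL, rotation_deg = 0,
                         pixel_size = 1, pores = NULL, margin = 6) {
  shape <- match.arg(shape)
  if (length(outer) == 1L) outer <- c(outer, outer)
  stopifnot(length(outer) == 2L, all(outer > 0))
  if (shape == "disc") inner <- NULL
  if (shape != "disc") {
    if (is.null(inner)) stop("ring shapes need inner semi-axes")
    if (length(inner) == 1L) inner <- c(inner, inner)
    if (any(inner <= 0) || any(inner >= outer))
      stop("inner semi-axes must be strictly inside outer")
  }
  structure(list(shape = shape, outer = outer, inner = inner,
                 rotation_deg = rotation_deg, pixel_size = pixel_size,
                 pores = pores, margin = margin),
            class = "section_spec")
}

#' Rasterize a synthetic section and return its analytic truth
#'
#' Pixels are scored inside a shape iff their centre satisfies the implicit
#' ellipse inequality (no anti-aliasing), so discretization error is the
#' only gap between raster measurements and the closed forms. The truth
#' record is recomputed from the spec parameters on every call.
#'
#' @param spec a [section_spec()].
#' @param element,specimen_id passed to [section_mask()].
#' @return List with `mask` (a [section_mask()]), `gray` (numeric matrix:
#'   background 1.0, cortex 0.7, pore lumina 0.05; only when pores are
#'   planted does it differ from the mask), `truth` (closed-form `CA`, `TA`,
#'   `Ixx`, `Iyy`, `Ixy`, `Imax`, `Imin`, `J`, `theta_deg`, `ca_ta`,
#'   `ellipticity` in physical units), `n_pixels` (cortical pixel count of
#'   the raster, before pore punching), `pore_centres`.
#' @export
make_section <- function(spec, element = "humerus", specimen_id = "synthetic") {
  stopifnot(inherits(spec, "section_spec"))
  a <- spec$outer[1]; b <- spec$outer[2]
  phi <- spec$rotation_deg * pi / 180
  half <- max(a, b) + spec$margin
  n <- 2L * as.integer(ceiling(half)) + 1L
  ctr <- (n + 1) / 2
  xg <- matrix(seq_len(n) - ctr, n, n)        # x along rows
  yg <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
  xr <- cos(phi) * xg + sin(phi) * yg
  yr <- -sin(phi) * xg + cos(phi) * yg
  inside <- (xr / a)^2 + (yr / b)^2 <= 1
  if (!is.null(spec$inner)) {
    ai <- spec$inner[1]; bi <- spec$inner[2]
    inside <- inside & ((xr / ai)^2 + (yr / bi)^2 > 1)
  }
  n_pixels <- sum(inside)

  pore_centres <- NULL
  px <- inside
  gray <- matrix(1, n, n)
  gray[inside] <- 0.7
  if (!is.null(spec$pores) && spec$pores$count > 0) {
    pc <- plant_pores(spec, n, ctr)
    pore_centres <- pc
    r <- spec$pores$radius
    for (k in seq_len(nrow(pc))) {
      d2 <- (xg - pc[k, 1])^2 + (yg - pc[k, 2])^2
      lumen <- d2 <= r^2
      px[lumen] <- FALSE
      gray[lumen & inside] <- 0.05
    }
  }

  list(mask = section_mask(px, spec$pixel_size, element = element,
                           specimen_id = specimen_id,
                           section_label = spec$shape),
       gray = gray,
       truth = section_truth(spec),
       n_pixels = n_pixels,
       pore_centres = pore_centres)
}

# Deterministic disjoint interior pore centres on the cortex mid-line.
plant_pores <- function(spec, n, ctr) {
  cnt <- spec$pores$count
  r <- spec$pores$radius
  a <- spec$outer[1]; b <- spec$outer[2]
  ai <- if (is.null(spec$inner)) 0 else spec$inner[1]
  bi <- if (is.null(spec$inner)) 0 else spec$inner[2]
  # equally spaced on the cortex mid-line with a seeded phase offset: disjoint
  # by construction whenever count * 2.5 * radius fits the mid-circumference
  mid <- mean(c((a + ai) / 2, (b + bi) / 2))
  if (cnt * 2.5 * r > 2 * pi * mid)
    stop("too many pores to place disjointly on the cortex mid-line")
  set.seed(spec$pores$seed %% .Machine$integer.max)
  ang <- 2 * pi * (seq_len(cnt) - 1) / cnt + runif(1, 0, 2 * pi / cnt)
  phi <- spec$rotation_deg * pi / 180
  mx <- (a + ai) / 2; my <- (b + bi) / 2
  x0 <- mx * cos(ang); y0 <- my * sin(ang)
  cbind(cos(phi) * x0 - sin(phi) * y0,
        sin(phi) * x0 + cos(phi) * y0)
}

# Closed-form properties of the specified shape, physical units.
section_truth <- function(spec) {
  ps <- spec$pixel_size
  a <- spec$outer[1]; b <- spec$outer[2]
  ai <- if (is.null(spec$inner)) 0 else spec$inner[1]
  bi <- if (is.null(spec$inner)) 0 else spec$inner[2]
  CA <- pi * (a * b - ai * bi) * ps^2
  TA <- pi * a * b * ps^2
  # unrotated frame: Ixx = integral x^2 dA = pi a^3 b / 4 (family)
  I10 <- pi * (a^3 * b - ai^3 * bi) / 4 * ps^4
  I20 <- pi * (a * b^3 - ai * bi^3) / 4 * ps^4
  phi <- spec$rotation_deg * pi / 180
  c2 <- cos(phi)^2; s2 <- sin(phi)^2; sc <- sin(phi) * cos(phi)
  Ixx <- I10 * c2 + I20 * s2
  Iyy <- I10 * s2 + I20 * c2
  Ixy <- (I10 - I20) * sc
  Imax <- max(I10, I20); Imin <- min(I10, I20)
  theta <- if (I10 == I20) 0 else {
    th <- spec$rotation_deg + if (I10 >= I20) 0 else 90
    th <- th %% 180
    if (th > 90) th <- th - 180
    th
  }
  list(CA = CA, TA = TA, Ixx = Ixx, Iyy = Iyy, Ixy = Ixy,
       Imax = Imax, Imin = Imin, J = Imax + Imin, theta_deg = theta,
       ca_ta = CA / TA, ellipticity = Imax / Imin)
}

#' Write a section raster to a PNG file
#'
#' Binary masks are written as 0/255 single-channel PNG; grey matrices in
#' `[0, 1]` verbatim.
#'
#' @param x logical matrix (mask) or numeric matrix in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_section_png <- function(x, path) {
  img <- if (is.logical(x)) matrix(as.numeric(x), nrow(x), ncol(x)) else x
  png::writePNG(img, path)
  invisible(path)
}
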