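#' Section masks: physically scaled binary rasters of bone cross sections
#'
#' A `section_mask` is the unit of the geometry stage: a 2-D logical grid in
#' which `TRUE` marks cortical bone, together with the physical pixel size
#' (mm per pixel edge) and specimen metadata. Masks are usually produced by
#' [load_section()] from a PNG/TIFF raster or by [make_section()] for
#' synthetic shapes with analytic ground truth.
#'
#' @param pixels logical matrix, `TRUE` = cortical bone.
#' @param pixel_size physical edge length of one pixel, in mm (> 0).
#' @param element skeletal element, `"humerus"` or `"ulna"`.
#' @param side `"left"`, `"right"` or `"unknown"`.
#' @param specimen_id free-text specimen identifier.
#' @param section_label free-text label for the individual section.
#' @return An object of class `section_mask`.
#' @export
section_mask <- function(pixels, pixel_size,
                         element = c("humerus", "ulna"),
                         side = c("unknown", "left", "right"),
                         specimen_id = "", section_label = "") {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  if (!is.logical(pixels)) storage.mode(pixels) <- "logical"
  if (any(is.na(pixels))) stop("'pixels' contains NA")
  if (length(pixels) == 0L) stop("empty section: grid has no pixels")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (mm)")
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         element = match.arg(element), side = match.arg(side),
         specimen_id = specimen_id, section_label = section_label),
    class = "section_mask")
}

#' @export
print.section_mask <- function(x, ...) {
  cat(sprintf("section_mask: %d x %d px, %.4g mm/px, %d cortical px (%s, %s)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              sum(x$pixels), x$element, x$side))
  invisible(x)
}

#' Load a bone cross-section raster as a section mask
#'
#' Reads a single-channel PNG or TIFF raster and binarises it. Binary masks
#' (only two grey levels present) are taken as-is with the brighter level as
#' bone; grayscale input is thresholded at the midpoint between its minimum
#' and maximum grey value unless an explicit `threshold` is given.
#'
#' @param path path to a PNG or TIFF file.
#' @param pixel_size mm per pixel edge.
#' @param threshold optional explicit grey threshold in `[0, 1]`; pixels
#'   strictly above it are scored as bone.
#' @param invert if `TRUE`, dark pixels are scored as bone.
#' @inheritParams section_mask
#' @return A [section_mask()].
#' @export
load_section <- function(path, pixel_size, threshold = NULL, invert = FALSE,
                         element = c("humerus", "ulna"),
                         side = c("unknown", "left", "right"),
                         specimen_id = basename(path), section_label = "") {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  img <- read_raster(path)
  if (isTRUE(invert)) img <- max(img) - img
  lv <- unique(as.vector(img))
  if (is.null(threshold)) {
    # midpoint rule covers both binary (0/255) and grayscale input; a
    # constant image is all-bone when bright, empty when black
    threshold <- if (length(lv) == 1L) lv / 2 else mean(range(img))
  }
  px <- img > threshold
  if (!any(px)) stop("empty section: no pixels above threshold in ", path)
  section_mask(px, pixel_size, element = element, side = side,
               specimen_id = specimen_id, section_label = section_label)
}

# Single-channel numeric matrix in [0,1] from a PNG or TIFF file; multi-channel
# input is collapsed by averaging the colour channels.
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE], c(1, 2), mean)
  img
}

#' Beam-theory properties of a bone cross section
#'
#' Computes all scalar geometric parameters used downstream: cortical area
#' CA, total subperiosteal area TA (cortex plus every enclosed void -
#' medullary cavity and intracortical canals), centroid, second moments of
#' area, principal moments, the polar moment J = Imax + Imin, relative
#' cortical thickness CA/TA, and section ellipticity Imax/Imin.
#'
#' Moments follow the solid-unit-square pixel convention: each cortical pixel
#' contributes as a filled square about its own centre, including its
#' px^4/12 self-moment. Axis indexing is chosen so that the reported
#' orientation follows the section's shape: `Ixx` is the second moment built
#' from x-deviations (`sum x^2 dA`), `Iyy` from y-deviations, `Ixy` the
#' product moment, where x runs along matrix rows and y along columns. With
#' this indexing the principal direction of `Imax` coincides with the
#' section's long axis and `theta_deg` is its counterclockwise angle from
#' +x in `(-90, 90]`.
#'
#' Sections whose Imax/Imin exceeds 1.50 are flagged (`ellipticity_flag`):
#' their J values are typically overestimated and should be read
#' proportionally, not quantitatively.
#'
#' @param mask a [section_mask()].
#' @param fill_canals fill enclosed voids before computing CA? Binary cortex
#'   profiles of fossil sections are solid cortex by construction; planted or
#'   imaged intracortical canals are closed so that CA measures the cortical
#'   compacta. Set `FALSE` to measure the mask verbatim.
#' @return A list of class `section_properties` with fields `CA`, `TA`
#'   (mm^2), `centroid` (mm), `Ixx`, `Iyy`, `Ixy`, `Imax`, `Imin`, `J`
#'   (mm^4), `theta_deg`, `ca_ta`, `ellipticity`, `ellipticity_flag`, and
#'   the mask metadata.
#' @export
compute_section_properties <- function(mask, fill_canals = TRUE) {
  stopifnot(inherits(mask, "section_mask"))
  px <- mask$pixels
  if (!any(px)) stop("empty section: no cortical pixels")
  if (sum(px) < 4L) stop("degenerate section: fewer than 4 cortical pixels")
  ncomp <- n_components(px)
  if (ncomp > 1L)
    warning(sprintf("cortex is not a single connected component (%d found)", ncomp))

  filled <- fill_holes(px)            # periosteal fill: cortex + enclosed voids
  cortex <- if (isTRUE(fill_canals)) fill_enclosed_canals(px, filled) else px

  ps <- mask$pixel_size
  idx <- which(cortex, arr.ind = TRUE)
  n <- nrow(idx)
  x <- idx[, 1] * ps                  # rows -> x
  y <- idx[, 2] * ps                  # cols -> y
  xc <- mean(x); yc <- mean(y)
  xm <- x - xc; ym <- y - yc
  self <- n * ps^4 / 12               # unit-square self-moment of each pixel
  Ixx <- sum(xm^2) * ps^2 + self
  Iyy <- sum(ym^2) * ps^2 + self
  Ixy <- sum(xm * ym) * ps^2
  pm <- principal_moments(Ixx, Iyy, Ixy)

  CA <- n * ps^2
  TA <- sum(filled) * ps^2
  out <- list(
    CA = CA, TA = TA, centroid = c(x = xc, y = yc),
    Ixx = Ixx, Iyy = Iyy, Ixy = Ixy,
    Imax = pm[["Imax"]], Imin = pm[["Imin"]], theta_deg = pm[["theta_deg"]],
    J = pm[["Imax"]] + pm[["Imin"]],
    ca_ta = CA / TA,
    ellipticity = pm[["Imax"]] / pm[["Imin"]],
    ellipticity_flag = pm[["Imax"]] / pm[["Imin"]] > 1.50,
    element = mask$element, side = mask$side,
    specimen_id = mask$specimen_id, section_label = mask$section_label)
  class(out) <- "section_properties"
  out
}

#' @export
print.section_properties <- function(x, ...) {
  cat(sprintf(paste0(
    "section_properties (%s %s %s)\n",
    "  CA %.4g mm^2   TA %.4g mm^2   CA/TA %.4f\n",
    "  Imax %.4g  Imin %.4g  J %.4g mm^4   theta %.1f deg\n",
    "  ellipticity %.3f%s\n"),
    x$specimen_id, x$element, x$side, x$CA, x$TA, x$ca_ta,
    x$Imax, x$Imin, x$J, x$theta_deg, x$ellipticity,
    if (x$ellipticity_flag) "  [flagged > 1.50: J overestimated]" else ""))
  invisible(x)
}

#' Principal second moments of area
#'
#' Eigendecomposition of the symmetric 2x2 moment tensor
#' `[[Ixx, Ixy], [Ixy, Iyy]]`. `Imax`/`Imin` quantify bending resistance
#' along the orthogonal major and minor principal axes; their sum is
#' invariant (`Imax + Imin = Ixx + Iyy`, the polar moment J).
#'
#' @param Ixx,Iyy diagonal moments, mm^4, non-negative.
#' @param Ixy product moment, mm^4.
#' @return Named numeric vector `(Imax, Imin, theta_deg)`; `theta_deg` is
#'   the counterclockwise angle of the `Imax` principal direction from +x,
#'   in `(-90, 90]`, with `theta = 0` by convention when `Imax == Imin`.
#' @export
principal_moments <- function(Ixx, Iyy, Ixy) {
  if (Ixx < 0 || Iyy < 0) stop("diagonal moments must be non-negative")
  avg <- (Ixx + Iyy) / 2
  half <- sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
  theta <- if (half == 0) 0 else atan2(2 * Ixy, Ixx - Iyy) / 2 * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  c(Imax = avg + half, Imin = avg - half, theta_deg = theta)
}

#' Mass-normalised torsional resistance J/M
#'
#' Normalises the polar moment over body mass so that torsional resistance
#' is comparable across taxa whose masses span several orders of magnitude.
#'
#' @param J polar moment of area, mm^4.
#' @param mass body mass, g (> 0).
#' @return J/M in mm^4 g^-1.
#' @export
mass_normalised_torsion <- function(J, mass) {
  if (any(mass <= 0)) stop("mass must be positive")
  J / mass
}

#' Combine repeated sections of one element
#'
#' Specimens measured on two circa mid-diaphyseal sections contribute the
#' arithmetic mean of each scalar property; singly sampled elements pass
#' through unchanged. Derived fields (`ca_ta`, `J`, `ellipticity`) are
#' recomputed from the averaged primitives for internal consistency.
#'
#' @param sections list of [compute_section_properties()] results for the
#'   same element of the same specimen.
#' @param policy `"mean"` (default) or `"single"` (requires exactly one
#'   section).
#' @return A `section_properties` object.
#' @export
aggregate_element <- function(sections, policy = c("mean", "single")) {
  policy <- match.arg(policy)
  if (length(sections) < 1L) stop("need at least one section")
  stopifnot(all(vapply(sections, inherits, logical(1), "section_properties")))
  el <- unique(vapply(sections, `[[`, character(1), "element"))
  if (length(el) != 1L) stop("cannot aggregate mixed elements: ",
                             paste(el, collapse = ", "))
  if (policy == "single") {
    if (length(sections) != 1L) stop("policy 'single' requires one section")
    return(sections[[1L]])
  }
  scalars <- c("CA", "TA", "Ixx", "Iyy", "Ixy", "Imax", "Imin", "theta_deg")
  out <- sections[[1L]]
  for (f in scalars)
    out[[f]] <- mean(vapply(sections, `[[`, numeric(1), f))
  out$centroid <- rowMeans(vapply(sections, `[[`, numeric(2), "centroid"))
  out$J <- out$Imax + out$Imin
  out$ca_ta <- out$CA / out$TA
  out$ellipticity <- out$Imax / out$Imin
  out$ellipticity_flag <- out$ellipticity > 1.50
  out$section_label <- paste(vapply(sections, `[[`, character(1),
                                    "section_label"), collapse = "+")
  out
}

#' Cortical vascular canal density
#'
#' Counts vascular canals as connected components of sub-threshold (dark)
#' pixels inside the cortical domain whose pixel area falls within a canal
#' size range, and expresses their density per mm^2 of cortical bone area.
#' Grey threshold and size gate are specimen-specific acquisition choices
#' and therefore mandatory explicit parameters.
#'
#' @param gray numeric matrix of grey values congruent with `cortex`.
#' @param cortex [section_mask()] delimiting the cortical domain.
#' @param threshold grey level; pixels strictly below count as canal lumen.
#' @param size_range length-2 numeric, inclusive `(min, max)` component area
#'   in pixels.
#' @return List of class `vascular_report`: `canal_count`, `cortical_area`
#'   (mm^2), `density` (canals mm^-2), `threshold_used`, `size_range`.
#' @export
vascular_density <- function(gray, cortex, threshold, size_range) {
  stopifnot(inherits(cortex, "section_mask"))
  if (!is.matrix(gray) || !all(dim(gray) == dim(cortex$pixels)))
    stop("'gray' must be a matrix congruent with the cortex mask")
  if (!any(cortex$pixels)) stop("no cortical pixels")
  if (length(size_range) != 2L || size_range[1] >= size_range[2])
    stop("size_range must be (min, max) with min < max")
  dark <- gray < threshold & cortex$pixels
  count <- 0L
  if (any(dark)) {
    lab <- EBImage::bwlabel(dark)
    sizes <- tabulate(as.integer(lab[lab > 0]))
    count <- sum(sizes >= size_range[1] & sizes <= size_range[2])
  }
  ca <- sum(cortex$pixels) * cortex$pixel_size^2
  structure(list(canal_count = count, cortical_area = ca,
                 density = count / ca, threshold_used = threshold,
                 size_range = size_range),
            class = "vascular_report")
}

#' Tabulate section properties
#'
#' One row per section, in the units of the geometry stage (mm, mm^2, mm^4,
#' degrees), suitable for writing with [utils::write.csv()].
#'
#' @param props list of `section_properties` objects.
#' @return A data.frame with columns specimen, element, side, CA, TA, Ixx,
#'   Iyy, Ixy, Imax, Imin, theta_deg, J, CA_TA, ellipticity,
#'   ellipticity_flag.
#' @export
section_table <- function(props) {
  if (inherits(props, "section_properties")) props <- list(props)
  do.call(rbind, lapply(props, function(p) data.frame(
    specimen = p$specimen_id, element = p$element, side = p$side,
    CA = p$CA, TA = p$TA, Ixx = p$Ixx, Iyy = p$Iyy, Ixy = p$Ixy,
    Imax = p$Imax, Imin = p$Imin, theta_deg = p$theta_deg, J = p$J,
    CA_TA = p$ca_ta, ellipticity = p$ellipticity,
    ellipticity_flag = p$ellipticity_flag,
    stringsAsFactors = FALSE)))
}

# ---- raster helpers ---------------------------------------------------------

# Periosteal fill: every pixel not reachable from the grid border through
# background is part of the section's total subperiosteal area.
fill_holes <- function(px) {
  f <- EBImage::fillHull(matrix(as.integer(px), nrow(px), ncol(px)))
  f > 0
}

# Close intracortical voids while keeping the medullary cavity open. Holes
# whose area is below `canal_frac` of the periosteal fill are scored as
# canals and filled into the compacta; larger voids are cavities.
fill_enclosed_canals <- function(px, filled = fill_holes(px),
                                 canal_frac = 0.05) {
  holes <- filled & !px
  if (!any(holes)) return(px)
  lab <- EBImage::bwlabel(holes)
  sizes <- tabulate(as.integer(lab[lab > 0]))
  canal_ids <- which(sizes < canal_frac * sum(filled))
  if (length(canal_ids) == 0L) return(px)
  px | matrix(lab %in% canal_ids, nrow(px), ncol(px))
}

n_components <- function(px) {
  if (!any(px)) return(0L)
  max(as.integer(EBImage::bwlabel(px)))
}
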