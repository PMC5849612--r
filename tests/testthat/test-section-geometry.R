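test_that("disc and annulus rasters reproduce closed-form beam properties", {
  # solid disc, R = 50 px, 1 mm pixels
  disc <- make_section(section_spec("disc", 50))
  p <- compute_section_properties(disc$mask)
  expect_equal(p$ca_ta, 1.0)
  expect_lt(abs(p$J - pi / 2 * 50^4) / (pi / 2 * 50^4), 0.01)
  expect_lt(abs(p$ellipticity - 1), 0.01)
  expect_false(p$ellipticity_flag)

  # annulus R = 50, r = 40
  ann <- make_section(section_spec("annulus", 50, 40))
  p <- compute_section_properties(ann$mask)
  expect_lt(abs(p$ca_ta - 0.36) / 0.36, 0.02)       # 1 - (r/R)^2
  J_true <- pi / 2 * (50^4 - 40^4)
  expect_lt(abs(p$J - J_true) / J_true, 0.01)
  expect_lt(abs(p$CA - ann$truth$CA) / ann$truth$CA, 0.01)
  expect_lt(abs(p$TA - ann$truth$TA) / ann$truth$TA, 0.01)
  expect_lt(abs(p$Imax / p$Imin - 1), 0.01)         # circular: Imax ~ Imin
})

test_that("elliptical ring recovers its planted orientation and moments", {
  spec <- section_spec("elliptical_ring", c(60, 35), c(45, 25),
                       rotation_deg = 30)
  s <- make_section(spec)
  p <- compute_section_properties(s$mask)
  expect_lt(abs(p$theta_deg - 30), 1)
  expect_lt(abs(p$Imax - s$truth$Imax) / s$truth$Imax, 0.01)
  expect_lt(abs(p$Imin - s$truth$Imin) / s$truth$Imin, 0.01)
  expect_true(p$ellipticity_flag)                   # strongly elliptic ring
})

test_that("J = Imax + Imin and the trace identity hold exactly", {
  for (spec in list(section_spec("disc", 31),
                    section_spec("annulus", 40, 28),
                    section_spec("elliptical_ring", c(50, 30), c(35, 20),
                                 rotation_deg = 72))) {
    p <- compute_section_properties(make_section(spec)$mask)
    expect_identical(p$J, p$Imax + p$Imin)
    expect_equal(p$Imax + p$Imin, p$Ixx + p$Iyy)
    expect_gte(p$ellipticity, 1)
    expect_true(p$CA <= p$TA)
  }
})

test_that("scalar properties are invariant under rotation and translation", {
  s <- make_section(section_spec("elliptical_ring", c(45, 28), c(32, 18)))
  p0 <- compute_section_properties(s$mask)
  # 90 degree rotation of the pixel grid
  rot <- section_mask(t(s$mask$pixels)[ncol(s$mask$pixels):1, ], 1)
  p90 <- compute_section_properties(rot)
  expect_equal(p90$CA, p0$CA)
  expect_equal(p90$TA, p0$TA)
  expect_equal(p90$J, p0$J, tolerance = 1e-10)
  expect_equal(p90$Imax, p0$Imax, tolerance = 1e-10)
  expect_equal((p90$theta_deg - p0$theta_deg) %% 180, 90, tolerance = 1e-6)
  # translation by grid padding
  pad <- rbind(matrix(FALSE, 7, ncol(s$mask$pixels) + 5),
               cbind(s$mask$pixels, matrix(FALSE, nrow(s$mask$pixels), 5)))
  pt <- compute_section_properties(section_mask(pad, 1))
  expect_equal(pt$J, p0$J)
  expect_equal(pt$CA, p0$CA)
  expect_equal(pt$theta_deg, p0$theta_deg)
})

test_that("discretization error decreases with raster resolution", {
  err <- sapply(c(25, 50, 100), function(R) {
    s <- make_section(section_spec("annulus", R, 0.8 * R))
    p <- compute_section_properties(s$mask)
    c(CA = abs(p$CA - s$truth$CA) / s$truth$CA,
      J = abs(p$J - s$truth$J) / s$truth$J)
  })
  expect_true(all(diff(err["CA", ]) < 0))
  expect_true(all(diff(err["J", ]) < 0))
  expect_true(all(err[, 2:3] < 0.01))               # within 1% from R = 50
})

test_that("CA/TA is scale-free while J scales with the fourth power of pixel size", {
  base <- make_section(section_spec("annulus", 40, 30, pixel_size = 1))$mask
  fine <- section_mask(base$pixels, 0.02)
  p1 <- compute_section_properties(base)
  p2 <- compute_section_properties(fine)
  expect_equal(p2$ca_ta, p1$ca_ta)
  expect_equal(p2$J, p1$J * 0.02^4)
  expect_equal(p2$CA, p1$CA * 0.02^2)
})

test_that("principal_moments matches the closed-form 2x2 eigendecomposition", {
  expect_equal(principal_moments(2, 1, 0),
               c(Imax = 2, Imin = 1, theta_deg = 0))
  pm <- principal_moments(1, 1, 0.5)
  expect_equal(unname(pm), c(1.5, 0.5, 45))
  # trace invariance over random inputs
  set.seed(8)
  for (i in 1:25) {
    Ixx <- runif(1, 0, 10); Iyy <- runif(1, 0, 10); Ixy <- rnorm(1)
    pm <- principal_moments(Ixx, Iyy, Ixy)
    expect_equal(pm[["Imax"]] + pm[["Imin"]], Ixx + Iyy)
    expect_gte(pm[["Imax"]], pm[["Imin"]])
    expect_true(pm[["theta_deg"]] > -90 && pm[["theta_deg"]] <= 90)
  }
  expect_error(principal_moments(-1, 1, 0), "non-negative")
})

test_that("rasters load from PNG with midpoint binarization", {
  tmp <- withr::local_tempdir()
  white <- file.path(tmp, "white.png")
  png::writePNG(matrix(1, 100, 100), white)
  m <- load_section(white, pixel_size = 0.01)
  expect_equal(sum(m$pixels), 10000L)
  expect_equal(m$pixel_size, 0.01)

  black <- file.path(tmp, "black.png")
  png::writePNG(matrix(0, 50, 50), black)
  expect_error(load_section(black, 0.01), "empty section")

  s <- make_section(section_spec("annulus", 30, 20))
  ann <- file.path(tmp, "annulus.png")
  write_section_png(s$mask$pixels, ann)
  m2 <- load_section(ann, 1)
  expect_equal(sum(m2$pixels), s$n_pixels)
  expect_error(load_section(file.path(tmp, "missing.png"), 1), "cannot read")
})

test_that("mass-normalised torsion is an exact, proportional quotient", {
  expect_equal(mass_normalised_torsion(100, 50), 2)
  expect_equal(mass_normalised_torsion(0, 10), 0)
  expect_equal(mass_normalised_torsion(7, 4),
               2 * mass_normalised_torsion(7, 8))
  expect_error(mass_normalised_torsion(10, 0), "positive")
})

test_that("element aggregation averages scalars and rebuilds derived fields", {
  s <- compute_section_properties(make_section(section_spec("annulus", 30, 20))$mask)
  expect_identical(aggregate_element(list(s, s))$J, s$J)       # idempotent
  expect_identical(aggregate_element(list(s), policy = "single"), s)
  s2 <- s; s2$Imax <- s$Imax * 3; s2$J <- s2$Imax + s2$Imin
  ag <- aggregate_element(list(s, s2))
  expect_equal(ag$Imax, (s$Imax + s2$Imax) / 2)
  expect_equal(ag$J, ag$Imax + ag$Imin)
  expect_equal(ag$ca_ta, ag$CA / ag$TA)
  s3 <- s; s3$element <- "ulna"
  expect_error(aggregate_element(list(s, s3)), "mixed elements")
})

test_that("vascular density counts exactly the planted in-gate canals", {
  # pixel size chosen so the cortex is 0.5 mm^2: density = count / CA
  spec0 <- section_spec("annulus", 50, 30)
  ps <- sqrt(0.5 / (make_section(spec0)$n_pixels))
  spec <- section_spec("annulus", 50, 30, pixel_size = ps,
                       pores = list(count = 30, radius = 2, seed = 11))
  s <- make_section(spec)
  cortex <- section_mask(s$gray < 0.9, ps)
  vr <- vascular_density(s$gray, cortex, threshold = 0.5, size_range = c(1, 40))
  expect_identical(vr$canal_count, 30L)
  expect_equal(vr$density, 60, tolerance = 0.02)
  # pore-free cortex
  s0 <- make_section(spec0)
  vr0 <- vascular_density(s0$gray, section_mask(s0$gray < 0.9, 1), 0.5, c(1, 40))
  expect_identical(vr0$canal_count, 0L)
  expect_identical(vr0$density, 0)
  # size gate excludes every planted component
  vr_big <- vascular_density(s$gray, cortex, 0.5, c(50, 500))
  expect_identical(vr_big$canal_count, 0L)
  expect_error(vascular_density(s$gray, cortex, 0.5, c(40, 1)), "min < max")
})

test_that("degenerate masks are rejected and split cortices warned about", {
  expect_error(section_mask(matrix(logical(0), 0, 0), 1), "empty")
  one_px <- matrix(FALSE, 5, 5); one_px[3, 3] <- TRUE
  expect_error(compute_section_properties(section_mask(one_px, 1)),
               "degenerate")
  two <- matrix(FALSE, 20, 20)
  two[2:5, 2:5] <- TRUE; two[12:15, 12:15] <- TRUE
  expect_warning(compute_section_properties(section_mask(two, 1)),
                 "connected component")
})
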