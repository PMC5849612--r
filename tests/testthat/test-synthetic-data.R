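test_that("section generator truths satisfy every beam-theory invariant", {
  set.seed(51)
  for (i in 1:15) {
    a <- runif(1, 30, 60); b <- runif(1, 15, a)
    sp <- section_spec("elliptical_ring", c(a, b), c(a, b) * runif(1, 0.4, 0.8),
                       rotation_deg = runif(1, -90, 90))
    tr <- make_section(sp)$truth
    expect_equal(tr$J, tr$Imax + tr$Imin)
    expect_equal(tr$Imax + tr$Imin, tr$Ixx + tr$Iyy)
    expect_gte(tr$Imax, tr$Imin)
    expect_true(tr$ca_ta > 0 && tr$ca_ta <= 1)
    expect_lte(tr$CA, tr$TA)
    expect_gte(tr$ellipticity, 1)
  }
  expect_error(section_spec("annulus", 30, 35), "strictly inside")
})

test_that("dataset generation is bit-reproducible and obeys its spec", {
  spec <- dataset_spec()
  d1 <- make_dataset(spec, seed = 101)
  d2 <- make_dataset(spec, seed = 101)
  expect_identical(d1$traits, d2$traits)
  expect_true(ape::all.equal.phylo(d1$tree, d2$tree, use.edge.length = TRUE))

  tr <- d1$traits
  expect_equal(nrow(tr), 70L)
  expect_equal(sum(!tr$is_mystery), 67L)
  expect_equal(sum(tr$is_mystery), 3L)
  expect_true(all(is.na(tr$scheme_close[tr$is_mystery])))
  expect_true(all(tr$mass_g > 0))
  # masses span five orders of magnitude across categories by construction
  rng <- range(spec$mass_ranges)
  expect_gte(log10(rng[2] / rng[1]), 5)
  # every taxon maps to exactly one tip
  expect_setequal(tr$taxon, d1$tree$tip.label)
})

test_that("volant and non-volant CA/TA separate at 0.60 for nearly all taxa", {
  spec <- dataset_spec()
  expect_true(all(rowMeans(spec$means[spec$schemes$volant,
                                      c("ca_ta_h", "ca_ta_u")]) < 0.60))
  expect_true(all(rowMeans(spec$means[!spec$schemes$volant,
                                      c("ca_ta_h", "ca_ta_u")]) > 0.60))
  frac <- sapply(1:10, function(s) {
    ds <- make_dataset(spec, seed = s)
    tr <- ds$traits[!ds$traits$is_mystery, ]
    avg <- (tr$ca_ta_h + tr$ca_ta_u) / 2
    mean((avg < 0.60) == tr$volant)
  })
  expect_true(all(frac >= 0.95))
})

test_that("a noise-free spec collapses every taxon onto its category mean", {
  spec <- dataset_spec(sd_noise = c(ca_ta = 0, ljm = 0),
                       bm_sd = c(ca_ta = 0, ljm = 0))
  ds <- make_dataset(spec, seed = 7)
  cat_of <- ds$truth$category[ds$traits$taxon]
  expect_equal(ds$traits$ca_ta_h, unname(spec$means[cat_of, "ca_ta_h"]))
  expect_equal(log10(ds$traits$jm_u), unname(spec$means[cat_of, "ljm_u"]),
               tolerance = 1e-12)
})

test_that("standalone mystery rows come from the requested category", {
  spec <- dataset_spec()
  m <- make_mystery(spec, "burst", 3, seed = 9)
  expect_equal(nrow(m), 3L)
  expect_identical(attr(m, "truth_category"), "burst")
  expect_true(all(m$is_mystery))
  m0 <- make_mystery(dataset_spec(sd_noise = c(ca_ta = 0, ljm = 0)),
                     "soaring", 2, seed = 9)
  expect_equal(m0$ca_ta_h, rep(spec$means["soaring", "ca_ta_h"], 2))
  expect_error(make_mystery(spec, "swimming", 1, seed = 1), "unknown category")
})
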