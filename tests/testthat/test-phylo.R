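test_that("chronogram round trip preserves topology and branch lengths", {
  tr <- read_chronogram("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(unname(ape::node.depth.edgelength(tr)[1:3]), rep(2, 3))
  rt <- read_chronogram(write_chronogram(tr))
  expect_true(ape::all.equal.phylo(tr, rt, use.edge.length = TRUE))

  set.seed(4)
  big <- ape::rphylo(40, 0.1, 0.03)
  rt2 <- read_chronogram(write_chronogram(big))
  expect_true(ape::all.equal.phylo(big, rt2, use.edge.length = TRUE))

  expect_error(read_chronogram("((A:1,A:1):1,B:2);"), "duplicate")
  expect_error(read_chronogram("((A,B),C);"), "branch lengths")
})

test_that("BM covariance equals shared root-to-MRCA path lengths", {
  C <- phylo_covariance(read_chronogram("((A:1,B:1):1,C:2);"))
  expect_equal(C[c("A", "B", "C"), c("A", "B", "C")],
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  Cs <- phylo_covariance(unit_star(6))
  expect_equal(unname(Cs), diag(6))
  # symmetric PSD on a random chronogram
  set.seed(1)
  Cr <- phylo_covariance(ape::rphylo(20, 0.1, 0.05))
  expect_equal(Cr, t(Cr))
  expect_true(all(eigen(Cr, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
})

test_that("lambda transform scales off-diagonals only and composes multiplicatively", {
  C <- phylo_covariance(five_tip_tree())
  expect_identical(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  Ch <- lambda_transform(C, 0.5)
  off <- upper.tri(C)
  expect_equal(Ch[off], C[off] / 2)
  expect_equal(diag(Ch), diag(C))
  expect_equal(lambda_transform(lambda_transform(C, 0.6), 0.5),
               lambda_transform(C, 0.3))
  expect_error(lambda_transform(C, 1.2), "\\[0, 1\\]")
})

test_that("BM simulation obeys the Brownian variance and covariance laws", {
  # zero-length star: every tip sits at the root state
  zs <- unit_star(5); zs$edge.length <- rep(0, 5)
  sims <- simulate_bm(zs, 1, root_state = 3.5, n_sims = 10, seed = 1)
  expect_true(all(sims == 3.5))

  # single-tip variance ~ sigma2 * depth over 10000 sims
  one <- read_chronogram("(A:4,B:0.0001);")
  v <- var(simulate_bm(one, 1.7, 0, 10000, seed = 2)[, "A"])
  expect_lt(abs(v - 1.7 * 4) / (1.7 * 4), 0.05)

  # empirical tip covariance matches sigma2 * C elementwise
  tt <- five_tip_tree()
  sims <- simulate_bm(tt, 2, 0, 20000, seed = 4)
  emp <- cov(sims)
  theo <- 2 * phylo_covariance(tt)[colnames(sims), colnames(sims)]
  se <- 3 * sqrt((theo^2 + outer(diag(theo), diag(theo))) / 20000)
  expect_true(all(abs(emp - theo) < pmax(se, 0.15)))

  # determinism from the seed
  expect_identical(simulate_bm(tt, 1, 0, 5, seed = 9),
                   simulate_bm(tt, 1, 0, 5, seed = 9))
  expect_error(simulate_bm(tt, -1, 0, 1, seed = 1), "non-negative")
})

test_that("lambda fit stays in bounds and dominates its profile grid", {
  set.seed(6)
  tr <- ape::rphylo(60, 0.1, 0.04)
  y <- simulate_bm(tr, 1, 0, 1, seed = 3)[1, ]
  fl <- fit_lambda(y, tr, grid_n = 101)
  expect_true(fl$lambda_hat >= 0 && fl$lambda_hat <= 1)
  expect_true(all(fl$logLik >= fl$profile$logLik - 1e-6))
  const <- fit_lambda(setNames(rep(2, 60), tr$tip.label), tr)
  expect_true(const$constant)
  expect_true(is.na(const$lambda_hat))
})

test_that("lambda fit agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  set.seed(13)
  tr <- ape::rphylo(80, 0.1, 0.03)
  for (s in 1:3) {
    y <- simulate_bm(tr, 1, 0, 1, seed = 20 + s)[1, ]
    fl <- fit_lambda(y, tr)
    ps <- phytools::phylosig(tr, y, method = "lambda")
    expect_lt(abs(fl$lambda_hat - min(ps$lambda, 1)), 0.05)
  }
  y_iid <- setNames(rnorm(80), tr$tip.label)
  expect_lt(abs(fit_lambda(y_iid, tr)$lambda_hat -
                phytools::phylosig(tr, y_iid, method = "lambda")$lambda), 0.05)
})

test_that("unresolved divergence nodes are placed 4 MY rootward", {
  expect_equal(place_node_age(150), 154)
  expect_equal(place_node_age(10, rule = "explicit", explicit_age = 12.5), 12.5)
  expect_error(place_node_age(150, parent_age = 152), "younger")
})
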