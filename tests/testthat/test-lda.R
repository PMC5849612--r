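test_that("LDA is perfect on separated groups and bounded by the rank rule", {
  sg <- separated_groups()
  fit <- lda_fit(sg$X, sg$groups)
  expect_equal(fit$percent_correct, 100)
  expect_equal(ncol(fit$axes), 2L)                  # min(3 - 1, 4)
  expect_equal(sum(diag(fit$confusion)), length(sg$groups))
  expect_equal(unname(rowSums(fit$confusion)),
               unname(as.integer(table(sg$groups))))
})

test_that("LDA classification agrees with an independent implementation", {
  set.seed(31)
  X <- matrix(rnorm(90 * 4), 90)
  X[1:30, 1] <- X[1:30, 1] + 2.5
  X[31:60, 2] <- X[31:60, 2] + 2.5
  dimnames(X) <- list(sprintf("s%02d", 1:90), paste0("v", 1:4))
  g <- rep(c("a", "b", "c"), each = 30)
  fit <- lda_fit(X, g)
  ref <- MASS::lda(X, g, prior = rep(1 / 3, 3))
  pr <- predict(ref)
  expect_equal(unname(fit$predicted), as.character(pr$class))
  expect_true(all(abs(diag(cor(fit$scores, pr$x))) > 0.999))
})

test_that("resubstitution accuracy is invariant under invertible affine maps", {
  sg <- separated_groups(seed = 32)
  base <- lda_fit(sg$X, sg$groups)$percent_correct
  set.seed(33)
  for (i in 1:5) {
    A <- matrix(rnorm(16), 4)
    while (abs(det(A)) < 0.05) A <- matrix(rnorm(16), 4)
    shift <- matrix(rnorm(4), nrow(sg$X), 4, byrow = TRUE)
    expect_equal(lda_fit(sg$X %*% A + shift, sg$groups)$percent_correct, base)
  }
})

test_that("indistinguishable groups classify at chance level", {
  set.seed(34)
  X <- matrix(rnorm(120 * 4), 120)
  g <- rep(c("a", "b"), each = 60)
  acc <- lda_fit(X, g)$percent_correct
  expect_lt(acc, 75)                                # max prior is 50%
  expect_gt(acc, 40)
})

test_that("mystery classification is exact at group means and flags ties", {
  sg <- separated_groups()
  fit <- lda_fit(sg$X, sg$groups)
  m <- rbind(fit$group_means["g2", ])
  rownames(m) <- "m1"
  cls <- lda_classify(fit, m)
  expect_identical(unname(cls$assignments), "g2")
  expect_equal(cls$distances["m1", "g2"], 0)
  # equidistant point between g1 and g2 means -> first group, flagged
  mid <- rbind((fit$group_means["g1", ] + fit$group_means["g2", ]) / 2)
  rownames(mid) <- "tie"
  # project the midpoint so distances to g1/g2 tie exactly in pooled metric
  cls2 <- lda_classify(fit, mid)
  if (length(cls2$ties)) expect_identical(cls2$ties, "tie")
  expect_error(lda_classify(fit, rbind(c(1, NA, 2, 3))), "missing")
})

test_that("planted mystery rows classify into their source group", {
  sg <- separated_groups(seed = 35)
  fit <- lda_fit(sg$X, sg$groups)
  set.seed(36)
  myst <- matrix(rnorm(3 * 4, sd = 0.5), 3, 4)
  myst[, 2] <- myst[, 2] + 6                        # g2's signature
  colnames(myst) <- colnames(sg$X); rownames(myst) <- paste0("m", 1:3)
  expect_true(all(lda_classify(fit, myst)$assignments == "g2"))
})

test_that("phylogenetic signal screening is calibrated on both regimes", {
  set.seed(37)
  tr <- ape::rphylo(60, 0.1, 0.04)
  recs <- sapply(1:50, function(r) {
    Xi <- matrix(rnorm(60 * 4), 60,
                 dimnames = list(tr$tip.label, paste0("v", 1:4)))
    iid <- screen_phylogenetic_signal(Xi, tr)$recommendation
    Xb <- sapply(1:4, function(j) simulate_bm(tr, 1, 0, 1, seed = r * 10 + j)[1, ])
    dimnames(Xb) <- dimnames(Xi)
    c(iid = iid, bm = screen_phylogenetic_signal(Xb, tr)$recommendation)
  })
  expect_gte(mean(recs["iid", ] == "LDA"), 0.9)
  expect_gte(mean(recs["bm", ] == "lambda-DA"), 0.9)
  # lambda reported for every variable
  X <- matrix(rnorm(60 * 4), 60, dimnames = list(tr$tip.label, paste0("v", 1:4)))
  sc <- screen_phylogenetic_signal(X, tr)
  expect_length(sc$lambda, 4)
  expect_named(sc$lambda, paste0("v", 1:4))
  # when transformation is recommended, the whitened matrix is provided
  # and keeps the taxon geometry usable by LDA
  Xb <- sapply(1:4, function(j) simulate_bm(tr, 1, 0, 1, seed = 900 + j)[1, ])
  dimnames(Xb) <- dimnames(X)
  scb <- screen_phylogenetic_signal(Xb, tr)
  if (scb$recommendation == "lambda-DA") {
    expect_identical(dim(scb$whitened), dim(Xb))
    expect_false(anyNA(scb$whitened))
  }
})

test_that("MANOVA behaves across the degenerate and separable extremes", {
  set.seed(38)
  # identical groups: Wilks near 1
  X <- matrix(rnorm(80 * 3), 80)
  g <- rep(c("a", "b"), each = 40)
  m0 <- manova_groups(X, g)
  expect_gt(m0$wilks, 0.9)
  expect_gt(m0$p, 0.05)
  # strongly separated groups: Wilks near 0, pairwise significant
  X2 <- X; X2[g == "b", ] <- X2[g == "b", ] + 6
  m1 <- manova_groups(X2, g)
  expect_lt(m1$wilks, 0.1)
  expect_lt(m1$pairwise$p_adj[1], 1e-6)
  # one variable, two groups: Rao's F reduces to the one-way ANOVA F
  x1 <- matrix(rnorm(40), dimnames = list(NULL, "v"))
  g1 <- rep(c("a", "b"), each = 20)
  expect_equal(manova_groups(x1, g1)$F,
               anova(lm(x1[, 1] ~ g1))$`F value`[1])
})
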