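#' Simulation-based phylogenetic ANCOVA
#'
#' Tests whether a biomechanical parameter differs among locomotor groups
#' after accounting for body mass, against a null distribution that
#' respects the phylogenetic non-independence of species. The observed
#' statistic is the F for the group effect in the linear model
#' `y ~ covariate + group` (covariate entered first). The null distribution
#' is built by simulating the response under unbounded Brownian motion
#' along the chronogram - rate estimated from the observed data via
#' phylogenetically independent contrasts, root state at the GLS mean -
#' and recomputing F on every simulated response with groups and covariate
#' held fixed. The empirical p-value uses the add-one estimator
#' `(1 + #\{F_null >= F_obs\}) / (1 + n_sims)`, which can never return zero.
#'
#' @param y named numeric response (the biomechanical parameter), one value
#'   per tip.
#' @param group factor/character of locomotor labels, named or ordered as
#'   `y`.
#' @param covariate numeric covariate (body mass, typically on log scale),
#'   named or ordered as `y`.
#' @param tree rooted [ape::phylo] containing all names of `y`.
#' @param n_sims number of Brownian-motion simulations (>= 100).
#' @param seed integer seed for the simulations.
#' @return Object of class `ancova_result`: `F_obs`, `p` (empirical),
#'   `p_classical` (parametric ANCOVA p, for reference), `null_F`,
#'   `sigma2_hat`, `root_hat`, `df`, `n_sims`, `seed`.
#' @export
phylo_ancova <- function(y, group, covariate, tree, n_sims = 10000, seed) {
  if (n_sims < 100) stop("n_sims must be at least 100")
  if (missing(seed)) stop("an explicit integer seed is required")
  if (is.null(names(y))) stop("y must be named by tip label")
  tree <- ape::keep.tip(tree, names(y))
  ord <- tree$tip.label
  y <- y[ord]
  group <- factor(if (!is.null(names(group))) group[ord] else group)
  if (any(table(group) < 2L)) stop("every group needs at least 2 members")
  covariate <- if (!is.null(names(covariate))) covariate[ord] else covariate
  n <- length(y)

  X0 <- stats::model.matrix(~covariate)
  X1 <- stats::model.matrix(~covariate + group)
  if (qr(X1)$rank < ncol(X1)) stop("singular design")
  df_g <- ncol(X1) - ncol(X0)
  df_r <- n - ncol(X1)
  Q0 <- qr.Q(qr(X0)); Q1 <- qr.Q(qr(X1))
  f_group <- function(Y) {
    rss0 <- colSums((Y - Q0 %*% crossprod(Q0, Y))^2)
    rss1 <- colSums((Y - Q1 %*% crossprod(Q1, Y))^2)
    ((rss0 - rss1) / df_g) / (rss1 / df_r)
  }

  F_obs <- f_group(cbind(y))
  C <- phylo_covariance(tree)
  invC <- solve(C)
  root_hat <- sum(invC %*% y) / sum(invC)
  pics <- ape::pic(y, ape::multi2di(tree))
  sigma2_hat <- mean(pics^2)

  sims <- simulate_bm(tree, sigma2_hat, root_hat, n_sims, seed)
  null_F <- f_group(t(sims[, ord, drop = FALSE]))
  p <- (1 + sum(null_F >= F_obs)) / (1 + n_sims)

  structure(list(F_obs = unname(F_obs), p = p,
                 p_classical = stats::pf(F_obs, df_g, df_r,
                                         lower.tail = FALSE),
                 null_F = null_F, sigma2_hat = sigma2_hat,
                 root_hat = root_hat, df = c(df_g, df_r),
                 n_sims = n_sims, seed = seed),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf(
    "phylogenetic ANCOVA: F(%d, %d) = %.3f, empirical p = %.4g (%d BM sims)\n",
    x$df[1], x$df[2], x$F_obs, x$p, x$n_sims))
  invisible(x)
}

#' One-way MANOVA over locomotor groups
#'
#' Wilks' lambda `det(W) / det(W + B)` with Rao's F approximation for the
#' overall test, followed by pairwise two-sample Hotelling T-squared
#' comparisons with a multiple-testing correction.
#'
#' @param X numeric matrix, taxa x variables.
#' @param groups factor/character group labels.
#' @param correction p-value adjustment for the pairwise tests
#'   (default Bonferroni).
#' @param min_n smallest group size admitted to a pairwise comparison.
#' @return List of class `manova_result`: `wilks`, `F`, `df`, `p`,
#'   `pairwise` (data.frame: group pair, T2, F, p, p_adj).
#' @export
manova_groups <- function(X, groups, correction = "bonferroni", min_n = 2L) {
  X <- as.matrix(X)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (ncol(X) == 1L) {
    # Wilks reduces to SSW / SST and Rao's F to the one-way ANOVA F
    a <- stats::anova(stats::lm(X[, 1] ~ groups))
    sm <- matrix(c(a$`Sum Sq`[2] / sum(a$`Sum Sq`), a$`F value`[1],
                   a$Df[1], a$Df[2], a$`Pr(>F)`[1]), 1,
                 dimnames = list("groups", c("Wilks", "approx F", "num Df",
                                             "den Df", "Pr(>F)")))
  } else {
    fit <- stats::manova(X ~ groups)
    sm <- summary(fit, test = "Wilks")$stats
  }
  keep <- levels(groups)[table(groups) >= max(min_n, 2L)]
  pairs <- utils::combn(keep, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    ht <- hotelling_t2(X[groups == g1, , drop = FALSE],
                       X[groups == g2, , drop = FALSE])
    data.frame(group1 = g1, group2 = g2, T2 = ht$T2, F = ht$F, p = ht$p)
  }))
  if (!is.null(pw)) pw$p_adj <- stats::p.adjust(pw$p, method = correction)
  structure(list(wilks = sm["groups", "Wilks"],
                 F = sm["groups", "approx F"],
                 df = c(sm["groups", "num Df"], sm["groups", "den Df"]),
                 p = sm["groups", "Pr(>F)"],
                 pairwise = pw),
            class = "manova_result")
}

# Two-sample Hotelling T-squared with pooled covariance and its exact F
# transform.
hotelling_t2 <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B); p <- ncol(A)
  S <- (stats::cov(A) * (n1 - 1) + stats::cov(B) * (n2 - 1)) / (n1 + n2 - 2)
  d <- colMeans(A) - colMeans(B)
  T2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(S) %*% d)
  dfF <- n1 + n2 - p - 1
  if (dfF < 1) return(list(T2 = T2, F = NA_real_, p = NA_real_))
  Fst <- T2 * dfF / ((n1 + n2 - 2) * p)
  list(T2 = T2, F = Fst, p = stats::pf(Fst, p, dfF, lower.tail = FALSE))
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("MANOVA: Wilks' lambda = %.4f, F(%g, %g) = %.3f, p = %.4g\n",
              x$wilks, x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}
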