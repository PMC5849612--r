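#' Linear discriminant analysis of locomotor groups
#'
#' Fisher discriminant axes from the eigendecomposition of `W^-1 B`, where
#' `W` is the pooled within-group covariance and `B` the between-group
#' covariance of the group means. Training taxa are classified by minimal
#' Mahalanobis distance to the group means in the pooled metric (equal
#' priors: palaeontological groups are small and unbalanced, so group size
#' is not treated as prevalence), and the resubstitution confusion matrix
#' and percent-correct are reported.
#'
#' @param X numeric matrix, taxa x variables (rownames kept).
#' @param groups factor or character vector of group labels, length
#'   `nrow(X)`; at least two groups, and the pooled covariance must be
#'   invertible (groups of size one are allowed, contributing no
#'   within-group degrees of freedom).
#' @return Object of class `lda_result`: `axes` (variables x discriminant
#'   axes `DA1..`), `scores` (training taxa on the axes), `group_means`,
#'   `W` (pooled covariance), `confusion` (resubstitution confusion
#'   matrix), `percent_correct`, `predicted`, `priors`.
#' @export
lda_fit <- function(X, groups) {
  X <- as.matrix(X)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (length(groups) != nrow(X)) stop("groups must match rows of X")
  p <- ncol(X)
  g <- nlevels(groups)
  means <- apply(X, 2, function(col) tapply(col, groups, mean))
  ns <- as.integer(table(groups))
  W <- matrix(0, p, p)
  for (lev in levels(groups)) {
    rows <- X[groups == lev, , drop = FALSE]
    if (nrow(rows) > 1L)
      W <- W + stats::cov(rows) * (nrow(rows) - 1L)
  }
  dfw <- sum(ns - 1L)
  if (dfw < p) stop("too few within-group degrees of freedom")
  W <- W / dfw
  Winv <- tryCatch(solve(W), error = function(e)
    stop("singular pooled within-group covariance; drop a variable"))
  grand <- colMeans(means)              # unweighted: equal priors
  B <- crossprod(sweep(means, 2, grand)) / (g - 1)
  eig <- eigen(Winv %*% B)
  n_axes <- min(g - 1L, p)
  axes <- Re(eig$vectors[, seq_len(n_axes), drop = FALSE])
  # normalise axes to unit pooled within-group variance (MASS convention)
  for (j in seq_len(n_axes))
    axes[, j] <- axes[, j] / sqrt(drop(t(axes[, j]) %*% W %*% axes[, j]))
  dimnames(axes) <- list(colnames(X), paste0("DA", seq_len(n_axes)))
  scores <- sweep(X, 2, grand) %*% axes
  fit <- structure(list(axes = axes, eigenvalues = Re(eig$values[seq_len(n_axes)]),
                        scores = scores, group_means = means, W = W,
                        Winv = Winv, grand_mean = grand,
                        levels = levels(groups),
                        priors = rep(1 / g, g)),
                   class = "lda_result")
  pred <- lda_classify(fit, X)
  fit$predicted <- pred$assignments
  fit$confusion <- table(observed = groups,
                         predicted = factor(pred$assignments,
                                            levels = levels(groups)))
  fit$percent_correct <- 100 * mean(pred$assignments == as.character(groups))
  fit
}

#' Classify taxa with a fitted discriminant model
#'
#' Assigns each row to the group whose mean is closest in the pooled
#' Mahalanobis metric. Exact ties are broken deterministically by group
#' order and flagged.
#'
#' @param model an [lda_fit()] result.
#' @param newX numeric matrix of taxa x the same variables.
#' @return List: `assignments` (named character), `distances` (taxa x
#'   groups Mahalanobis distances), `scores` (discriminant scores), `ties`
#'   (names of taxa with tied minimal distance).
#' @export
lda_classify <- function(model, newX) {
  stopifnot(inherits(model, "lda_result"))
  newX <- as.matrix(newX)
  if (anyNA(newX)) stop("missing parameter values in classification input")
  d2 <- t(apply(newX, 1, function(x) {
    dif <- sweep(model$group_means, 2, x)
    rowSums((dif %*% model$Winv) * dif)
  }))
  if (nrow(newX) == 1L) d2 <- matrix(d2, 1, dimnames = list(rownames(newX), model$levels))
  colnames(d2) <- model$levels
  idx <- apply(d2, 1, which.min)
  ties <- rownames(newX)[apply(d2, 1, function(r) sum(r == min(r)) > 1L)]
  list(assignments = stats::setNames(model$levels[idx], rownames(newX)),
       distances = sqrt(d2),
       scores = sweep(newX, 2, model$grand_mean) %*% model$axes,
       ties = ties)
}

#' @export
print.lda_result <- function(x, ...) {
  cat(sprintf("LDA: %d groups, %d axes, resubstitution %.2f%% correct\n",
              length(x$levels), ncol(x$axes), x$percent_correct))
  invisible(x)
}

#' Screen phylogenetic signal before discriminant analysis
#'
#' Fits Pagel's lambda per variable ([fit_lambda()]) and tests it against
#' `lambda = 0` by likelihood ratio. If no variable rejects independence
#' (after a multiple-testing correction across variables), plain LDA is
#' appropriate; otherwise a lambda-transformed discriminant analysis is
#' recommended and a pre-whitened trait matrix is returned, each variable
#' decorrelated by the Cholesky inverse of its lambda-scaled covariance.
#'
#' @param X numeric matrix, taxa x variables, rownames = tip labels.
#' @param tree rooted [ape::phylo].
#' @param alpha significance level.
#' @param correction multiple-testing correction across variables
#'   (see [stats::p.adjust()]).
#' @return List: `lambda` (per-variable estimates), `p` (raw LRT p-values),
#'   `p_adj`, `recommendation` (`"LDA"` or `"lambda-DA"`), `whitened`
#'   (matrix, only when transformation is recommended).
#' @export
screen_phylogenetic_signal <- function(X, tree, alpha = 0.05,
                                       correction = "bonferroni") {
  X <- as.matrix(X)
  tree <- ape::keep.tip(tree, rownames(X))
  fits <- lapply(seq_len(ncol(X)), function(j)
    fit_lambda(stats::setNames(X[, j], rownames(X)), tree))
  lambda <- vapply(fits, `[[`, numeric(1), "lambda_hat")
  p <- vapply(fits, `[[`, numeric(1), "p_signal")
  names(lambda) <- names(p) <- colnames(X)
  p_adj <- stats::p.adjust(p, method = correction)
  signif <- !is.na(p_adj) & p_adj < alpha
  rec <- if (any(signif)) "lambda-DA" else "LDA"
  out <- list(lambda = lambda, p = p, p_adj = p_adj, recommendation = rec)
  if (rec == "lambda-DA") {
    C <- phylo_covariance(tree)[rownames(X), rownames(X)]
    Wh <- X
    for (j in seq_len(ncol(X))) {
      lam <- if (is.na(lambda[j])) 0 else lambda[j]
      Tj <- solve(t(chol(lambda_transform(C, lam))))
      Wh[, j] <- drop(Tj %*% X[, j]) * sqrt(mean(diag(C)))
    }
    out$whitened <- Wh
  }
  out
}
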