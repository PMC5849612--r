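#' Phylogenetic principal component analysis
#'
#' PCA of tip traits corrected for Brownian-motion covariance on a
#' chronogram. The ancestral (GLS) mean is
#' `a = (1' C^-1 1)^-1 1' C^-1 X`, the evolutionary covariance
#' `(X - 1a)' C^-1 (X - 1a) / (n - 1)`; in correlation mode (the default
#' used throughout the volancy analysis) variables are first scaled by
#' their evolutionary standard deviations so the decomposed matrix is the
#' evolutionary correlation matrix. Scores are centred on the GLS mean, not
#' phylogenetically whitened, so on a star tree with unit branch lengths
#' the analysis reduces exactly to ordinary correlation-matrix PCA.
#'
#' @param X numeric matrix, taxa x variables, rownames = tip labels.
#' @param tree rooted [ape::phylo]; extra tips are pruned, every row of `X`
#'   must be a tip.
#' @param mode `"cor"` (evolutionary correlation) or `"cov"`.
#' @return Object of class `ppca` with `scores` (taxa x components),
#'   `loadings` (variables x components, eigenvector basis scaled by
#'   sqrt eigenvalue), `vectors` (raw eigenvectors), `eigenvalues`,
#'   `gls_mean`, `evol_sd`, `mode`.
#' @export
phyl_pca <- function(X, tree, mode = c("cor", "cov")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (is.null(rownames(X))) stop("X must have taxon rownames")
  if (nrow(X) <= ncol(X)) stop("need more taxa than variables")
  missing <- setdiff(rownames(X), tree$tip.label)
  if (length(missing)) stop("taxa absent from tree: ",
                            paste(missing, collapse = ", "))
  tree <- ape::keep.tip(tree, rownames(X))
  C <- phylo_covariance(tree)[rownames(X), rownames(X)]
  invC <- solve(C)
  n <- nrow(X)

  gls_mean <- function(M) as.numeric(colSums(invC %*% M) / sum(invC))
  a <- gls_mean(X)
  ctr <- sweep(X, 2, a)
  Vv <- crossprod(ctr, invC %*% ctr) / (n - 1)
  evol_sd <- sqrt(diag(Vv))
  if (mode == "cor") {
    if (any(evol_sd == 0)) stop("constant variable in correlation mode")
    Xs <- sweep(X, 2, evol_sd, "/")
    V <- Vv / tcrossprod(evol_sd)
    a <- gls_mean(Xs)
    ctr <- sweep(Xs, 2, a)
  } else {
    V <- Vv
  }
  eig <- eigen(V, symmetric = TRUE)
  vec <- eig$vectors
  dimnames(vec) <- list(colnames(X), paste0("PC", seq_len(ncol(vec))))
  scores <- ctr %*% vec
  colnames(scores) <- colnames(vec)
  structure(list(scores = scores,
                 loadings = sweep(vec, 2, sqrt(pmax(eig$values, 0)), "*"),
                 vectors = vec, eigenvalues = eig$values,
                 gls_mean = a, evol_sd = evol_sd, mode = mode),
            class = "ppca")
}

#' Project new taxa onto fitted phylogenetic principal components
#'
#' Applies the training scaling (evolutionary SDs in correlation mode), GLS
#' centring, and eigenvector rotation to rows that took no part in the fit
#' (mystery taxa).
#'
#' @param fit a [phyl_pca()] result.
#' @param newX numeric matrix, taxa x the same variables.
#' @return score matrix for the new taxa.
#' @export
ppca_project <- function(fit, newX) {
  stopifnot(inherits(fit, "ppca"))
  newX <- as.matrix(newX)
  if (fit$mode == "cor") newX <- sweep(newX, 2, fit$evol_sd, "/")
  sweep(newX, 2, fit$gls_mean) %*% fit$vectors
}

#' @export
print.ppca <- function(x, ...) {
  cat(sprintf("Phylogenetic PCA (mode %s): %d taxa, %d variables\n",
              x$mode, nrow(x$scores), length(x$eigenvalues)))
  cat("eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}
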