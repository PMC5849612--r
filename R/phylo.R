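#' Read and validate a chronogram
#'
#' Thin wrapper over [ape::read.tree()] that enforces the contract the
#' comparative machinery assumes: a rooted tree with branch lengths (in MY)
#' and unique tip labels.
#'
#' @param x Newick text or a path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_chronogram <- function(x) {
  tree <- if (length(x) == 1L && file.exists(x)) ape::read.tree(x)
          else ape::read.tree(text = x)
  if (is.null(tree)) stop("malformed Newick input")
  validate_chronogram(tree)
  tree
}

#' @rdname read_chronogram
#' @param tree an [ape::phylo] tree.
#' @param path output file; if `NULL` the Newick string is returned.
#' @export
write_chronogram <- function(tree, path = NULL) {
  validate_chronogram(tree)
  if (is.null(path)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = path); invisible(path) }
}

validate_chronogram <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("chronogram must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  # a star phylogeny (single basal polytomy) is rooted by construction
  if (!ape::is.rooted(tree) && tree$Nnode > 1L)
    stop("chronogram must be rooted")
  invisible(tree)
}

#' Brownian-motion covariance of a chronogram
#'
#' Under Brownian motion, the expected covariance between two tips is the
#' shared root-to-MRCA path length. Returns that matrix (`lambda = 1`) in
#' the tree's tip order.
#'
#' @param tree rooted [ape::phylo] with branch lengths in MY.
#' @return `n x n` matrix `C` with `C[i, j]` the shared path length, MY.
#' @export
phylo_covariance <- function(tree) {
  validate_chronogram(tree)
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving tip variances
#' unchanged: `lambda = 1` is pure Brownian motion, `lambda = 0` a star
#' phylogeny (no autocorrelation).
#'
#' @param C phylogenetic covariance matrix.
#' @param lambda scalar in `[0, 1]`.
#' @return transformed covariance matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Simulate Brownian motion along a chronogram
#'
#' Unbounded Brownian motion: each branch adds an independent zero-mean
#' Gaussian increment of variance `sigma2 * branch length`; tips inherit
#' the cumulative sum from the root state. Increments are drawn
#' branch-by-branch in a deterministic preorder so a seed fully reproduces
#' the simulation.
#'
#' @param tree rooted [ape::phylo], branch lengths MY.
#' @param sigma2 BM rate (trait variance per MY), > 0.
#' @param root_state trait value at the root.
#' @param n_sims number of independent replicate simulations.
#' @param seed integer seed; required for reproducibility.
#' @return `n_sims x n_tips` matrix, columns named by tip label.
#' @export
simulate_bm <- function(tree, sigma2, root_state = 0, n_sims = 1, seed) {
  validate_chronogram(tree)
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  if (missing(seed)) stop("an explicit integer seed is required")
  set.seed(as.integer(seed))
  n_tip <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "cladewise")       # preorder: root outward
  n_node <- n_tip + tr$Nnode
  states <- matrix(0, n_node, n_sims)
  root <- n_tip + 1L
  states[root, ] <- root_state
  inc <- matrix(stats::rnorm(nrow(tr$edge) * n_sims), nrow(tr$edge), n_sims) *
    sqrt(sigma2 * tr$edge.length)
  for (e in seq_len(nrow(tr$edge)))
    states[tr$edge[e, 2], ] <- states[tr$edge[e, 1], ] + inc[e, ]
  out <- t(states[seq_len(n_tip), , drop = FALSE])
  colnames(out) <- tr$tip.label
  out
}

#' Maximum-likelihood Pagel's lambda for a univariate trait
#'
#' Profiles the Gaussian phylogenetic likelihood over `lambda` in `[0, 1]`:
#' at each `lambda` the ancestral mean is the GLS estimate and the rate its
#' ML profile, leaving a 1-D bounded optimisation. A likelihood-ratio test
#' against `lambda = 0` (chi-squared, 1 df; conservative at the boundary)
#' quantifies phylogenetic signal.
#'
#' @param trait named numeric vector of tip values.
#' @param tree rooted [ape::phylo]; tips must match `names(trait)`.
#' @param grid_n resolution of the returned profile grid.
#' @return list with `lambda_hat`, `logLik`, `logLik0` (at `lambda = 0`),
#'   `p_signal` (LRT p-value vs `lambda = 0`), `profile` (data.frame of
#'   `lambda`, `logLik`), and `constant` (TRUE when the trait is constant
#'   and lambda is unidentifiable).
#' @export
fit_lambda <- function(trait, tree, grid_n = 21) {
  validate_chronogram(tree)
  if (ape::Ntip(tree) < 4L) stop("need at least 4 tips")
  if (is.null(names(trait))) stop("trait must be named by tip label")
  if (!setequal(names(trait), tree$tip.label))
    stop("trait names do not match tree tips")
  C <- phylo_covariance(tree)
  y <- trait[rownames(C)]
  n <- length(y)
  if (stats::sd(y) == 0)
    return(list(lambda_hat = NA_real_, logLik = NA_real_, logLik0 = NA_real_,
                p_signal = NA_real_, profile = NULL, constant = TRUE))
  ll <- function(lam) lambda_loglik(y, C, lam)
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-8)
  # the optimum can sit on a boundary that optimize() never evaluates
  cand <- rbind(c(opt$maximum, opt$objective), c(0, ll(0)), c(1, ll(1)))
  best <- cand[which.max(cand[, 2]), ]
  ll0 <- cand[2, 2]
  grid <- seq(0, 1, length.out = grid_n)
  list(lambda_hat = unname(best[1]), logLik = unname(best[2]), logLik0 = ll0,
       p_signal = stats::pchisq(2 * (best[2] - ll0), df = 1,
                                lower.tail = FALSE),
       profile = data.frame(lambda = grid, logLik = vapply(grid, ll, 0)),
       constant = FALSE)
}

# Profile log-likelihood of the lambda model: GLS mean, ML-profiled rate.
lambda_loglik <- function(y, C, lambda) {
  V <- lambda_transform(C, lambda)
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  one <- rep(1, n)
  Vi1 <- backsolve(ch, forwardsolve(t(ch), one))
  Viy <- backsolve(ch, forwardsolve(t(ch), y))
  a <- sum(Vi1 * y) / sum(Vi1 * one)
  r <- y - a
  Vir <- Viy - a * Vi1
  s2 <- sum(r * Vir) / n
  -n / 2 * log(2 * pi * s2) - logdet / 2 - n / 2
}

#' Place an insufficiently resolved divergence node
#'
#' Chronogram construction rule for divergence nodes whose age cannot be
#' resolved from occurrence data: place them a standard 4 MY rootward of
#' their closest established crownward node.
#'
#' @param crownward_age age of the closest established crownward node, MY.
#' @param rule `"+4MY"` (default) or `"explicit"`.
#' @param explicit_age node age used under rule `"explicit"`, MY.
#' @param parent_age optional age of the parent (rootward) node, MY; the
#'   placed node must be younger.
#' @return placed node age, MY.
#' @export
place_node_age <- function(crownward_age, rule = c("+4MY", "explicit"),
                           explicit_age = NULL, parent_age = NULL) {
  rule <- match.arg(rule)
  age <- switch(rule,
    "+4MY" = crownward_age + 4,
    explicit = {
      if (is.null(explicit_age)) stop("rule 'explicit' needs explicit_age")
      explicit_age
    })
  if (!is.null(parent_age) && age >= parent_age)
    stop(sprintf("placed age %.6g MY is not younger than parent %.6g MY",
                 age, parent_age))
  age
}
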