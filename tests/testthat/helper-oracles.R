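# Independent oracles and small fixtures shared across tests.

# Exhaustive k-medoids optimum: enumerate every medoid set.
brute_force_pam_cost <- function(points, k) {
  d <- as.matrix(stats::dist(points))
  combos <- utils::combn(nrow(points), k)
  min(apply(combos, 2, function(m)
    sum(apply(d[, m, drop = FALSE], 1, min))))
}

# Fully binary 5-tip chronogram, depth 2.5 MY everywhere.
five_tip_tree <- function() {
  read_chronogram("(((A:1,B:1):1,(C:0.5,D:0.5):1.5):0.5,E:2.5);")
}

# Star phylogeny with unit branch lengths.
unit_star <- function(n) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(1, n)
  tr
}

# Two well-separated Gaussian blobs with known labels.
two_blobs <- function(n_per = 15, sep = 8, d = 3, seed = 1) {
  set.seed(seed)
  pts <- rbind(matrix(stats::rnorm(n_per * d), n_per),
               matrix(stats::rnorm(n_per * d) + sep, n_per))
  rownames(pts) <- paste0("p", seq_len(2 * n_per))
  list(points = pts, labels = rep(1:2, each = n_per))
}

# Small trait system for discriminant tests: three clearly separated groups
# in four variables.
separated_groups <- function(n_per = 12, seed = 3) {
  set.seed(seed)
  X <- matrix(stats::rnorm(3 * n_per * 4, sd = 0.5), 3 * n_per, 4)
  X[seq_len(n_per), 1] <- X[seq_len(n_per), 1] + 6
  X[n_per + seq_len(n_per), 2] <- X[n_per + seq_len(n_per), 2] + 6
  colnames(X) <- c("ca_ta_h", "ca_ta_u", "jm_h", "jm_u")
  rownames(X) <- sprintf("tx%02d", seq_len(nrow(X)))
  list(X = X, groups = rep(c("g1", "g2", "g3"), each = n_per))
}
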