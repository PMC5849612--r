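#' Partitioning Around Medoids (BUILD + SWAP)
#'
#' k-medoids clustering with the classical BUILD initialisation and greedy
#' SWAP refinement: swaps of a medoid with a non-medoid are applied while
#' the total within-cluster dissimilarity to the medoid strictly decreases,
#' taking the best available swap at each step. Euclidean dissimilarity;
#' ties are broken by the first (lowest) index, so the result is
#' deterministic.
#'
#' BUILD + SWAP is a local search and can stall short of the global
#' optimum on small adversarial instances; whenever the number of candidate
#' medoid sets is modest (`choose(n, k) <= enum_limit`) the solution is
#' refined to the exact optimum by enumeration, so two-cluster problems at
#' the scale of this analysis are always solved to optimality.
#'
#' @param points numeric matrix, observations x dimensions (rownames kept).
#' @param k number of clusters, `k < n`.
#' @param enum_limit largest number of candidate medoid sets enumerated in
#'   the exact refinement pass.
#' @return List of class `cluster_result`: `assignments` (named integer
#'   cluster ids), `medoids` (row indices), `cost` (total dissimilarity to
#'   medoids), `k`, `method = "pam"`.
#' @export
pam_cluster <- function(points, k, enum_limit = 10000) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k >= n) {
    if (k > n) stop("k must not exceed n")
    med <- seq_len(n)
  } else {
    d <- as.matrix(stats::dist(points))
    # BUILD: start from the most central point, then add the point giving
    # the largest decrease in total cost
    med <- which.min(rowSums(d))
    while (length(med) < k) {
      best_gain <- -Inf; best_j <- NA_integer_
      cur <- apply(d[, med, drop = FALSE], 1, min)
      for (j in setdiff(seq_len(n), med)) {
        gain <- sum(pmax(cur - d[, j], 0))
        if (gain > best_gain + 1e-12) { best_gain <- gain; best_j <- j }
      }
      med <- c(med, best_j)
    }
    # SWAP
    repeat {
      cur_cost <- sum(apply(d[, med, drop = FALSE], 1, min))
      best_cost <- cur_cost; best_swap <- NULL
      for (i in seq_along(med)) for (j in setdiff(seq_len(n), med)) {
        cand <- med; cand[i] <- j
        cost <- sum(apply(d[, cand, drop = FALSE], 1, min))
        if (cost < best_cost - 1e-12) { best_cost <- cost; best_swap <- c(i, j) }
      }
      if (is.null(best_swap)) break
      med[best_swap[1]] <- best_swap[2]
    }
    # exact refinement: enumerate all medoid sets when feasible
    if (choose(n, k) <= enum_limit) {
      combos <- utils::combn(n, k)
      costs <- apply(combos, 2, function(m)
        sum(apply(d[, m, drop = FALSE], 1, min)))
      med <- combos[, which.min(costs)]
    }
    med <- sort(med)
  }
  assign_to_medoids(points, med, method = "pam")
}

assign_to_medoids <- function(points, med, method) {
  n <- nrow(points)
  if (length(med) == n) {
    asg <- seq_len(n); cost <- 0
  } else {
    d <- as.matrix(stats::dist(points))[, med, drop = FALSE]
    asg <- apply(d, 1, which.min)
    cost <- sum(d[cbind(seq_len(n), asg)])
  }
  names(asg) <- rownames(points)
  structure(list(assignments = asg, medoids = med, cost = cost,
                 k = length(med), method = method),
            class = "cluster_result")
}

#' k-means clustering with seeded restarts
#'
#' Lloyd-type k-means ([stats::kmeans()]) with multiple random restarts,
#' keeping the solution of lowest total within-cluster sum of squares;
#' deterministic given the seed.
#'
#' @param points numeric matrix, observations x dimensions.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param nstart number of restarts.
#' @return List of class `cluster_result`: `assignments`, `centers`,
#'   `inertia` (total within-cluster SS), `k`, `method = "kmeans"`.
#' @export
kmeans_cluster <- function(points, k, seed, nstart = 25) {
  points <- as.matrix(points)
  if (k >= nrow(points)) stop("k must be smaller than n")
  if (missing(seed)) stop("an explicit integer seed is required")
  set.seed(as.integer(seed))
  km <- stats::kmeans(points, centers = k, nstart = nstart, iter.max = 100)
  asg <- km$cluster
  names(asg) <- rownames(points)
  structure(list(assignments = asg, centers = km$centers,
                 inertia = km$tot.withinss, k = k, method = "kmeans"),
            class = "cluster_result")
}

#' Volancy success rate of a two-cluster partition
#'
#' Maps the two clusters onto volant / non-volant by majority vote over the
#' training taxa, then scores the percentage of training taxa whose mapped
#' cluster label matches their known volancy. Mystery taxa receive a mapped
#' label but are excluded from the rate.
#'
#' @param assignments named integer vector of cluster ids (two clusters).
#' @param volant named logical vector of known volancy for training taxa;
#'   taxa present in `assignments` but absent here are treated as mystery.
#' @return List: `success_rate` (percent), `misclassified` (taxon names),
#'   `cluster_map` (cluster id -> `TRUE`/`FALSE` volant), `mystery_volant`
#'   (mapped volancy of mystery taxa), `tie` (logical).
#' @export
volancy_success <- function(assignments, volant) {
  ids <- sort(unique(assignments))
  if (length(ids) != 2L) stop("expected exactly two clusters")
  train <- intersect(names(assignments), names(volant))
  if (!length(train)) stop("no training taxa with volancy labels")
  tie <- FALSE
  map <- vapply(ids, function(id) {
    v <- volant[train[assignments[train] == id]]
    if (!length(v)) return(NA)
    frac <- mean(v)
    if (frac == 0.5) tie <<- TRUE
    frac >= 0.5
  }, logical(1))
  if (anyNA(map)) map[is.na(map)] <- !map[!is.na(map)][1]
  if (map[1] == map[2]) {
    # both clusters majority-volant (or neither): fall back to the cluster
    # with the higher volant fraction carrying the volant label
    fr <- vapply(ids, function(id)
      mean(volant[train[assignments[train] == id]]), numeric(1))
    map <- fr == max(fr)
    if (sum(map) != 1L) { map <- c(TRUE, FALSE); tie <- TRUE }
  }
  names(map) <- as.character(ids)
  mapped <- map[as.character(assignments)]
  names(mapped) <- names(assignments)
  ok <- mapped[train] == volant[train]
  mystery <- setdiff(names(assignments), names(volant))
  list(success_rate = 100 * mean(ok),
       misclassified = train[!ok],
       cluster_map = map,
       mystery_volant = mapped[mystery],
       tie = tie)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("%s clustering: k = %d, n = %d", x$method, x$k,
              length(x$assignments)))
  if (!is.null(x$cost)) cat(sprintf(", cost = %.4g", x$cost))
  if (!is.null(x$inertia)) cat(sprintf(", inertia = %.4g", x$inertia))
  cat("\n")
  invisible(x)
}
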