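#' Locomotor category schemes
#'
#' The thirteen locomotor categories used throughout: five avian flight
#' modes under each of the two classification schemes (near-synonymous
#' pairs share a generator category), the volant wing-propelled diving
#' group, and the added archosaurian strategies (two pterosaurian flight
#' categories, non-volant wing-propelled diving, ratite bipedal,
#' dinosaurian bipedal and omnipedal, crocodilian quadrupedal).
#'
#' @return data.frame with columns `category` (generator key), `viscor`,
#'   `close` (scheme labels), `volant` (logical).
#' @export
locomotor_schemes <- function() {
  data.frame(
    category = c("burst", "bounding", "flapping", "flap_gliding", "soaring",
                 "volant_diving", "ptero_long", "ptero_short",
                 "nonvolant_diving", "ratite", "dino_biped", "dino_omniped",
                 "croc"),
    viscor = c("short", "forward_flapping_bounding", "high_frequency_flapping",
               "undulating", "gliding_soaring",
               "volant_wing_propelled_diving", "long_tailed_pterosaurian",
               "short_tailed_pterosaurian", "non_volant_wing_propelled_diving",
               "ratite_bipedal", "dinosaurian_bipedal",
               "dinosaurian_omnipedal", "crocodilian_quadrupedal"),
    close = c("burst", "intermittent_bounding", "continuous_flapping",
              "flap_gliding", "soaring",
              "volant_wing_propelled_diving", "long_tailed_pterosaurian",
              "short_tailed_pterosaurian", "non_volant_wing_propelled_diving",
              "ratite_bipedal", "dinosaurian_bipedal",
              "dinosaurian_omnipedal", "crocodilian_quadrupedal"),
    volant = c(rep(TRUE, 8), rep(FALSE, 5)),
    stringsAsFactors = FALSE)
}

#' Specify an archosaur-like synthetic trait dataset
#'
#' Encodes the study conditions the trait generator emulates: 67 training
#' taxa over 13 locomotor categories plus 3 mystery specimens, body masses
#' log-uniform per category spanning five orders of magnitude (10 g to
#' 10^6 g), relative cortical thickness (CA/TA) of volant category means
#' below 0.60 and non-volant above (wing-propelled divers elevated but
#' volant), a mass-normalised torsional resistance (J/M) gradient rising
#' from flap-dominated to soar-dominated flight, and residual covariance
#' structured by Brownian motion on a chronogram.
#'
#' @param n_per_category named integer vector of taxa per category;
#'   defaults sum to 67.
#' @param tree_shape `"birth-death"`, `"star"` or `"balanced"`.
#' @param depth root-to-tip depth the tree is scaled to, MY.
#' @param means matrix `category x c(ca_ta_h, ca_ta_u, ljm_h, ljm_u)` of
#'   category means; `ljm_*` are log10 J/M (mm^4 g^-1).
#' @param sd_noise independent residual SD for `ca_ta` and `ljm` variables.
#' @param bm_sd SD of the Brownian tip deviation for `ca_ta` and `ljm`
#'   variables (BM rate is `bm_sd^2 / depth`).
#' @param mass_ranges matrix `category x c(lo, hi)` of body mass ranges, g.
#' @param n_mystery number of unlabeled mystery specimens.
#' @param mystery_category generator category the mystery specimens are
#'   drawn from (burst-like by default, standing in for unclassified
#'   fossils of a short/burst flyer).
#' @return List of class `dataset_spec`.
#' @export
dataset_spec <- function(n_per_category = NULL,
                         tree_shape = c("birth-death", "star", "balanced"),
                         depth = 250,
                         means = NULL,
                         sd_noise = c(ca_ta = 0.025, ljm = 0.12),
                         bm_sd = c(ca_ta = 0.012, ljm = 0.06),
                         mass_ranges = NULL,
                         n_mystery = 3,
                         mystery_category = "burst") {
  sch <- locomotor_schemes()
  cats <- sch$category
  if (is.null(n_per_category))
    n_per_category <- stats::setNames(
      c(8, 8, 10, 8, 8, 3, 1, 1, 4, 5, 6, 2, 3), cats)
  if (is.null(means)) {
    means <- matrix(c(
      # ca_ta_h, ca_ta_u, ljm_h, ljm_u
      0.48, 0.46, -0.45, -0.55,   # burst
      0.33, 0.32, -0.55, -0.65,   # bounding
      0.38, 0.36, -0.05, -0.15,   # flapping
      0.36, 0.35,  0.25,  0.15,   # flap_gliding
      0.43, 0.41,  0.65,  0.55,   # soaring
      0.59, 0.58, -0.85, -0.95,   # volant_diving
      0.56, 0.54,  0.00, -0.10,   # ptero_long
      0.27, 0.26,  0.70,  0.60,   # ptero_short
      0.76, 0.74, -1.05, -1.15,   # nonvolant_diving
      0.72, 0.74, -1.00, -1.10,   # ratite
      0.80, 0.78, -1.20, -1.30,   # dino_biped
      0.83, 0.81, -1.40, -1.50,   # dino_omniped
      0.86, 0.84, -1.50, -1.60),  # croc
      ncol = 4, byrow = TRUE,
      dimnames = list(cats, c("ca_ta_h", "ca_ta_u", "ljm_h", "ljm_u")))
  }
  if (is.null(mass_ranges)) {
    mass_ranges <- matrix(c(
      150, 3000,    10, 100,     100, 5000,   30, 500,    1000, 12000,
      400, 1000,    80, 120,     5000, 8000,  1000, 30000, 2e4, 1.5e5,
      1e3, 1e6,     1e4, 1e6,    2e4, 2e5),
      ncol = 2, byrow = TRUE, dimnames = list(cats, c("lo", "hi")))
  }
  stopifnot(setequal(names(n_per_category), cats),
            all(rownames(means) == cats),
            mystery_category %in% cats)
  structure(list(n_per_category = n_per_category[cats],
                 tree_shape = match.arg(tree_shape), depth = depth,
                 means = means, sd_noise = sd_noise, bm_sd = bm_sd,
                 mass_ranges = mass_ranges, n_mystery = n_mystery,
                 mystery_category = mystery_category, schemes = sch),
            class = "dataset_spec")
}

#' Generate a synthetic trait table and chronogram
#'
#' Builds the tree, assigns categories to tips, and generates traits as
#' category means plus a Brownian-motion deviation simulated on the tree
#' ([simulate_bm()]) plus independent Gaussian noise; body masses are drawn
#' log-uniform per category. Mystery specimens are unlabeled rows drawn
#' from the generative model of `spec$mystery_category`. Bit-reproducible
#' from `(spec, seed)`.
#'
#' @param spec a [dataset_spec()].
#' @param seed integer seed.
#' @return List: `traits` (data.frame: `taxon`, `ca_ta_h`, `ca_ta_u`,
#'   `jm_h`, `jm_u` (raw mm^4 g^-1), `mass_g`, `volant`, `scheme_viscor`,
#'   `scheme_close`, `is_mystery`; label columns `NA` for mystery rows),
#'   `tree` ([ape::phylo] over all taxa), `truth` (planted categories and
#'   deviations).
#' @export
make_dataset <- function(spec, seed) {
  stopifnot(inherits(spec, "dataset_spec"))
  if (missing(seed)) stop("an explicit integer seed is required")
  seed <- as.integer(seed)
  n_train <- sum(spec$n_per_category)
  n <- n_train + spec$n_mystery
  set.seed(seed)
  tree <- switch(spec$tree_shape,
    "birth-death" = ape::rphylo(n, birth = 0.1, death = 0.05),
    star = ape::stree(n, "star"),
    balanced = {
      k <- 2^ceiling(log2(n))
      tr <- ape::stree(k, "balanced")
      if (k > n) tr <- ape::drop.tip(tr, seq_len(k - n)) else tr
    })
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  tree$edge.length <- tree$edge.length * spec$depth /
    max(ape::node.depth.edgelength(tree)[seq_len(n)])
  tree$tip.label <- sprintf("sp%03d", seq_len(n))

  cats <- rep(names(spec$n_per_category), spec$n_per_category)
  perm <- sample.int(n)                       # category-to-tip assignment
  taxa <- tree$tip.label[perm]
  category <- stats::setNames(
    c(cats, rep(spec$mystery_category, spec$n_mystery)), taxa)
  is_mystery <- stats::setNames(
    c(rep(FALSE, n_train), rep(TRUE, spec$n_mystery)), taxa)

  vars <- colnames(spec$means)
  bm_sigma2 <- ifelse(grepl("^ca_ta", vars),
                      spec$bm_sd[["ca_ta"]], spec$bm_sd[["ljm"]])^2 / spec$depth
  noise_sd <- ifelse(grepl("^ca_ta", vars),
                     spec$sd_noise[["ca_ta"]], spec$sd_noise[["ljm"]])
  X <- matrix(NA_real_, n, length(vars), dimnames = list(taxa, vars))
  bm_dev <- X
  for (j in seq_along(vars)) {
    dev <- if (bm_sigma2[j] > 0)
      simulate_bm(tree, bm_sigma2[j], 0, 1, seed = seed + 1000L * j)[1, ]
    else stats::setNames(numeric(n), tree$tip.label)
    bm_dev[, j] <- dev[taxa]
    eps <- if (noise_sd[j] > 0) stats::rnorm(n, 0, noise_sd[j]) else 0
    X[, j] <- spec$means[category[taxa], vars[j]] + bm_dev[, j] + eps
  }
  X[, 1:2] <- pmin(pmax(X[, 1:2], 0.02), 1)   # CA/TA is a physical ratio

  mr <- spec$mass_ranges[category[taxa], , drop = FALSE]
  mass <- 10^stats::runif(n, log10(mr[, "lo"]), log10(mr[, "hi"]))

  sch <- spec$schemes
  row <- match(category[taxa], sch$category)
  traits <- data.frame(
    taxon = taxa,
    ca_ta_h = X[, "ca_ta_h"], ca_ta_u = X[, "ca_ta_u"],
    jm_h = 10^X[, "ljm_h"], jm_u = 10^X[, "ljm_u"],
    mass_g = mass,
    volant = ifelse(is_mystery[taxa], NA, sch$volant[row]),
    scheme_viscor = ifelse(is_mystery[taxa], NA, sch$viscor[row]),
    scheme_close = ifelse(is_mystery[taxa], NA, sch$close[row]),
    is_mystery = is_mystery[taxa],
    row.names = taxa, stringsAsFactors = FALSE)

  list(traits = traits, tree = tree,
       truth = list(category = category, bm_dev = bm_dev, seed = seed,
                    spec = spec))
}

#' Draw additional mystery specimens from a category's generative model
#'
#' Standalone generator for unlabeled rows (no tree deviation, mean plus
#' independent noise), used to stress classification beyond the mystery
#' tips already embedded in [make_dataset()].
#'
#' @param spec a [dataset_spec()].
#' @param category generator category to draw from.
#' @param n number of rows.
#' @param seed integer seed.
#' @return data.frame with the four biomechanical parameters and
#'   `is_mystery = TRUE`; the drawn category is recorded in
#'   `attr(, "truth_category")`.
#' @export
make_mystery <- function(spec, category, n, seed) {
  stopifnot(inherits(spec, "dataset_spec"))
  if (!category %in% rownames(spec$means)) stop("unknown category: ", category)
  set.seed(as.integer(seed))
  vars <- colnames(spec$means)
  noise_sd <- ifelse(grepl("^ca_ta", vars),
                     spec$sd_noise[["ca_ta"]], spec$sd_noise[["ljm"]])
  X <- matrix(rep(spec$means[category, ], each = n), n) +
    matrix(stats::rnorm(n * length(vars), 0, rep(noise_sd, each = n)), n)
  colnames(X) <- vars
  out <- data.frame(
    taxon = sprintf("mystery%02d", seq_len(n)),
    ca_ta_h = X[, "ca_ta_h"], ca_ta_u = X[, "ca_ta_u"],
    jm_h = 10^X[, "ljm_h"], jm_u = 10^X[, "ljm_u"],
    is_mystery = TRUE, stringsAsFactors = FALSE)
  attr(out, "truth_category") <- category
  out
}
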