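#' Assemble the biomechanical parameter matrix from a trait table
#'
#' Applies the pipeline's default transform: J/M is log10-transformed (it
#' spans orders of magnitude), CA/TA is kept on its natural 0-1 scale;
#' optionally all four columns are standardised.
#'
#' @param traits trait table (see [make_dataset()]): needs `ca_ta_h`,
#'   `ca_ta_u`, `jm_h`, `jm_u` and taxon rownames or a `taxon` column.
#' @param log_jm log10-transform the J/M columns?
#' @param standardise scale all columns to zero mean / unit SD?
#' @return numeric matrix taxa x 4 (`ca_ta_h`, `ca_ta_u`, `jm_h`, `jm_u`).
#' @export
trait_matrix <- function(traits, log_jm = TRUE, standardise = FALSE) {
  rn <- if (!is.null(traits$taxon)) traits$taxon else rownames(traits)
  X <- as.matrix(traits[, c("ca_ta_h", "ca_ta_u", "jm_h", "jm_u")])
  rownames(X) <- rn
  if (anyNA(X)) stop("missing biomechanical parameter values")
  if (log_jm) X[, c("jm_h", "jm_u")] <- log10(X[, c("jm_h", "jm_u")])
  if (standardise) X <- scale(X)
  X
}

#' Run the full locomotor-inference pipeline
#'
#' Executes the analysis chain on a trait table and chronogram: volancy by
#' PAM on the first three phylogenetic principal components (cross-checked
#' by k-means on the transformed raw parameters), Pagel's lambda screening
#' for the appropriateness of plain LDA, linear discriminant classification
#' of flight modes under one or both labelling schemes with mystery-taxon
#' assignment, simulation-based phylogenetic ANCOVA of each parameter
#' against locomotor class with body mass as covariate, and one-way MANOVA.
#' Mystery taxa are excluded from every fit and projected or classified
#' afterwards.
#'
#' @param traits trait table as produced by [make_dataset()] (or read from
#'   CSV with the same columns).
#' @param tree chronogram covering all taxa ([ape::phylo] or a Newick
#'   path/string).
#' @param schemes which labelling schemes to classify under.
#' @param seed integer master seed (k-means restarts and ANCOVA
#'   simulations derive their seeds from it).
#' @param n_sims Brownian-motion simulations per ANCOVA.
#' @param log_jm,standardise transform options, see [trait_matrix()].
#' @param n_pcs number of leading pPC scores passed to PAM.
#' @param alpha significance level of the lambda screening.
#' @param ca_ta_threshold reference CA/TA volancy threshold reported in the
#'   summary.
#' @param run_ancova set `FALSE` to skip the simulation-heavy ANCOVA stage.
#' @param out_dir optional directory: writes scores, confusion matrices and
#'   a JSON run report.
#' @return List of class `wingbeam_report`; see the `summary` element for
#'   the headline numbers.
#' @export
run_pipeline <- function(traits, tree, schemes = c("close", "viscor"),
                         seed = 1, n_sims = 1000,
                         log_jm = TRUE, standardise = FALSE, n_pcs = 3,
                         alpha = 0.05, ca_ta_threshold = 0.60,
                         run_ancova = TRUE, out_dir = NULL) {
  schemes <- match.arg(schemes, c("close", "viscor"), several.ok = TRUE)
  if (is.character(tree)) tree <- read_chronogram(tree)
  validate_chronogram(tree)
  if (!all(traits$taxon %in% tree$tip.label))
    stop("config error: trait table contains taxa absent from the tree")
  seed <- as.integer(seed)

  X <- trait_matrix(traits, log_jm = log_jm, standardise = standardise)
  train <- traits$taxon[!traits$is_mystery]
  mystery <- traits$taxon[traits$is_mystery]
  volant <- stats::setNames(as.logical(traits$volant), traits$taxon)[train]

  # --- volancy -------------------------------------------------------------
  pca <- phyl_pca(X[train, , drop = FALSE], tree, mode = "cor")
  sc_train <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  sc_all <- rbind(sc_train,
                  if (length(mystery))
                    ppca_project(pca, X[mystery, , drop = FALSE])[, seq_len(n_pcs), drop = FALSE])
  pam <- pam_cluster(sc_all, k = 2)
  # k-means runs on standardised parameters: CA/TA and log10 J/M live on
  # incommensurable scales, and squared-Euclidean inertia would otherwise
  # be dominated by the widest-ranged variable
  km <- kmeans_cluster(scale(X), k = 2, seed = seed + 1L)
  vol_pam <- volancy_success(pam$assignments, volant)
  vol_km <- volancy_success(km$assignments[rownames(sc_all)], volant)
  partitions_identical <- identical(
    unname(vol_pam$cluster_map[as.character(pam$assignments[train])]),
    unname(vol_km$cluster_map[as.character(km$assignments[train])]))

  ca_ta_avg <- rowMeans(X[train, c("ca_ta_h", "ca_ta_u")])
  threshold_ok <- (ca_ta_avg < ca_ta_threshold) == volant

  # --- lambda screening and discriminant classification --------------------
  screen <- screen_phylogenetic_signal(X[train, , drop = FALSE], tree,
                                       alpha = alpha)
  X_da <- if (screen$recommendation == "lambda-DA") screen$whitened
          else X[train, , drop = FALSE]
  lda <- lapply(stats::setNames(schemes, schemes), function(s) {
    labels <- traits[[paste0("scheme_", s)]][match(train, traits$taxon)]
    fit <- lda_fit(X_da, labels)
    cls <- if (length(mystery))
      lda_classify(fit, X[mystery, , drop = FALSE]) else NULL
    list(fit = fit, mystery = cls)
  })

  # --- phylogenetic ANCOVA per parameter -----------------------------------
  ancova <- NULL
  if (run_ancova) {
    grp <- stats::setNames(
      traits[[paste0("scheme_", schemes[1])]][match(train, traits$taxon)],
      train)
    # singleton locomotor categories (e.g. one pterosaur per category) carry
    # no within-group information; their taxa are set aside for this stage
    keep <- train[grp[train] %in% names(which(table(grp) >= 2L))]
    lmass <- stats::setNames(log10(traits$mass_g[match(keep, traits$taxon)]),
                             keep)
    ancova <- lapply(stats::setNames(colnames(X), colnames(X)), function(v)
      phylo_ancova(stats::setNames(X[keep, v], keep), grp[keep], lmass, tree,
                   n_sims = n_sims,
                   seed = seed + 10L + match(v, colnames(X))))
  }

  # --- MANOVA ---------------------------------------------------------------
  man <- lapply(stats::setNames(schemes, schemes), function(s)
    manova_groups(X[train, , drop = FALSE],
                  traits[[paste0("scheme_", s)]][match(train, traits$taxon)],
                  min_n = 3L))

  report <- structure(list(
    settings = list(schemes = schemes, seed = seed, n_sims = n_sims,
                    log_jm = log_jm, standardise = standardise,
                    n_pcs = n_pcs, alpha = alpha,
                    ca_ta_threshold = ca_ta_threshold),
    ppca = pca, pam = pam, kmeans = km,
    volancy = list(pam = vol_pam, kmeans = vol_km,
                   partitions_identical = partitions_identical),
    ca_ta_separation = list(fraction_correct = mean(threshold_ok),
                            crossers = names(threshold_ok)[!threshold_ok]),
    screen = screen, lda = lda, ancova = ancova, manova = man,
    summary = list(
      volancy_success_pct = vol_pam$success_rate,
      volancy_misclassified = vol_pam$misclassified,
      partitions_identical = partitions_identical,
      ca_ta_separation_pct = 100 * mean(threshold_ok),
      lambda_recommendation = screen$recommendation,
      lda_percent_correct = vapply(lda, function(l) l$fit$percent_correct,
                                   numeric(1)),
      mystery_assignments = lapply(lda, function(l)
        if (is.null(l$mystery)) character(0) else l$mystery$assignments),
      ancova_p = if (is.null(ancova)) NULL
                 else vapply(ancova, `[[`, numeric(1), "p"),
      manova_p = vapply(man, `[[`, numeric(1), "p"))),
    class = "wingbeam_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.wingbeam_report <- function(x, ...) {
  s <- x$summary
  cat("wingbeam run\n")
  cat(sprintf("  volancy (PAM on pPC1-%d): %.2f%% success; %d misclassified\n",
              x$settings$n_pcs, s$volancy_success_pct,
              length(s$volancy_misclassified)))
  cat(sprintf("  PAM and k-means partitions identical: %s\n",
              s$partitions_identical))
  cat(sprintf("  CA/TA %.2f threshold separates %.1f%% of training taxa\n",
              x$settings$ca_ta_threshold, s$ca_ta_separation_pct))
  cat(sprintf("  lambda screening: %s\n", s$lambda_recommendation))
  for (s2 in names(s$lda_percent_correct))
    cat(sprintf("  LDA (%s): %.2f%% correct; mystery -> %s\n", s2,
                s$lda_percent_correct[[s2]],
                paste(unique(s$mystery_assignments[[s2]]), collapse = ", ")))
  if (!is.null(s$ancova_p))
    cat("  ANCOVA empirical p:",
        paste(sprintf("%s=%.3g", names(s$ancova_p), s$ancova_p),
              collapse = ", "), "\n")
  invisible(x)
}

# CSV + JSON outputs of a pipeline run.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$ppca$scores,
                   file.path(out_dir, "ppca_scores.csv"))
  utils::write.csv(data.frame(taxon = names(report$pam$assignments),
                              pam = report$pam$assignments,
                              kmeans = report$kmeans$assignments[
                                names(report$pam$assignments)]),
                   file.path(out_dir, "volancy_clusters.csv"),
                   row.names = FALSE)
  for (s in names(report$lda))
    utils::write.csv(as.data.frame.matrix(report$lda[[s]]$fit$confusion),
                     file.path(out_dir, sprintf("lda_confusion_%s.csv", s)))
  json <- report$summary
  json$settings <- report$settings
  json$lambda <- as.list(report$screen$lambda)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(out_dir)
}
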