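#!/usr/bin/env Rscript
# Parameter-locomotion association under phylogeny: simulation-based
# phylogenetic ANCOVA of each biomechanical parameter against locomotor
# class with log body mass as covariate, plus a type-I calibration of the
# Brownian-motion null.

library(wingbeam)

stopifnot(file.exists("results/synthetic/traits.csv"))
traits <- read.csv("results/synthetic/traits.csv")
tree <- read_chronogram("results/synthetic/chronogram.nwk")
out <- "results"

rep <- run_pipeline(traits, tree, schemes = "close", seed = 1,
                    n_sims = 10000, run_ancova = TRUE)

tab <- do.call(rbind, lapply(names(rep$ancova), function(v) {
  a <- rep$ancova[[v]]
  data.frame(parameter = v, F_obs = a$F_obs, p_empirical = a$p,
             p_classical = a$p_classical, n_sims = a$n_sims)
}))
write.csv(tab, file.path(out, "phylo_ancova.csv"), row.names = FALSE)
cat("phylogenetic ANCOVA (10000 BM simulations per parameter):\n")
print(tab, row.names = FALSE, digits = 4)
cat("all four parameters associate with locomotor class beyond mass:",
    all(tab$p_empirical < 0.05), "\n")

# type-I calibration of the simulation null on a balanced chronogram
tr <- ape::compute.brlen(ape::stree(64, "balanced"))
set.seed(1)
grp <- setNames(rep(letters[1:4], each = 16), tr$tip.label)
cv <- setNames(rnorm(64), tr$tip.label)
pvals <- sapply(1:200, function(r) {
  y <- simulate_bm(tr, 1, 0, 1, seed = 50000 + r)
  phylo_ancova(y[1, ], grp, cv, tr, n_sims = 1000, seed = r)$p
})
cat(sprintf("type-I error at alpha = 0.05 under the BM null: %.3f (200 x 1000 sims)\n",
            mean(pvals < 0.05)))
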