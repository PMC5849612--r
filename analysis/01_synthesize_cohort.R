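#!/usr/bin/env Rscript
# Generate the synthetic archosaur cohort every later stage consumes:
# 67 training taxa over 13 locomotor categories plus 3 unlabeled
# burst-like mystery specimens, with a birth-death chronogram scaled to
# 250 MY and Brownian-motion structure in the residuals.

library(wingbeam)

seed <- 1L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- dataset_spec()
ds <- make_dataset(spec, seed = seed)

write.csv(ds$traits, file.path(out, "traits.csv"), row.names = FALSE)
write_chronogram(ds$tree, file.path(out, "chronogram.nwk"))
write.csv(data.frame(taxon = names(ds$truth$category),
                     category = ds$truth$category),
          file.path(out, "true_categories.csv"), row.names = FALSE)

tr <- ds$traits[!ds$traits$is_mystery, ]
cat(sprintf("cohort: %d training taxa + %d mystery, %d categories\n",
            nrow(tr), sum(ds$traits$is_mystery),
            length(unique(ds$truth$category))))
cat(sprintf("body mass span: %.0f g - %.0f g (%.1f orders of magnitude)\n",
            min(tr$mass_g), max(tr$mass_g),
            log10(max(tr$mass_g) / min(tr$mass_g))))
avg <- (tr$ca_ta_h + tr$ca_ta_u) / 2
cat(sprintf("species-average CA/TA: volant %.2f-%.2f, non-volant %.2f-%.2f\n",
            min(avg[tr$volant]), max(avg[tr$volant]),
            min(avg[!tr$volant]), max(avg[!tr$volant])))
cat("wrote traits.csv, chronogram.nwk, true_categories.csv to", out, "\n")
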