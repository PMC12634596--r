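#!/usr/bin/env Rscript
# Statistics: assemble the (participant, trial, pair, layer) observation
# table of layer-averaged Fisher-normalized coherence I_Z for synergistic
# and non-synergistic muscle pairs, and fit, per layer and per frequency
# bin, a linear mixed model with direction dummies, repetition and pair
# type as fixed effects and a participant random intercept. The pair-type
# Wald p-values are the study's headline comparison.
#
# Reads results/synergies.rds, results/cohsets.rds, results/layers.rds.

suppressPackageStartupMessages(library(imcoh))

dataset <- readRDS("results/dataset.rds")
syn <- readRDS("results/synergies.rds")
cohsets <- readRDS("results/cohsets.rds")
layers <- readRDS("results/layers.rds")
k <- layers$selection$k

obs <- do.call(rbind, lapply(seq_along(cohsets), function(p) {
  lb <- layer_bounds(layers$models[[p]][[k]])
  assemble_observations(syn[[p]]$classification, cohsets[[p]], lb)
}))
write.csv(obs, "results/observations.csv", row.names = FALSE)
cat(sprintf("observation table: %d rows (%s)\n", nrow(obs),
            paste(names(table(obs$pair_type)), table(obs$pair_type),
                  sep = "=", collapse = ", ")))

res <- per_layer_lmm(obs)
write.csv(res, "results/lmm_per_layer.csv", row.names = FALSE)
cat("per-layer mixed model (pair-type effect, synergistic - non-synergistic):\n")
print(res[, c("layer", "estimate", "se", "statistic", "p")], row.names = FALSE)

bin_obs <- do.call(rbind, lapply(seq_along(cohsets), function(p) {
  assemble_bin_observations(syn[[p]]$classification, cohsets[[p]])
}))
bin_res <- per_bin_analysis(bin_obs)
write.csv(bin_res, "results/lmm_per_bin.csv", row.names = FALSE)
cat("per-bin significant pair-type effects at:",
    paste(round(bin_res$bin_hz[bin_res$significant], 1), collapse = ", "),
    "Hz\n")

counts <- do.call(rbind, lapply(seq_along(syn), function(p) {
  tab <- table(syn[[p]]$classification$label)
  data.frame(participant = p,
             synergistic = as.integer(tab["synergistic"]),
             non_synergistic = as.integer(tab["non_synergistic"]))
}))
jsonlite::write_json(counts, "results/pair_counts.json", digits = NA)
cat("Wrote results/lmm_per_layer.csv, results/lmm_per_bin.csv\n")
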