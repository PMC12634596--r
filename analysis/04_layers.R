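#!/usr/bin/env Rscript
# Frequency layers: concatenate each participant's thresholded coherence
# spectra into a 15 x (trials * pairs) matrix, decompose by NMF for
# k = 1..15, select the layer count at the first interior local minimum of
# the across-participant SD of the aligned coherence patterns, and derive
# subject-specific layer bounds (bins assigned to the pattern with maximal
# weight; bounds reported as bin-edge frequencies tiling 1-60 Hz).
#
# Reads results/cohsets.rds; writes the selection curve, per-participant
# patterns and the layer-bound table.

suppressPackageStartupMessages(library(imcoh))

dataset <- readRDS("results/dataset.rds")
cohsets <- readRDS("results/cohsets.rds")
set.seed(dataset$config$seed + 3000L)

mats <- lapply(cohsets, build_coherence_matrix)
kmax <- length(mats[[1]]$bin_centers)
models <- lapply(mats, function(m) {
  lapply(seq_len(kmax), function(k) decompose_layers(m, k, restarts = 10))
})
sel <- select_num_layers(models)
cat("aggregate SD curve over k:\n")
print(round(setNames(sel$curve, seq_len(kmax)), 4))
cat(sprintf("selected number of layers: %d\n", sel$k))

bound_rows <- list()
for (p in seq_along(models)) {
  lb <- layer_bounds(models[[p]][[sel$k]])
  b <- lb$bounds
  bound_rows[[p]] <- data.frame(participant = p, layer = b$layer,
                                f1_hz = b$f1, f2_hz = b$f2)
  write.csv(models[[p]][[sel$k]]$W, sprintf("results/layer_W_p%02d.csv", p),
            row.names = FALSE)
}
bounds <- do.call(rbind, bound_rows)
write.csv(bounds, "results/layer_bounds.csv", row.names = FALSE)
write.csv(data.frame(k = seq_len(kmax), aggregate_sd = sel$curve),
          "results/layer_selection_curve.csv", row.names = FALSE)

agg <- aggregate(cbind(f1_hz, f2_hz) ~ layer, bounds, function(x) {
  sprintf("%.1f (%.1f)", mean(x), sd(x))
})
cat("layer bounds, mean (SD) across participants [Hz]:\n")
print(agg, row.names = FALSE)
saveRDS(list(models = models, selection = sel), "results/layers.rds")
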