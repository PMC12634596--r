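#!/usr/bin/env Rscript
# Muscle-synergy extraction: condition each trial (rectify, 5 Hz low-pass,
# 100 Hz resample, rest-baseline subtraction, MVC normalization, hold-phase
# average), factorize the activation matrix by NMF for every candidate rank,
# and select the number of synergies by the three criteria (R2 > 0.9; linear
# tail fit MSE < 1e-4; preferred-direction uniformity on mismatch).
#
# Reads results/dataset.rds; writes per-participant weight/coefficient
# tables, the R2 curves and the muscle-pair classification.

suppressPackageStartupMessages(library(imcoh))

dataset <- readRDS("results/dataset.rds")
set.seed(dataset$config$seed + 1000L)

out <- list()
for (p in dataset$participants) {
  am <- activation_matrix(p$trials, p$mvc)
  curve <- synergy_r2_curve(am$A, restarts = 10)
  dirs <- as.matrix(am$meta[, c("dx", "dy", "dz")])
  sel <- select_num_synergies(
    curve$r2, function(n) preferred_directions(curve$models[[n]], dirs)
  )
  model <- curve$models[[sel$selected]]
  cls <- classify_pairs(normalize_weights(model$W))
  # recovery against the generative weights
  mc <- match_columns(model$W[, seq_len(min(ncol(model$W), dataset$config$n_synergies)), drop = FALSE],
                      p$ground_truth$W_true[, seq_len(min(ncol(model$W), dataset$config$n_synergies)), drop = FALSE])
  cat(sprintf(
    "participant %d: N = %d (R2 %.3f; criteria i/ii: %s/%s), %d synergistic / %d non-synergistic pairs, W similarity %.2f\n",
    p$id, sel$selected, model$r2, sel$n_r2, sel$n_slope,
    sum(cls$label == "synergistic"), sum(cls$label == "non_synergistic"),
    mean(mc$similarity)
  ))
  write.csv(model$W, sprintf("results/synergy_W_p%02d.csv", p$id), row.names = FALSE)
  write.csv(data.frame(n = curve$n_range, r2 = curve$r2),
            sprintf("results/synergy_r2_p%02d.csv", p$id), row.names = FALSE)
  write.csv(cls, sprintf("results/pairs_p%02d.csv", p$id), row.names = FALSE)
  out[[p$id]] <- list(model = model, selection = sel, classification = cls)
}
saveRDS(out, "results/synergies.rds")
cat("Wrote results/synergies.rds\n")
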