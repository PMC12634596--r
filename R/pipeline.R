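#' Run the full synergy--coherence--layers--statistics pipeline
#'
#' Convenience driver over a simulated dataset: per participant it conditions
#' the EMG, extracts muscle synergies (at a fixed rank or via the
#' three-criterion rule), classifies muscle pairs, computes
#' surrogate-thresholded coherence spectra, decomposes them into frequency
#' layers (fixed k or across-participant selection), derives layer bounds,
#' and assembles the observation table for the per-layer mixed model.
#'
#' @param dataset A `sim_dataset` from [generate_dataset()].
#' @param n_synergies Fixed synergy rank; `NULL` selects per participant by
#'   the three-criterion rule.
#' @param k_layers Fixed layer count; `NULL` selects across participants by
#'   the stability criterion (requires >= 2 participants).
#' @param n_surrogates,quantile Surrogate-test parameters.
#' @param restarts NMF restarts for both factorizations.
#' @param fit_lmm Fit the per-layer mixed model (needs >= 2 participants).
#' @param verbose Print progress.
#' @return List with per-participant `synergies`, `classifications`,
#'   `cohsets`, `layer_models`, `bounds`, plus `layer_selection` (when
#'   selected), `observations`, and `lmm` (per-layer results when fitted).
#' @export
run_pipeline <- function(dataset, n_synergies = NULL, k_layers = NULL,
                         n_surrogates = 100, quantile = 0.95, restarts = 10,
                         fit_lmm = TRUE, verbose = FALSE) {
  parts <- dataset$participants
  np <- length(parts)
  synergies <- vector("list", np)
  classifications <- vector("list", np)
  cohsets <- vector("list", np)
  say <- function(...) if (verbose) message(sprintf(...))

  for (p in seq_len(np)) {
    say("participant %d/%d: conditioning + synergies", p, np)
    am <- activation_matrix(parts[[p]]$trials, parts[[p]]$mvc)
    if (is.null(n_synergies)) {
      curve <- synergy_r2_curve(am$A, restarts = restarts)
      dirs <- as.matrix(am$meta[, c("dx", "dy", "dz")])
      sel <- select_num_synergies(
        curve$r2,
        preferred_dirs = function(n) preferred_directions(curve$models[[n]], dirs)
      )
      model <- curve$models[[sel$selected]]
    } else {
      model <- extract_synergies(am$A, n_synergies, restarts = restarts)
    }
    synergies[[p]] <- model
    classifications[[p]] <- classify_pairs(normalize_weights(model$W))
    say("participant %d/%d: coherence (%d trials)", p, np,
        length(parts[[p]]$trials))
    cohsets[[p]] <- coherence_participant(parts[[p]]$trials,
                                          n_surrogates = n_surrogates,
                                          quantile = quantile)
  }

  say("frequency layers")
  mats <- lapply(cohsets, build_coherence_matrix)
  selection <- NULL
  if (is.null(k_layers)) {
    kmax <- length(mats[[1]]$bin_centers)
    models_by_p <- lapply(mats, function(m) {
      lapply(seq_len(kmax), function(k) decompose_layers(m, k, restarts = restarts))
    })
    selection <- select_num_layers(models_by_p)
    k_layers <- selection$k
    layer_models <- lapply(models_by_p, `[[`, k_layers)
  } else {
    layer_models <- lapply(mats, decompose_layers, k = k_layers,
                           restarts = restarts)
  }
  bounds <- lapply(layer_models, layer_bounds)

  obs <- do.call(rbind, lapply(seq_len(np), function(p) {
    assemble_observations(classifications[[p]], cohsets[[p]], bounds[[p]])
  }))

  lmm <- NULL
  if (fit_lmm && !is.null(obs) && length(unique(obs$participant)) >= 2 &&
      length(unique(obs$pair_type)) >= 2) {
    say("mixed models")
    lmm <- per_layer_lmm(obs)
  }

  list(synergies = synergies, classifications = classifications,
       cohsets = cohsets, layer_models = layer_models, bounds = bounds,
       layer_selection = selection, k_layers = k_layers,
       observations = obs, lmm = lmm)
}
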