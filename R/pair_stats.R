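#' Normalize synergy weights across synergies per muscle
#'
#' Divides each muscle's row of the weight matrix by its Euclidean norm so
#' that the squared sum of the muscle's contributions to all synergies is 1.
#' Under this normalization a muscle can exceed the 0.75 threshold in at most
#' one synergy (since 2 * 0.75^2 > 1).
#'
#' @param W Nonnegative muscle-weight matrix (muscles x synergies).
#' @return Matrix of the same shape with unit-norm rows.
#' @export
normalize_weights <- function(W) {
  if (any(W < 0)) stop("weights must be nonnegative")
  nrm <- sqrt(rowSums(W^2))
  bad <- which(nrm == 0)
  if (length(bad)) {
    stop(sprintf("all-zero weight row for muscle(s): %s",
                 paste(bad, collapse = ", ")))
  }
  W / nrm
}

#' Classify muscle pairs as synergistic or non-synergistic
#'
#' A pair is synergistic when both muscles have normalized weight above `hi`
#' in one common synergy; non-synergistic when in some synergy one muscle is
#' above `hi` and the other below `lo`; every other pair is excluded (e.g.
#' one muscle above `hi` while the other falls between `lo` and `hi`, or
#' neither muscle above `hi`).
#'
#' @param weights Normalized weight matrix from [normalize_weights()].
#' @param hi,lo Weight thresholds (defaults 0.75 and 0.25).
#' @return Data frame with `i`, `j` (`i < j`), `label` (factor: synergistic /
#'   non_synergistic / excluded), `synergy` (supporting synergy index, NA for
#'   excluded).
#' @export
classify_pairs <- function(weights, hi = 0.75, lo = 0.25) {
  nm <- nrow(weights)
  ns <- ncol(weights)
  idx <- which(upper.tri(matrix(0, nm, nm)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  label <- character(nrow(idx))
  synergy <- rep(NA_integer_, nrow(idx))
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1]; j <- idx[p, 2]
    lab <- "excluded"; syn <- NA_integer_
    for (s in seq_len(ns)) {
      wi <- weights[i, s]; wj <- weights[j, s]
      if (wi > hi && wj > hi) { lab <- "synergistic"; syn <- s; break }
      if ((wi > hi && wj < lo) || (wj > hi && wi < lo)) {
        lab <- "non_synergistic"; syn <- s
        # keep scanning: a synergistic match elsewhere would override, but the
        # row normalization makes that impossible when hi >= sqrt(1/2)
      }
    }
    label[p] <- lab; synergy[p] <- syn
  }
  data.frame(i = idx[, 1], j = idx[, 2],
             label = factor(label, levels = c("synergistic", "non_synergistic",
                                              "excluded")),
             synergy = synergy)
}

#' Assemble the per-layer observation table for the mixed model
#'
#' One row per (trial, pair, layer) holding the layer-averaged
#' Fisher-normalized coherence `I_Z`, for pairs classified synergistic or
#' non-synergistic. A pair enters only when it shows significant coherence
#' in at least one frequency bin of at least one trial, so silent pairs do
#' not mask the effects; within included pairs, only trials in which both
#' muscles were recruited contribute rows (conditioning rows on per-trial
#' significance instead would bias noise-level spectra upward).
#' Excluded-label pairs are dropped.
#'
#' @param classification Data frame from [classify_pairs()] for the
#'   participant.
#' @param cohset The participant's `coherence_set`.
#' @param lb The participant's `layer_bounds`.
#' @return Data frame with `participant`, `trial_id`, `direction_id`,
#'   `repetition`, `i`, `j`, `pair_type`, `layer`, `iz`.
#' @export
assemble_observations <- function(classification, cohset, lb) {
  if (is.null(lb)) stop("layer bounds missing for participant")
  keep_lab <- classification$label != "excluded"
  cls <- classification[keep_lab, , drop = FALSE]
  if (nrow(cls) == 0) return(NULL)
  pair_key <- paste(cohset$pairs$i, cohset$pairs$j)
  cls_idx <- match(paste(cls$i, cls$j), pair_key)
  if (anyNA(cls_idx)) stop("classified pairs not found in the coherence set")
  b <- lb$bounds
  nt <- dim(cohset$Z)[3]
  # pair-level inclusion: significant somewhere in at least one trial
  pair_sig <- apply(cohset$sig[, cls_idx, , drop = FALSE], 2, any)
  out <- vector("list", nt)
  for (t in seq_len(nt)) {
    Zt <- cohset$Z[, cls_idx, t, drop = FALSE]
    dim(Zt) <- dim(Zt)[1:2]
    has_sig <- pair_sig & cohset$co_active[cls_idx, t]
    if (!any(has_sig)) next
    sel <- which(has_sig)
    iz <- sapply(seq_len(nrow(b)), function(l) {
      colMeans(Zt[b$first_bin[l]:b$last_bin[l], sel, drop = FALSE])
    })
    iz <- matrix(iz, nrow = length(sel))
    out[[t]] <- data.frame(
      participant = cohset$participant_id,
      trial_id = cohset$trials$trial_id[t],
      direction_id = cohset$trials$direction_id[t],
      repetition = cohset$trials$repetition[t],
      i = rep(cls$i[sel], times = nrow(b)),
      j = rep(cls$j[sel], times = nrow(b)),
      pair_type = rep(as.character(cls$label[sel]), times = nrow(b)),
      layer = rep(seq_len(nrow(b)), each = length(sel)),
      iz = as.vector(iz)
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Per-bin observation table
#'
#' Like [assemble_observations()] but at single-bin resolution: one row per
#' (trial, pair, bin) with the thresholded Z value, under the same pair-level
#' inclusion and co-activity rules.
#'
#' @inheritParams assemble_observations
#' @return Data frame with `participant`, `trial_id`, `direction_id`,
#'   `repetition`, `i`, `j`, `pair_type`, `bin`, `bin_hz`, `z`.
#' @export
assemble_bin_observations <- function(classification, cohset) {
  keep_lab <- classification$label != "excluded"
  cls <- classification[keep_lab, , drop = FALSE]
  if (nrow(cls) == 0) return(NULL)
  pair_key <- paste(cohset$pairs$i, cohset$pairs$j)
  cls_idx <- match(paste(cls$i, cls$j), pair_key)
  nb <- length(cohset$bin_centers)
  nt <- dim(cohset$Z)[3]
  pair_sig <- apply(cohset$sig[, cls_idx, , drop = FALSE], 2, any)
  out <- vector("list", nt)
  for (t in seq_len(nt)) {
    Zt <- cohset$Z[, cls_idx, t, drop = FALSE]
    dim(Zt) <- dim(Zt)[1:2]
    has_sig <- pair_sig & cohset$co_active[cls_idx, t]
    if (!any(has_sig)) next
    sel <- which(has_sig)
    out[[t]] <- data.frame(
      participant = cohset$participant_id,
      trial_id = cohset$trials$trial_id[t],
      direction_id = cohset$trials$direction_id[t],
      repetition = cohset$trials$repetition[t],
      i = rep(cls$i[sel], each = nb),
      j = rep(cls$j[sel], each = nb),
      pair_type = rep(as.character(cls$label[sel]), each = nb),
      bin = rep(seq_len(nb), times = length(sel)),
      bin_hz = rep(cohset$bin_centers, times = length(sel)),
      z = as.vector(Zt[, sel, drop = FALSE])
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Linear mixed model for the pair-type effect on coherence
#'
#' Fits `response ~ direction dummies + repetition + pair type + (1 |
#' participant)` by REML and reports a Wald test on the pair-type coefficient
#' (synergistic relative to non-synergistic). The response is `iz` (layer
#' observations) or `z` (bin observations).
#'
#' @param obs Observation data frame (one layer or one bin).
#' @param response Name of the response column.
#' @return One-row data frame: `estimate` (synergistic minus non-synergistic),
#'   `se`, `statistic`, `p`, `n_obs`, `n_participants`, `singular`.
#' @export
fit_pair_lmm <- function(obs, response = "iz") {
  if (length(unique(obs$participant)) < 2) {
    stop("the mixed model needs at least 2 participants")
  }
  if (length(unique(obs$pair_type)) < 2) {
    stop("both pair types (synergistic and non-synergistic) are required")
  }
  d <- obs
  d$y <- d[[response]]
  d$direction <- stats::relevel(factor(d$direction_id),
                                ref = as.character(min(d$direction_id)))
  d$pair_type <- factor(d$pair_type, levels = c("non_synergistic", "synergistic"))
  fit <- lme4::lmer(y ~ direction + repetition + pair_type + (1 | participant),
                    data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  cf <- summary(fit)$coefficients
  row <- cf["pair_typesynergistic", ]
  stat <- row["t value"]
  data.frame(
    estimate = unname(row["Estimate"]),
    se = unname(row["Std. Error"]),
    statistic = unname(stat),
    p = unname(2 * stats::pnorm(-abs(stat))),
    n_obs = nrow(d),
    n_participants = length(unique(d$participant)),
    singular = lme4::isSingular(fit)
  )
}

#' Per-layer mixed-model analysis
#'
#' @param obs Observation table from [assemble_observations()] (all layers,
#'   possibly several participants row-bound).
#' @return Data frame with one [fit_pair_lmm()] row per layer.
#' @export
per_layer_lmm <- function(obs) {
  layers <- sort(unique(obs$layer))
  out <- lapply(layers, function(l) {
    res <- fit_pair_lmm(obs[obs$layer == l, , drop = FALSE], response = "iz")
    cbind(layer = l, res)
  })
  do.call(rbind, out)
}

#' Per-bin mixed-model analysis
#'
#' One mixed model per frequency bin on the thresholded Z values; raw
#' p-values are reported without multiplicity correction.
#'
#' @param obs Bin-level observation table from [assemble_bin_observations()].
#' @param alpha Significance level for the per-bin flag.
#' @return Data frame with one row per bin: `bin`, `bin_hz`, model columns,
#'   `significant`.
#' @export
per_bin_analysis <- function(obs, alpha = 0.05) {
  bins <- sort(unique(obs$bin))
  out <- lapply(bins, function(b) {
    d <- obs[obs$bin == b, , drop = FALSE]
    res <- fit_pair_lmm(d, response = "z")
    cbind(bin = b, bin_hz = d$bin_hz[1], res)
  })
  res <- do.call(rbind, out)
  res$significant <- res$p < alpha
  res
}
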