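# Independent brute-force rule evaluator for pair classification, written as
# direct set logic over synergies (distinct from the package's scan).
brute_classify <- function(Wn, hi = 0.75, lo = 0.25) {
  nm <- nrow(Wn)
  out <- NULL
  for (i in seq_len(nm - 1)) {
    for (j in (i + 1):nm) {
      syn_both <- which(Wn[i, ] > hi & Wn[j, ] > hi)
      syn_split <- which((Wn[i, ] > hi & Wn[j, ] < lo) |
                         (Wn[j, ] > hi & Wn[i, ] < lo))
      lab <- if (length(syn_both)) "synergistic" else {
        if (length(syn_split)) "non_synergistic" else "excluded"
      }
      out <- rbind(out, data.frame(i = i, j = j, label = lab))
    }
  }
  out
}

test_that("weight normalization gives unit squared sums per muscle", {
  W <- rbind(c(3, 4), c(1, 0), c(2, 2))
  Wn <- normalize_weights(W)
  expect_equal(Wn[1, ], c(0.6, 0.8))
  expect_equal(Wn[2, ], c(1, 0))
  expect_equal(rowSums(Wn^2), rep(1, 3), tolerance = 1e-9)
  expect_error(normalize_weights(rbind(c(1, 1), c(0, 0))), "2")
  # at most one weight above 0.75 per muscle is implied by the normalization
  set.seed(61)
  Wr <- normalize_weights(matrix(runif(60), 10, 6))
  expect_true(all(rowSums(Wr > 0.75) <= 1))
})

test_that("classification follows the threshold rules", {
  # muscles: A, B share synergy 1; C is in synergy 2; D is ambiguous
  W <- rbind(A = c(0.9, 0.1), B = c(0.9, 0.2), C = c(0.1, 0.95),
             D = c(0.5, 0.5))
  Wn <- normalize_weights(W)
  cl <- classify_pairs(Wn)
  lab <- function(i, j) as.character(cl$label[cl$i == i & cl$j == j])
  expect_equal(lab(1, 2), "synergistic")
  expect_equal(lab(1, 3), "non_synergistic")
  expect_equal(lab(2, 3), "non_synergistic")
  expect_equal(lab(1, 4), "excluded")     # one high, other between 25 and 75
  expect_equal(lab(3, 4), "excluded")
})

test_that("a pair with one weight between thresholds is excluded", {
  W <- rbind(c(0.8, sqrt(1 - 0.64)), c(0.5, sqrt(0.75)))
  cl <- classify_pairs(W)
  expect_equal(as.character(cl$label[1]), "excluded")
})

test_that("classification matches the brute-force evaluator on random weights", {
  set.seed(62)
  for (rep in 1:10) {
    Wn <- normalize_weights(matrix(runif(24) + 0.01, 8, 3))
    a <- classify_pairs(Wn)
    b <- brute_classify(Wn)
    expect_equal(as.character(a$label), b$label)
  }
})

test_that("every pair receives exactly one label and the sets are disjoint", {
  set.seed(63)
  Wn <- normalize_weights(matrix(runif(60) + 0.01, 12, 5))
  cl <- classify_pairs(Wn)
  expect_equal(nrow(cl), choose(12, 2))
  expect_false(any(duplicated(cl[, c("i", "j")])))
  expect_true(all(cl$label %in% c("synergistic", "non_synergistic", "excluded")))
})

# -- observation assembly ----------------------------------------------------

fake_cohset <- function(Z, trials, pairs, pid = 1, co_active = NULL) {
  if (is.null(co_active)) co_active <- matrix(TRUE, dim(Z)[2], dim(Z)[3])
  structure(list(
    Z = Z, C = Z / (1 + Z), sig = Z > 0, co_active = co_active,
    pairs = pairs, trials = trials,
    bin_centers = (1:dim(Z)[1]) * 1000 / 256, Ns = 29, participant_id = pid
  ), class = "coherence_set")
}

fake_bounds <- function(first, last, bc = (1:15) * 1000 / 256) {
  n <- length(first)
  structure(list(
    bounds = data.frame(layer = seq_len(n), f1 = bc[first] - 2, f2 = bc[last] + 2,
                        first_bin = first, last_bin = last, component = seq_len(n)),
    assignment = rep(seq_len(n), times = last - first + 1), bin_centers = bc
  ), class = "layer_bounds")
}

test_that("observation rows follow trials x included pairs x layers", {
  set.seed(64)
  pairs <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3))
  trials <- data.frame(trial_id = 1:2, direction_id = c(1, 2), repetition = c(1, 1))
  Z <- array(0, dim = c(15, 3, 2))
  Z[3, 1, ] <- 5   # pair (1,2) significant in both trials
  cls <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                    label = factor(c("synergistic", "excluded", "non_synergistic"),
                                   levels = c("synergistic", "non_synergistic", "excluded")),
                    synergy = c(1, NA, 1))
  cs <- fake_cohset(Z, trials, pairs)
  lb <- fake_bounds(first = c(1, 4, 7, 10, 12, 14), last = c(3, 6, 9, 11, 13, 15))
  obs <- assemble_observations(cls, cs, lb)
  # 2 trials x 1 significant pair x 6 layers = 12 rows
  expect_equal(nrow(obs), 12)
  expect_true(all(obs$i == 1 & obs$j == 2))
  expect_equal(obs$iz[obs$layer == 1 & obs$trial_id == 1], 5 / 3)
  expect_equal(unique(obs$iz[obs$layer > 1]), 0)
  # all-zero pair absent entirely
  expect_false(any(obs$j == 3))
  expect_error(assemble_observations(cls, cs, NULL), "missing")
})

test_that("per-bin observations expand bins and keep Z values aligned", {
  pairs <- data.frame(i = 1, j = 2)
  trials <- data.frame(trial_id = 7, direction_id = 3, repetition = 2)
  Z <- array(0, dim = c(15, 1, 1))
  Z[c(2, 9), 1, 1] <- c(4, 8)
  cls <- data.frame(i = 1, j = 2,
                    label = factor("synergistic",
                                   levels = c("synergistic", "non_synergistic", "excluded")),
                    synergy = 1)
  obs <- assemble_bin_observations(cls, fake_cohset(Z, trials, pairs))
  expect_equal(nrow(obs), 15)
  expect_equal(obs$z[obs$bin == 2], 4)
  expect_equal(obs$z[obs$bin == 9], 8)
  expect_equal(sum(obs$z), 12)
})

# -- mixed model -------------------------------------------------------------

simulate_obs <- function(n_participants = 6, n_pairs = 24, effect = 0,
                         sd_resid = 1, sd_part = 0.5, n_directions = 4,
                         reps = 2) {
  rows <- list()
  for (p in seq_len(n_participants)) {
    u <- rnorm(1, sd = sd_part)
    for (d in seq_len(n_directions)) {
      for (r in seq_len(reps)) {
        type <- rep(c("synergistic", "non_synergistic"), length.out = n_pairs)
        iz <- u + 0.1 * d + 0.05 * r + effect * (type == "synergistic") +
          rnorm(n_pairs, sd = sd_resid)
        rows[[length(rows) + 1]] <- data.frame(
          participant = p, trial_id = (d - 1) * reps + r, direction_id = d,
          repetition = r, i = 1, j = 2, pair_type = type, layer = 1, iz = iz
        )
      }
    }
  }
  do.call(rbind, rows)
}

test_that("a large pair-type effect is recovered with a small p-value", {
  set.seed(65)
  obs <- simulate_obs(effect = 5, sd_resid = 1)
  res <- fit_pair_lmm(obs)
  expect_equal(res$estimate, 5, tolerance = 0.1 * 5)
  expect_lt(res$p, 0.01)
  expect_equal(res$n_participants, 6)
})

test_that("the null rejection rate is close to the nominal level", {
  set.seed(66)
  pvals <- replicate(300, {
    obs <- simulate_obs(n_participants = 4, n_pairs = 12, effect = 0,
                        n_directions = 2, reps = 2)
    fit_pair_lmm(obs)$p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
})

test_that("degenerate designs are rejected with informative errors", {
  set.seed(67)
  obs <- simulate_obs(n_participants = 1)
  expect_error(fit_pair_lmm(obs), "participants")
  obs2 <- simulate_obs()
  obs2$pair_type <- "synergistic"
  expect_error(fit_pair_lmm(obs2), "pair types")
})

test_that("per-bin analysis returns one model row per bin", {
  set.seed(68)
  obs <- simulate_obs(effect = 2)
  obs$bin <- 1
  obs$bin_hz <- 3.90625
  obs$z <- obs$iz
  res <- per_bin_analysis(obs)
  expect_equal(nrow(res), 1)
  expect_true(res$significant)
})
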