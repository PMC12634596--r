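# Build a coherence matrix whose columns occupy prescribed frequency bands.
# bands: list of bin-index vectors; each column draws one band.
banded_matrix <- function(bands, n_cols, nb = 15, noise = 0.02) {
  M <- matrix(abs(rnorm(nb * n_cols, sd = noise)), nb, n_cols)
  for (cc in seq_len(n_cols)) {
    b <- bands[[((cc - 1) %% length(bands)) + 1]]
    M[b, cc] <- M[b, cc] + runif(length(b), 5, 10)
  }
  M
}

bin_hz <- (1:15) * 1000 / 256

test_that("concatenation preserves shape, order and zero columns", {
  set.seed(51)
  cfg <- tiny_config(seed = 51, n_directions = 4)
  ds <- generate_dataset(cfg)
  cs <- coherence_participant(ds$participants[[1]]$trials[1:2],
                              n_surrogates = 20)
  cm <- build_coherence_matrix(cs)
  np <- nrow(cs$pairs)
  expect_equal(dim(cm$M), c(15, 2 * np))
  expect_equal(cm$cols$trial_id, rep(cs$trials$trial_id, each = np))
  # trial-major, pair-minor ordering
  expect_equal(cm$M[, np + 2], cs$Z[, 2, 2])
  expect_error(build_coherence_matrix(list()), "empty")
})

test_that("two-band columns separate into two one-band patterns", {
  set.seed(52)
  M <- banded_matrix(list(1:5, 9:14), 80)
  lm2 <- decompose_layers(M, 2, restarts = 5, bin_centers = bin_hz)
  for (k in 1:2) {
    col <- lm2$W[, k]
    band <- if (which.max(col) <= 5) 1:5 else 9:14
    expect_gt(sum(col[band]) / sum(col), 0.95)
  }
  # unit-maximum normalization
  expect_equal(apply(lm2$W, 2, max), c(1, 1))
})

test_that("a rank-1 matrix reconstructs exactly at one layer", {
  set.seed(53)
  M <- outer(c(0.1, 1, 5, 1, 0.1, rep(0.05, 10)), runif(40, 0.5, 2))
  lm1 <- decompose_layers(M, 1, restarts = 3, bin_centers = bin_hz)
  expect_gt(lm1$r2, 1 - 1e-6)
})

test_that("reconstruction error does not increase with more layers", {
  set.seed(54)
  M <- banded_matrix(list(1:4, 5:9, 10:15), 60)
  r2 <- sapply(c(1, 2, 3, 6, 15), function(k) {
    decompose_layers(M, k, restarts = 5, bin_centers = bin_hz)$r2
  })
  expect_true(all(diff(r2) > -1e-6))
})

test_that("the selection rule finds the deepest interior local minimum", {
  # synthetic curves injected through minimal fake layer models
  fake_models <- function(curves) {
    # curves: participants x k matrix of target SDs; realized by giving each
    # participant a pattern offset proportional to the desired SD
    np <- nrow(curves)
    lapply(seq_len(np), function(p) {
      lapply(seq_len(ncol(curves)), function(k) {
        W <- matrix(0.5, 15, k)
        W[1, ] <- 0.5 + curves[p, k] * (p - (np + 1) / 2)
        structure(list(W = W, C = matrix(1, k, 2), k = k, r2 = 0.5,
                       bin_centers = bin_hz, participant_id = p),
                  class = "layer_model")
      })
    })
  }
  # target aggregate SD over k = 1..5 proportional to c(5, 3, 4, 2, 6):
  # interior local minima at k = 2 (value 3) and k = 4 (value 2)
  curves <- rbind(c(5, 3, 4, 2, 6), c(5, 3, 4, 2, 6)) * 0.01
  sel <- select_num_layers(fake_models(curves))
  expect_equal(sel$k, 4)  # the deeper of the two local minima
  expect_length(sel$curve, 5)
  expect_error(select_num_layers(fake_models(curves)[1]), "2 participants")
})

test_that("identical participants give a flat zero curve and a defined fallback", {
  set.seed(55)
  # exactly rank-2: two fixed one-band patterns under random column scales
  W0 <- cbind(c(runif(7, 5, 10), rep(0, 8)), c(rep(0, 7), runif(8, 5, 10)))
  M <- W0 %*% matrix(runif(2 * 40, 0.5, 2), 2, 40)
  per_k <- lapply(1:6, function(k) decompose_layers(M, k, restarts = 5,
                                                    bin_centers = bin_hz))
  sel <- select_num_layers(list(per_k, per_k))
  expect_true(all(sel$curve == 0))
  # smallest k attaining near-exact reconstruction
  expect_equal(sel$k, min(which(sapply(per_k, `[[`, "r2") >= 0.999)))
})

test_that("one-hot patterns produce bounds at the block edges", {
  W <- matrix(0, 15, 3)
  W[1:4, 1] <- 1; W[5:9, 2] <- 1; W[10:15, 3] <- 1
  model <- structure(list(W = W, C = matrix(1, 3, 2), k = 3, r2 = 1,
                          bin_centers = bin_hz, participant_id = 1),
                     class = "layer_model")
  lb <- layer_bounds(model)
  expect_equal(lb$bounds$first_bin, c(1, 5, 10))
  expect_equal(lb$bounds$last_bin, c(4, 9, 15))
  expect_equal(lb$bounds$f1[1], 1)
  expect_equal(lb$bounds$f2[3], 60)
  # interior edges at bin boundaries
  d <- 1000 / 256
  expect_equal(lb$bounds$f2[1], 4 * d + d / 2)
  expect_equal(lb$bounds$f1[2], 4 * d + d / 2)
})

test_that("a single layer spans the whole analyzed range", {
  model <- structure(list(W = matrix(runif(15), 15, 1), C = matrix(1, 1, 2),
                          k = 1, r2 = 1, bin_centers = bin_hz,
                          participant_id = 1),
                     class = "layer_model")
  lb <- layer_bounds(model)
  expect_equal(nrow(lb$bounds), 1)
  expect_equal(c(lb$bounds$f1, lb$bounds$f2), c(1, 60))
})

test_that("bounds always partition the analyzed range", {
  set.seed(56)
  for (rep in 1:5) {
    W <- matrix(runif(15 * 4), 15, 4)
    model <- structure(list(W = W, C = matrix(1, 4, 2), k = 4, r2 = 1,
                            bin_centers = bin_hz, participant_id = 1),
                       class = "layer_model")
    lb <- suppressWarnings(layer_bounds(model))
    b <- lb$bounds
    expect_equal(b$f1[1], 1)
    expect_equal(b$f2[nrow(b)], 60)
    if (nrow(b) > 1) {
      expect_equal(b$f1[-1], b$f2[-nrow(b)])   # contiguous, disjoint
    }
    expect_equal(sort(unique(unlist(Map(seq, b$first_bin, b$last_bin)))), 1:15)
  }
})

test_that("isolated outlier bins are reassigned to a neighboring layer", {
  W <- matrix(0, 15, 2)
  W[c(1:6, 10), 1] <- 1    # bin 10 is an island of layer 1
  W[c(7:9, 11:15), 2] <- 1
  model <- structure(list(W = W, C = matrix(1, 2, 2), k = 2, r2 = 1,
                          bin_centers = bin_hz, participant_id = 1),
                     class = "layer_model")
  lb <- layer_bounds(model)
  expect_equal(nrow(lb$bounds), 2)
  expect_equal(lb$assignment[10], 2)
})

test_that("layer-averaged Z follows its discretized integral", {
  bc <- bin_hz
  expect_equal(layer_average_iz(rep(3, 15), c(1, 60), bc), 3)
  expect_equal(layer_average_iz(rep(0, 15), c(10, 30), bc), 0)
  z <- seq(1, 15)  # linear in bin index: mean of included bins
  inside <- bc >= 10 & bc <= 30
  expect_equal(layer_average_iz(z, c(10, 30), bc), mean(z[inside]))
  expect_error(layer_average_iz(z, c(60.5, 61), bc), "no bin")
})
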