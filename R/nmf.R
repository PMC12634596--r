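#' Non-negative matrix factorization by multiplicative updates
#'
#' Lee--Seung multiplicative updates for the Frobenius objective
#' `||V - W H||_F^2`, with uniform-random nonnegative initialization, a
#' relative-objective stopping tolerance, and best-of-restarts selection by
#' explained variation. `R2 = 1 - SSE/SST`, where SSE is the squared model
#' residual and SST the squared residual with respect to the row-mean vector.
#'
#' Uses the caller's RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param V Nonnegative matrix (rows x cols).
#' @param k Factorization rank.
#' @param restarts Number of random restarts; the restart with the highest R2
#'   is retained.
#' @param max_iter Maximum multiplicative-update iterations per restart.
#' @param tol Relative change in the objective (checked every 10 iterations)
#'   below which a restart stops.
#' @return List with `W` (rows x k), `H` (k x cols), `r2`, `sse`, `sst`,
#'   `restart_log` (per-restart R2 values).
#' @export
nmf <- function(V, k, restarts = 10, max_iter = 1000, tol = 1e-6) {
  stopifnot(is.matrix(V), k >= 1, k <= min(dim(V)) || k <= max(dim(V)))
  if (any(V < 0)) stop("V must be nonnegative")
  sst <- sum((V - rowMeans(V))^2)
  if (sum(V^2) == 0) stop("V is all zero; SST undefined")
  if (sst == 0) sst <- .Machine$double.eps
  eps <- .Machine$double.eps
  best <- NULL
  log_r2 <- numeric(restarts)
  for (r in seq_len(restarts)) {
    W <- matrix(stats::runif(nrow(V) * k), nrow(V), k)
    H <- matrix(stats::runif(k * ncol(V)), k, ncol(V))
    obj_prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      if (it %% 10 == 0 || it == max_iter) {
        obj <- sum((V - W %*% H)^2)
        if (is.finite(obj_prev) && (obj_prev - obj) <= tol * obj_prev) break
        obj_prev <- obj
      }
    }
    sse <- sum((V - W %*% H)^2)
    r2 <- 1 - sse / sst
    log_r2[r] <- r2
    if (is.null(best) || r2 > best$r2) {
      best <- list(W = W, H = H, r2 = r2, sse = sse, sst = sst)
    }
  }
  best$restart_log <- log_r2
  best
}

#' Match columns of two matrices by maximal cosine similarity
#'
#' One-to-one assignment maximizing the total cosine similarity between
#' columns of `A` and columns of `B`; exhaustive over permutations for up to
#' 8 columns, greedy beyond. Used to compare recovered synergies or layers
#' against ground truth.
#'
#' @param A,B Matrices with the same number of columns.
#' @return List with `perm` (`B` column matched to each `A` column) and
#'   `similarity` (per-pair cosine similarities).
#' @export
match_columns <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  k <- ncol(A)
  cs <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      cs[i, j] <- sum(A[, i] * B[, j]) /
        (sqrt(sum(A[, i]^2)) * sqrt(sum(B[, j]^2)) + .Machine$double.eps)
    }
  }
  if (k <= 8) {
    perms <- permutations_of(k)
    scores <- vapply(perms, function(p) sum(cs[cbind(seq_len(k), p)]), numeric(1))
    perm <- perms[[which.max(scores)]]
  } else {
    perm <- integer(k)
    avail <- seq_len(k)
    for (i in order(-apply(cs, 1, max))) {
      j <- avail[which.max(cs[i, avail])]
      perm[i] <- j
      avail <- setdiff(avail, j)
    }
  }
  list(perm = perm, similarity = cs[cbind(seq_len(k), perm)])
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations_of(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
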