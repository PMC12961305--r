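#' Non-negative JIERP magnitude matrix
#'
#' Restricts a JIERP to the post-stimulus latencies (t >= 1 ms), z-scores
#' the absolute amplitudes across the valid bins at each latency, and
#' subtracts the global minimum of the resulting matrix so its minimum is
#' exactly zero. Subtracting a common value preserves every pairwise
#' difference, i.e. the relative modulation structure. Bins invalid in the
#' input are excluded as rows and recorded.
#'
#' @param jierp a `jierp`.
#' @return a `nonneg_matrix`: list with `M` (valid bins x latencies,
#'   min 0), `row_bins` (data.frame row/col of each retained bin),
#'   `excluded_bins`, `time_ms`, `shift` (the subtracted minimum), `grid`.
#' @export
magnitude_transform <- function(jierp) {
  stopifnot(inherits(jierp, "jierp"))
  post <- jierp$time_ms >= 1
  stopifnot(any(post))
  b <- jierp$grid$n_bins
  flat <- matrix(jierp$amplitude[, , post, drop = FALSE], b * b, sum(post))
  vf <- as.vector(jierp$valid)
  if (sum(vf) < 2) stop("need at least 2 valid bins")
  x <- abs(flat[vf, , drop = FALSE])
  mu <- colMeans(x)
  sdv <- sqrt(colSums(sweep(x, 2, mu)^2) / (nrow(x) - 1))
  z <- sweep(sweep(x, 2, mu), 2, ifelse(sdv == 0, 1, sdv), "/")
  z[, sdv == 0] <- 0
  shift <- min(z)
  idx <- which(matrix(vf, b, b), arr.ind = TRUE)
  excl <- which(!matrix(vf, b, b), arr.ind = TRUE)
  structure(list(M = z - shift,
                 row_bins = data.frame(row = idx[, 1], col = idx[, 2]),
                 excluded_bins = data.frame(row = excl[, 1],
                                            col = excl[, 2]),
                 time_ms = jierp$time_ms[post], shift = shift,
                 grid = jierp$grid),
            class = "nonneg_matrix")
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes `M ~ W H` (Frobenius objective) with the classical
#' multiplicative update rules, which never increase the reconstruction
#' error. Iteration stops when the relative error change drops below
#' `tol` or at `max_iter`. Deterministic given the seed (uniform random
#' initialization).
#'
#' @param M non-negative matrix (or `nonneg_matrix`).
#' @param rank factorization rank, `1 <= rank <= min(dim(M))`.
#' @param seed integer seed for the initialization.
#' @param max_iter,tol stopping rule (defaults 500, 1e-5).
#' @param mask optional logical matrix; when given, only `TRUE` entries
#'   contribute to the objective (weighted updates, used for
#'   cross-validation holdout).
#' @return a `nnmf_fit`: list with `W`, `H`, `rank`, `frobenius_error`,
#'   `error_trace`, `iterations`, `converged`, `seed`.
#' @export
nnmf_factorize <- function(M, rank, seed = 1L, max_iter = 500, tol = 1e-5,
                           mask = NULL) {
  row_bins <- NULL
  grid <- NULL
  if (inherits(M, "nonneg_matrix")) {
    row_bins <- M$row_bins
    grid <- M$grid
    M <- M$M
  }
  stopifnot(is.matrix(M), all(M >= 0), rank >= 1)
  if (rank > min(dim(M))) stop("rank exceeds matrix dimensions")
  eps <- 1e-12
  n <- nrow(M); m <- ncol(M)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(M)))
    Wt <- mask * 1
    V <- M * Wt
  }
  init <- withr::with_seed(seed, list(
    W = matrix(stats::runif(n * rank, 0.1, 1), n, rank) * sqrt(mean(M) / rank),
    H = matrix(stats::runif(rank * m, 0.1, 1), rank, m) * sqrt(mean(M) / rank)))
  W <- init$W; H <- init$H
  err <- function(W, H) {
    R <- M - W %*% H
    if (is.null(mask)) sqrt(sum(R^2)) else sqrt(sum(R[mask]^2))
  }
  trace <- numeric(max_iter + 1)
  trace[1] <- err(W, H)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    if (is.null(mask)) {
      H <- H * (crossprod(W, M)) / (crossprod(W) %*% H + eps)
      W <- W * (M %*% t(H)) / (W %*% tcrossprod(H) + eps)
    } else {
      WH <- (W %*% H) * Wt
      H <- H * (crossprod(W, V)) / (crossprod(W, WH) + eps)
      WH <- (W %*% H) * Wt
      W <- W * (V %*% t(H)) / (WH %*% t(H) + eps)
    }
    trace[it + 1] <- err(W, H)
    if (trace[it] - trace[it + 1] < tol * max(trace[it], eps)) {
      converged <- TRUE
      break
    }
  }
  structure(list(W = W, H = H, rank = rank,
                 frobenius_error = trace[it + 1],
                 error_trace = trace[1:(it + 1)],
                 iterations = it, converged = converged,
                 seed = as.integer(seed), stability_score = NA_real_,
                 row_bins = row_bins, grid = grid),
            class = "nnmf_fit")
}

#' Cross-validated rank selection (Wold-style entry holdout)
#'
#' For each candidate rank, repeatedly masks a random fraction of matrix
#' entries, fits the factorization on the observed entries only, and
#' scores the root-mean-square reconstruction error on the held-out
#' entries; fold errors are averaged. The selected rank minimizes the
#' mean held-out error, with a one-standard-error tie-break toward the
#' smaller rank. Holdout draws that fully mask a row or column are
#' redrawn (and counted).
#'
#' @param M non-negative matrix (or `nonneg_matrix`).
#' @param rank_range candidate ranks, default `2:10`.
#' @param holdout_fraction fraction of entries held out per fold
#'   (default 0.1).
#' @param n_folds folds per rank (default 5).
#' @param seed integer seed.
#' @param max_iter,tol convergence controls for the per-fold fits. The
#'   defaults are stricter than [nnmf_factorize()]'s because held-out
#'   scoring is only meaningful once each fold has converged; an
#'   under-converged low-rank fit inflates its held-out error and biases
#'   the selection upward.
#' @param ... passed to [nnmf_factorize()].
#' @return list with `best_rank`, `error_curve` (data.frame rank /
#'   mean_error / se_error), `n_redraws`.
#' @export
select_rank_cv <- function(M, rank_range = 2:10, holdout_fraction = 0.1,
                           n_folds = 5, seed = 1L, max_iter = 6000,
                           tol = 1e-8, ...) {
  if (inherits(M, "nonneg_matrix")) M <- M$M
  stopifnot(all(rank_range >= 1), max(rank_range) <= min(dim(M)))
  nm <- length(M)
  redraws <- 0L
  masks <- withr::with_seed(seed, lapply(seq_len(n_folds), function(f) {
    repeat {
      hold <- matrix(FALSE, nrow(M), ncol(M))
      hold[sample.int(nm, round(holdout_fraction * nm))] <- TRUE
      if (all(rowSums(!hold) > 0) && all(colSums(!hold) > 0)) return(hold)
      redraws <<- redraws + 1L
    }
  }))
  errs <- sapply(rank_range, function(r) {
    vapply(seq_len(n_folds), function(f) {
      hold <- masks[[f]]
      fit <- nnmf_factorize(M, rank = r, seed = seed + f, mask = !hold,
                            max_iter = max_iter, tol = tol, ...)
      R <- M - fit$W %*% fit$H
      sqrt(mean(R[hold]^2))
    }, numeric(1))
  })                                        # n_folds x n_ranks
  mean_err <- colMeans(errs)
  se_err <- apply(errs, 2, stats::sd) / sqrt(n_folds)
  best_i <- which.min(mean_err)
  # one-standard-error rule: smallest rank within one SE of the minimum
  ok <- mean_err <= mean_err[best_i] + se_err[best_i]
  best_rank <- rank_range[min(which(ok))]
  list(best_rank = best_rank,
       error_curve = data.frame(rank = rank_range, mean_error = mean_err,
                                se_error = se_err),
       n_redraws = redraws)
}

# exact min-cost assignment for small cost matrices via subset DP
assignment_min_cost <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), n <= 20)
  full <- bitwShiftL(1L, n) - 1L
  f <- rep(Inf, full + 1L)
  pick <- rep(NA_integer_, full + 1L)
  f[1L] <- 0
  for (S in 1:full) {
    row <- sum(bitwAnd(S, bitwShiftL(1L, 0:(n - 1))) > 0)  # popcount
    for (j in 0:(n - 1)) {
      bit <- bitwShiftL(1L, j)
      if (bitwAnd(S, bit) > 0) {
        v <- f[S - bit + 1L] + cost[row, j + 1L]
        if (v < f[S + 1L]) { f[S + 1L] <- v; pick[S + 1L] <- j + 1L }
      }
    }
  }
  # backtrack the column assigned to each row
  assign <- integer(n)
  S <- full
  for (row in n:1) {
    j <- pick[S + 1L]
    assign[row] <- j
    S <- S - bitwShiftL(1L, j - 1L)
  }
  list(cost = f[full + 1L], assignment = assign)
}

#' Matched cosine similarity between two factorizations
#'
#' Mean cosine similarity of the W columns of two fits after the optimal
#' one-to-one column matching, invariant to column order and to the
#' rescaling `c W, H / c`.
#'
#' @param fit_a,fit_b `nnmf_fit` objects of equal rank.
#' @return scalar in `[0, 1]` (columns are non-negative).
#' @export
factor_similarity <- function(fit_a, fit_b) {
  stopifnot(fit_a$rank == fit_b$rank)
  unit <- function(W) sweep(W, 2, pmax(sqrt(colSums(W^2)), 1e-300), "/")
  S <- crossprod(unit(fit_a$W), unit(fit_b$W))   # cosine similarity matrix
  res <- assignment_min_cost(-S)
  mean(S[cbind(seq_len(nrow(S)), res$assignment)])
}

#' Stability-selected NNMF
#'
#' Runs `n_reps` factorizations from independent random initializations,
#' scores every run by its mean matched-cosine similarity to all other
#' runs, and returns the medoid run — the factorization most commonly
#' visible across repetitions — with that mean similarity as its
#' stability score.
#'
#' @param M non-negative matrix (or `nonneg_matrix`).
#' @param rank factorization rank.
#' @param n_reps repetitions (default 100). With `n_reps = 1` the single
#'   fit is returned with an NA stability score.
#' @param seed integer seed (each repetition derives its own).
#' @param ... passed to [nnmf_factorize()].
#' @return a `nnmf_fit` with `stability_score` set.
#' @export
stable_factorize <- function(M, rank, n_reps = 100, seed = 1L, ...) {
  vals <- if (inherits(M, "nonneg_matrix")) M$M else M
  if (all(vals == 0)) stop("degenerate all-zero matrix")
  fits <- lapply(seq_len(n_reps), function(r)
    nnmf_factorize(M, rank = rank, seed = seed * 1000L + r, ...))
  if (n_reps == 1) return(fits[[1]])
  S <- matrix(1, n_reps, n_reps)
  for (i in seq_len(n_reps - 1)) for (j in (i + 1):n_reps) {
    S[i, j] <- S[j, i] <- factor_similarity(fits[[i]], fits[[j]])
  }
  mean_sim <- (rowSums(S) - 1) / (n_reps - 1)
  best <- which.max(mean_sim)
  fit <- fits[[best]]
  fit$stability_score <- mean_sim[best]
  fit
}
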