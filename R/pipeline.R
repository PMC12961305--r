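#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the reference
#' analysis: 1-45 Hz passband, -200..299 ms epochs, +/-80 uV rejection,
#' -200..-50 ms baseline, bin edges 0.5/1/2/4/8 s, 10 trials per bin,
#' alpha 0.05, 25 ms diagonal band, NNMF ranks 2-10 with 100 stability
#' repetitions, k-means over 3-7 clusters with 1000 restarts.
#'
#' @param ... overrides for any default.
#' @return a `pipeline_config` list with a `config_hash` stamp.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    filter_low = 1, filter_high = 45, two_stage = FALSE,
    epoch_window = c(-200, 299), baseline_window = c(-200, -50),
    reject_uv = 80,
    roi = NULL, select_window = c(25, 75), criterion = "max_positive",
    bin_edges = c(0.5, 1, 2, 4, 8), min_trials = 10,
    min_subject_fraction = 0.8,
    alpha = 0.05, band_halfwidth_ms = 25,
    rank_range = 2:10, nnmf_reps = 100, nnmf_max_iter = 500,
    nnmf_tol = 1e-5,
    k_range = 3:7, kmeans_restarts = 1000,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$config_hash <- rlang::hash(cfg[setdiff(names(cfg), "config_hash")])
  structure(cfg, class = "pipeline_config")
}

#' Run the full JIERP analysis on a set of recordings
#'
#' Per subject: preprocess, select the analysis electrode, build and
#' z-score the JIERP, transform to the magnitude matrix and run
#' stability-selected NNMF (rank chosen by cross-validation unless
#' `fixed_rank` is set). Across subjects: grand average, mass-univariate
#' t-tests with joint FDR, latency cross-correlation with off-diagonal
#' FDR, and k-means clustering of pooled meta-times. A provenance record
#' (parameters, seeds, counts at each filter) accompanies the bundle, and
#' every stage result carries the config hash.
#'
#' @param recordings list of `eeg_recording` objects (one per subject).
#' @param config a [pipeline_config()].
#' @param fixed_rank skip rank CV and use this NNMF rank.
#' @param stages subset of `c("nnmf", "cluster")` to run beyond the core
#'   statistics (both by default).
#' @return a `jierp_bundle` list: `jierps`, `z_jierps`, `grand`,
#'   `grand_z`, `stats`, `xcorr`, `fits`, `clusters`, `representatives`,
#'   `provenance`.
#' @export
run_pipeline <- function(recordings, config = pipeline_config(),
                         fixed_rank = NULL,
                         stages = c("nnmf", "cluster")) {
  stopifnot(inherits(config, "pipeline_config"), length(recordings) >= 1)
  grid <- bin_grid(config$bin_edges)
  counts <- list()
  jierps <- vector("list", length(recordings))
  fits <- if ("nnmf" %in% stages) vector("list", length(recordings))
  for (s in seq_along(recordings)) {
    rec <- recordings[[s]]
    ep <- preprocess(rec, low = config$filter_low, high = config$filter_high,
                     two_stage = config$two_stage,
                     epoch_window = config$epoch_window,
                     baseline_window = config$baseline_window,
                     reject_uv = config$reject_uv)
    roi <- if (is.null(config$roi)) seq_len(dim(ep$data)[2]) else config$roi
    ch <- select_channel(ep, latency_window = config$select_window,
                         roi = roi, criterion = config$criterion)
    triads <- compute_triads(rec$events)
    jierps[[s]] <- build_jierp(ep, triads, channel = ch, grid = grid,
                               min_trials = config$min_trials)
    counts[[s]] <- c(jierps[[s]]$counts,
                     list(n_rejected = sum(ep$rejected),
                          n_dropped_edge = ep$n_dropped_edge,
                          channel = as.integer(ch)))
    if ("nnmf" %in% stages) {
      nn <- magnitude_transform(jierps[[s]])
      r <- fixed_rank
      if (is.null(r)) {
        r <- select_rank_cv(nn, rank_range = config$rank_range,
                            seed = config$seed + s)$best_rank
      }
      fits[[s]] <- normalize_factors(
        stable_factorize(nn, rank = r, n_reps = config$nnmf_reps,
                         seed = config$seed + s,
                         max_iter = config$nnmf_max_iter,
                         tol = config$nnmf_tol))
    }
  }
  z_jierps <- lapply(jierps, zscore_latencywise)
  grand <- grand_average(jierps, config$min_subject_fraction)
  grand_z <- zscore_latencywise(grand)
  stats_map <- if (length(recordings) >= 3)
    bin_ttest(z_jierps, alpha = config$alpha)
  post <- restrict_post_stimulus(grand_z)
  xc <- fdr_offdiagonal(crosscorr_spearman(post), alpha = config$alpha,
                        band_halfwidth_ms = config$band_halfwidth_ms)
  clusters <- NULL
  reps <- NULL
  pooled <- NULL
  if ("cluster" %in% stages && "nnmf" %in% stages &&
      length(recordings) >= 2) {
    pooled <- pool_factors(fits)
    if (nrow(pooled$metatimes) > min(config$k_range)) {
      clusters <- cluster_metatimes(pooled$metatimes,
                                    k_range = config$k_range,
                                    n_restarts = config$kmeans_restarts,
                                    seed = config$seed)
      reps <- cluster_representatives(clusters, pooled)
    }
  }
  structure(list(jierps = jierps, z_jierps = z_jierps, grand = grand,
                 grand_z = grand_z, stats = stats_map, xcorr = xc,
                 fits = fits, pooled = pooled, clusters = clusters,
                 representatives = reps,
                 provenance = list(
                   config = unclass(config),
                   config_hash = config$config_hash,
                   n_subjects = length(recordings),
                   counts = counts,
                   pipeline_order = c("filter", "epoch", "reject",
                                      "reference", "baseline", "jierp",
                                      "zscore", "stats", "xcorr", "nnmf",
                                      "cluster"),
                   r_version = as.character(getRversion()))),
            class = "jierp_bundle")
}

#' Restrict a z-scored JIERP to post-stimulus latencies
#' @param zjierp a `zjierp`.
#' @param from first latency kept, ms (default 1).
#' @return the restricted `zjierp`.
#' @export
restrict_post_stimulus <- function(zjierp, from = 1) {
  keep <- zjierp$time_ms >= from
  zjierp$z <- zjierp$z[, , keep, drop = FALSE]
  zjierp$constant_latency <- zjierp$constant_latency[keep]
  zjierp$time_ms <- zjierp$time_ms[keep]
  zjierp
}

#' Write the provenance record of a pipeline bundle as JSON
#' @param bundle a `jierp_bundle`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(bundle, path) {
  stopifnot(inherits(bundle, "jierp_bundle"))
  jsonlite::write_json(bundle$provenance, path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}
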