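#' Remove NNMF scale indeterminacy
#'
#' Rescales each meta-time (H row) to unit Euclidean norm and absorbs the
#' inverse scale into the matching W column, leaving the product W H
#' unchanged. All-zero meta-times are dropped (and counted), since they
#' carry no latency information.
#'
#' @param fit a `nnmf_fit`.
#' @return the normalized fit; `n_dropped` records removed factors.
#' @export
normalize_factors <- function(fit) {
  stopifnot(inherits(fit, "nnmf_fit"))
  nrm <- sqrt(rowSums(fit$H^2))
  keep <- nrm > 0
  fit$n_dropped <- sum(!keep)
  fit$H <- fit$H[keep, , drop = FALSE] / nrm[keep]
  fit$W <- sweep(fit$W[, keep, drop = FALSE], 2, nrm[keep], "*")
  fit$rank <- sum(keep)
  fit
}

#' Pool factors across subjects
#'
#' Stacks the (unit-normalized) meta-times of a list of per-subject fits
#' into one matrix of points for clustering, tracking subject of origin
#' and factor index. Meta-JIERPs are expanded onto the full bin grid
#' using each fit's bin mapping (bins that were invalid for a subject
#' stay NA — they are missing, not zero), so subjects with different
#' valid-bin sets pool cleanly.
#'
#' @param fits list of `nnmf_fit` objects (run [normalize_factors()]
#'   first).
#' @return list with `metatimes` (points x latencies), `metajierps`
#'   (points x bins, the paired W columns), `subject`, `factor_index`.
#' @export
pool_factors <- function(fits) {
  stopifnot(length(fits) >= 1)
  mt <- do.call(rbind, lapply(fits, function(f) f$H))
  expand_w <- function(f) {
    if (is.null(f$row_bins)) return(t(f$W))
    b <- f$grid$n_bins
    full <- matrix(NA_real_, ncol(f$W), b * b)
    cells <- (f$row_bins$col - 1L) * b + f$row_bins$row
    full[, cells] <- t(f$W)
    full
  }
  mj <- do.call(rbind, lapply(fits, expand_w))
  subject <- rep(seq_along(fits), vapply(fits, function(f) f$rank,
                                         integer(1)))
  fi <- unlist(lapply(fits, function(f) seq_len(f$rank)))
  list(metatimes = mt, metajierps = mj, subject = subject,
       factor_index = fi)
}

#' Cluster meta-times across the population with k-means
#'
#' For every k in the search range runs seeded best-of-restarts k-means
#' (Lloyd, squared Euclidean objective; each restart initialized from k
#' distinct points drawn uniformly) and evaluates the mean silhouette
#' width; the k with the largest mean silhouette wins. Values of k with
#' fewer points than clusters are skipped.
#'
#' @param metatimes points x latencies matrix (unit-normalized rows).
#' @param k_range candidate cluster counts, default `3:7`.
#' @param n_restarts k-means restarts per k (default 1000).
#' @param seed integer seed.
#' @return a `cluster_solution`: list with `assignments`, `k`,
#'   `silhouette` (per point), `mean_silhouette`, `silhouette_by_k`,
#'   `centers`, `tot_withinss`.
#' @export
cluster_metatimes <- function(metatimes, k_range = 3:7, n_restarts = 1000,
                              seed = 1L) {
  stopifnot(is.matrix(metatimes), nrow(metatimes) >= 2)
  if (nrow(unique(metatimes)) == 1)
    stop("all points identical: silhouette undefined")
  d <- stats::dist(metatimes)
  ks <- k_range[k_range < nrow(metatimes)]
  if (length(ks) == 0) stop("every k in range exceeds the point count")
  sol_by_k <- withr::with_seed(seed, lapply(ks, function(k) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- metatimes[sample.int(nrow(metatimes), k), , drop = FALSE]
      km <- tryCatch(
        stats::kmeans(metatimes, centers = init, iter.max = 100,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) return(NULL)
    sil <- cluster::silhouette(best$cluster, d)
    list(km = best, mean_sil = mean(sil[, "sil_width"]),
         sil = sil[, "sil_width"])
  }))
  ok <- !vapply(sol_by_k, is.null, logical(1))
  if (!any(ok)) stop("k-means failed for every k in range")
  msil <- vapply(sol_by_k[ok], function(s) s$mean_sil, numeric(1))
  pick <- which(ok)[which.max(msil)]
  sol <- sol_by_k[[pick]]
  structure(list(assignments = sol$km$cluster, k = ks[pick],
                 silhouette = sol$sil, mean_silhouette = sol$mean_sil,
                 silhouette_by_k = data.frame(
                   k = ks[ok],
                   mean_silhouette = msil),
                 centers = sol$km$centers,
                 tot_withinss = sol$km$tot.withinss,
                 seed = as.integer(seed)),
            class = "cluster_solution")
}

#' Cluster-averaged representative patterns
#'
#' Per cluster, the elementwise mean of member meta-times and of their
#' paired meta-JIERPs, with subject of origin recorded per member.
#'
#' @param solution a `cluster_solution`.
#' @param pooled output of [pool_factors()] behind the solution.
#' @return list of per-cluster lists: `metatime` (length-T mean),
#'   `metajierp` (mean over members, length b*b), `members`
#'   (data.frame point / subject / factor_index).
#' @export
cluster_representatives <- function(solution, pooled) {
  stopifnot(inherits(solution, "cluster_solution"),
            length(solution$assignments) == nrow(pooled$metatimes))
  lapply(sort(unique(solution$assignments)), function(cl) {
    idx <- which(solution$assignments == cl)
    if (length(idx) == 0) stop("empty cluster ", cl)
    list(cluster = cl,
         metatime = colMeans(pooled$metatimes[idx, , drop = FALSE]),
         metajierp = colMeans(pooled$metajierps[idx, , drop = FALSE],
                              na.rm = TRUE),
         members = data.frame(point = idx,
                              subject = pooled$subject[idx],
                              factor_index = pooled$factor_index[idx]))
  })
}
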