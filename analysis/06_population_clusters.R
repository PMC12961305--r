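#!/usr/bin/env Rscript
# Individual-level decomposition and population clustering: per subject,
# stability-selected NNMF of the JIERP magnitude matrix at the
# population-level rank; unit-normalize the meta-times, pool them across
# subjects, cluster with best-of-restarts k-means (silhouette-selected k,
# search 3-7), and write the cluster-averaged representative meta-times
# and meta-JIERPs.

library(jierp)

rank_cv <- read.delim("results/05_rank_cv.tsv")
r <- rank_cv$rank[which.min(rank_cv$mean_error)]
se <- rank_cv$se_error[which.min(rank_cv$mean_error)]
r <- min(rank_cv$rank[rank_cv$mean_error <= min(rank_cv$mean_error) + se])

jierps <- lapply(Sys.glob("results/jierp/sub*_jierp.tsv"), read_jierp_tsv)
fits <- lapply(seq_along(jierps), function(s)
  normalize_factors(stable_factorize(magnitude_transform(jierps[[s]]),
                                     rank = r, n_reps = 100,
                                     seed = 7 + s)))
pooled <- pool_factors(fits)
sol <- cluster_metatimes(pooled$metatimes, k_range = 3:7,
                         n_restarts = 1000, seed = 7)
reps <- cluster_representatives(sol, pooled)

write.table(sol$silhouette_by_k, "results/06_silhouette_by_k.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(
  do.call(rbind, lapply(reps, function(r)
    data.frame(cluster = r$cluster, n_members = nrow(r$members),
               n_subjects = length(unique(r$members$subject))))),
  "results/06_cluster_sizes.tsv", sep = "\t", row.names = FALSE,
  quote = FALSE)
write.table(do.call(cbind, lapply(reps, function(x) x$metatime)),
            "results/06_cluster_meta_times.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE, col.names = FALSE)
write.table(do.call(cbind, lapply(reps, function(x) x$metajierp)),
            "results/06_cluster_meta_jierps.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE, col.names = FALSE)

message(sprintf(
  "pooled %d meta-times from %d subjects; silhouette selected k = %d (mean width %.2f)",
  nrow(pooled$metatimes), length(fits), sol$k, sol$mean_silhouette))
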