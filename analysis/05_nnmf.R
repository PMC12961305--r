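#!/usr/bin/env Rscript
# Population-level dimensionality reduction: transform the grand-averaged
# JIERP to its non-negative magnitude matrix, choose the NNMF rank by
# Wold-style cross-validation (search 2-10), and run stability-selected
# NNMF (100 repetitions). Writes the meta-JIERPs, meta-times, the CV
# error curve and the stability score.

library(jierp)

grand <- grand_average(lapply(Sys.glob("results/jierp/sub*_jierp.tsv"),
                              read_jierp_tsv))
nn <- magnitude_transform(grand)

cv <- select_rank_cv(nn, rank_range = 2:10, seed = 7)
write.table(cv$error_curve, "results/05_rank_cv.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

fit <- normalize_factors(stable_factorize(nn, rank = cv$best_rank,
                                          n_reps = 100, seed = 7))
W_full <- matrix(NA_real_, 25, fit$rank)
cells <- (nn$row_bins$col - 1) * 5 + nn$row_bins$row
W_full[cells, ] <- fit$W
write.table(W_full, "results/05_meta_jierps.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE, col.names = FALSE)
write.table(t(fit$H), "results/05_meta_times.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE, col.names = FALSE)

message(sprintf(
  "CV selected rank %d; stability score %.3f over 100 repetitions",
  cv$best_rank, fit$stability_score))
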