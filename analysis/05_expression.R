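#!/usr/bin/env Rscript
# Stage 5 — expression post-statistics: l2fc skewness per contrast, DEG
# counts and sign balance, the practical-equivalence "significantly
# unchanged" test on the mutant contrast, and equal-population l2fc bins.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                  value = TRUE)[1])), "_settings.R"))

`%||%` <- function(a, b) if (is.null(a)) b else a

inp <- study_inputs()
cfg <- inp$cfg
de <- simulate_expression_tables(inp$genome, inp$truth, cfg$sim)

summary_ <- list()
for (ct in names(de)) {
  d <- de[[ct]]
  sk <- l2fc_skewness(d$l2fc[d$base_mean > 0])
  degs <- d[d$q < 0.1, ]
  summary_[[ct]] <- list(skewness = sk$skewness, n_degs = nrow(degs),
                         frac_negative = if (nrow(degs)) mean(degs$l2fc < 0)
                                         else NA)
  message(sprintf("%-12s skewness %+.3f over %d genes; %d DEGs (q < 0.1), %.0f%% negative",
                  ct, sk$skewness, sk$n, nrow(degs),
                  100 * (summary_[[ct]]$frac_negative %||% NA)))
  d$bin <- bin_equally_populated(d$l2fc, 7)
  write_de_tsv(d, file.path(RESULTS, "de", paste0(ct, "_binned.tsv")))
}

# of the genes repressed on the sugar diet, how many are significantly
# unchanged in the mutant contrast (practical equivalence, 1.5-fold ROPE)?
repressed <- with(de$SD_vs_CD, gene_id[q < 0.1 & l2fc < 0])
mut <- de$PclSD_vs_CD[de$PclSD_vs_CD$gene_id %in% repressed, ]
eq <- equivalence_test(mut, fold_bound = cfg$fold_bound, alpha_q = cfg$alpha_q)
write.table(eq, file.path(RESULTS, "equivalence_mutant.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
summary_$unchanged_in_mutant <- mean(eq$unchanged)
message(sprintf("%d/%d repressed genes significantly unchanged in the mutant (%.0f%%)",
                sum(eq$unchanged), nrow(eq), 100 * mean(eq$unchanged)))

jsonlite::write_json(summary_, file.path(RESULTS, "expression_summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
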