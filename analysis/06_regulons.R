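#!/usr/bin/env Rscript
# Stage 6 — regulon inference: PWM promoter scans, robust z, threshold
# curves with automatic tau* selection, regulon recovery against the
# planted truth, and pairwise Fisher overlap tests.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                  value = TRUE)[1])), "_settings.R"))

inp <- study_inputs()
de <- simulate_expression_tables(inp$genome, inp$truth, inp$cfg$sim)
windows <- promoter_windows(inp$genome, width = inp$cfg$upstream)

dir.create(file.path(RESULTS, "regulons"), showWarnings = FALSE)
regulons <- list()
for (tf in names(inp$truth$motifs)) {
  hits <- scan_motif(inp$genome, inp$truth$motifs[[tf]])
  grid <- seq(2, max(ceiling(max(hits$z)), 3), by = 0.5)
  curve <- threshold_curve(hits, windows, de$SD_vs_CD, grid)
  tau_star <- attr(curve, "tau_star")
  reg <- build_regulon(hits, windows, tau_star)
  regulons[[tf]] <- reg
  write.table(curve, file.path(RESULTS, "regulons", paste0(tf, "_curve.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(reg$genes, file.path(RESULTS, "regulons", paste0(tf, "_genes.txt")))
  jac <- length(intersect(reg$genes, inp$truth$true_regulons[[tf]])) /
         length(union(reg$genes, inp$truth$true_regulons[[tf]]))
  message(sprintf("%s: tau* = %.2f (planted %.2f), %d genes, Jaccard vs truth %.2f",
                  tf, tau_star, inp$truth$tf_thresholds[[tf]],
                  length(reg$genes), jac))
}

ov <- regulon_overlap_tests(regulons, inp$genome$genes$gene_id)
write.table(ov, file.path(RESULTS, "regulons", "overlap_tests.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("pairwise overlap odds ratios: ",
        paste(sprintf("%.1f", ov$odds_ratio), collapse = ", "))

changed <- names(inp$truth$true_l2fc)[inp$truth$true_l2fc != 0]
union_reg <- unique(unlist(lapply(regulons, `[[`, "genes")))
message(sprintf("regulon union covers %.0f%% of the %d changed genes",
                100 * mean(changed %in% union_reg), length(changed)))
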