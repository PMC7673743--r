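#!/usr/bin/env Rscript
# Stage 4 — Monte Carlo overlap enrichment of SD peaks against predicted
# PREs (overall and by class, confidence >= 0.8), and observed/expected
# gene proportions across the five chromatin states.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                  value = TRUE)[1])), "_settings.R"))

inp <- study_inputs()
cfg <- inp$cfg
peaks_sd <- read.delim(file.path(RESULTS, "peaks_SD.bed"), header = FALSE,
                       col.names = c("chrom", "start", "end"))

res <- list()
for (cls in list(NULL, "intergenic", "enhancer")) {
  pres <- select_pres(inp$genome, pre_class = cls, min_confidence = 0.8)
  if (!nrow(pres)) next
  er <- permutation_enrichment(peaks_sd, pres, inp$genome,
                               n_shuffles = cfg$n_shuffles_enrich,
                               seed = stage_seed(SEED, "enrich"))
  lab <- if (is.null(cls)) "all" else cls
  res[[lab]] <- list(observed = er$observed, fold = er$fold,
                     p_empirical = er$p_empirical)
  message(sprintf("PRE class %-10s fold %.2f (p = %.4g, %d shuffles)",
                  lab, er$fold, er$p_empirical, er$n_shuffles))
}
jsonlite::write_json(res, file.path(RESULTS, "pre_enrichment.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

bound <- read.delim(file.path(RESULTS, "bound_genes_SD.tsv"))
tab <- chromatin_state_proportions(bound$gene_id[bound$bound], inp$genome)
write.table(tab, file.path(RESULTS, "chromatin_state_proportions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("state with maximal observed/expected ratio: ",
        tab$state[which.max(tab$ratio)],
        sprintf(" (%.2f)", max(tab$ratio)))
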