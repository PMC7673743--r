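#!/usr/bin/env Rscript
# Stage 1 — simulate the study genome and write its plain-text artifacts:
# FASTA sequence, GFF3 genes, BED chromatin states and PREs, per-sample
# fragment count tables, DE result tables, and the planted truth.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                  value = TRUE)[1])), "_settings.R"))

inp <- study_inputs()
cfg <- inp$cfg

message("genome: ", nrow(inp$genome$chromosomes), " chromosomes, ",
        nrow(inp$genome$genes), " genes, ",
        nrow(inp$fragmap), " GATC fragments")

write_genome_fasta(inp$genome, file.path(RESULTS, "genome.fa"))
write_genes_gff3(inp$genome, file.path(RESULTS, "genes.gff3"))
write_bed(inp$genome$chromatin_states, file.path(RESULTS, "states.bed"))
write_bed(inp$genome$pres, file.path(RESULTS, "pres.bed"))

counts <- simulate_damid_counts(inp$genome, inp$truth, cfg$sim, inp$fragmap)
dir.create(file.path(RESULTS, "counts"), showWarnings = FALSE)
for (id in names(counts))
  write_counts_tsv(counts[[id]], file.path(RESULTS, "counts", paste0(id, ".tsv")))

de <- simulate_expression_tables(inp$genome, inp$truth, cfg$sim)
dir.create(file.path(RESULTS, "de"), showWarnings = FALSE)
for (ct in names(de))
  write_de_tsv(de[[ct]], file.path(RESULTS, "de", paste0(ct, ".tsv")))

truth_summary <- list(
  n_planted_peaks = lapply(inp$truth$planted_peaks, nrow),
  regulon_sizes = lapply(inp$truth$true_regulons, length),
  tf_thresholds = as.list(inp$truth$tf_thresholds),
  n_changed_genes = sum(inp$truth$true_l2fc != 0))
jsonlite::write_json(truth_summary, file.path(RESULTS, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

message("planted: ", nrow(inp$truth$peak_table), " peaks, ",
        truth_summary$n_changed_genes, " changed genes across ",
        cfg$sim$n_tfs, " regulons")
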