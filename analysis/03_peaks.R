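#!/usr/bin/env Rscript
# Stage 3 — shuffle-FDR peak calling per replicate, replicate intersection,
# peak-to-gene association, and per-gene occupancy differences between the
# control (CD) and sugar (SD) conditions.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                  value = TRUE)[1])), "_settings.R"))

inp <- study_inputs()
cfg <- inp$cfg
counts <- simulate_damid_counts(inp$genome, inp$truth, cfg$sim, inp$fragmap)

peaks <- list(); mean_track <- list()
for (cond in c("CD", "SD")) {
  reps <- lapply(1:cfg$sim$n_replicates, function(r)
    compute_log_ratio(counts[[sprintf("fusion_%s_rep%d", cond, r)]],
                      counts[[sprintf("Dam_%s_rep%d", cond, r)]]))
  psets <- lapply(seq_along(reps), function(r)
    call_peaks_fdr(reps[[r]], fdr_max = cfg$fdr_max,
                   n_shuffles = cfg$n_shuffles_peaks, min_run = cfg$min_run,
                   threshold_q = cfg$threshold_q,
                   seed = stage_seed(SEED, paste0("peaks_", cond, "_", r))))
  message(cond, ": ", paste(vapply(psets, nrow, 1L), collapse = "/"),
          " peaks per replicate")
  peaks[[cond]] <- merge_intervals(intersect_replicate_peaks(psets))
  write_bed(peaks[[cond]], file.path(RESULTS, paste0("peaks_", cond, ".bed")))
  mt <- reps[[1]]
  mt$values <- rowMeans(vapply(reps, `[[`, numeric(nrow(inp$fragmap)), "values"))
  mean_track[[cond]] <- mt
}

message("replicate-intersected peaks: CD ", nrow(peaks$CD), ", SD ",
        nrow(peaks$SD), "; SD peaks sharing any overlap with CD: ",
        round(shared_peak_fraction(peaks$SD, peaks$CD), 3))
message("bp Jaccard vs planted truth: CD ",
        round(interval_jaccard(peaks$CD, inp$truth$planted_peaks$CD), 3), ", SD ",
        round(interval_jaccard(peaks$SD, inp$truth$planted_peaks$SD), 3))

bound <- peaks_to_genes(peaks$SD, inp$genome)
write.table(bound, file.path(RESULTS, "bound_genes_SD.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sum(bound$bound), " genes bound by SD peaks")

dd <- compare_occupancy(mean_track$CD, mean_track$SD, inp$genome)
write.table(dd, file.path(RESULTS, "occupancy_delta.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("occupancy groups: ", sum(dd$group == "1", na.rm = TRUE),
        " higher on SD (group 1), ", sum(dd$group == "2", na.rm = TRUE),
        " lower on SD (group 2)")
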