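#' Base-pair Jaccard index between two interval sets
#'
#' @param a,b interval data.frames.
#' @return |intersection| / |union| in bp (NA if both empty).
#' @export
interval_jaccard <- function(a, b) {
  chroms <- union(unique(a$chrom), unique(b$chrom))
  if (!length(chroms)) return(NA_real_)
  inter <- 0; uni <- 0
  for (cn in chroms) {
    ia <- IRanges::reduce(ir0(a$start[a$chrom == cn], a$end[a$chrom == cn]))
    ib <- IRanges::reduce(ir0(b$start[b$chrom == cn], b$end[b$chrom == cn]))
    inter <- inter + sum(IRanges::width(IRanges::intersect(ia, ib)))
    uni <- uni + sum(IRanges::width(IRanges::union(ia, ib)))
  }
  if (uni == 0) NA_real_ else inter / uni
}

set_jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

# average replicate occupancy tracks into one display/comparison track
average_tracks <- function(tracks) {
  vals <- rowMeans(do.call(cbind, lapply(tracks, `[[`, "values")))
  out <- tracks[[1]]
  out$values <- vals
  out$sample_id <- "mean"
  out
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass_rec(config), auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else x
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes simulate -> fragment map -> occupancy ratios -> peak calling
#' (per replicate, intersected) -> PRE overlap enrichment -> chromatin
#' state proportions -> expression post-statistics -> regulon inference,
#' and assembles a machine-readable `RunReport` including truth-recovery
#' metrics. Deterministic for a fixed config: all stage seeds derive from
#' the single seed in the `SimConfig`.
#'
#' @param config a [pipeline_config()].
#' @return a `RunReport` (nested list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  sim_cfg <- config$sim
  seed <- sim_cfg$seed

  sim <- simulate_genome(sim_cfg)
  genome <- sim$genome; truth <- sim$truth
  fragmap <- build_gatc_fragment_map(genome)
  counts <- simulate_damid_counts(genome, truth, sim_cfg, fragmap)

  ## ratio tracks per condition x replicate, kept separate
  ratio <- list(); mean_track <- list()
  for (cond in c("CD", "SD")) {
    reps <- lapply(seq_len(sim_cfg$n_replicates), function(r)
      compute_log_ratio(counts[[sprintf("fusion_%s_rep%d", cond, r)]],
                        counts[[sprintf("Dam_%s_rep%d", cond, r)]]))
    ratio[[cond]] <- reps
    mean_track[[cond]] <- average_tracks(reps)
  }

  ## peaks: call per replicate, keep regions present in all replicates
  peaks <- list()
  for (cond in c("CD", "SD")) {
    psets <- lapply(seq_along(ratio[[cond]]), function(r)
      call_peaks_fdr(ratio[[cond]][[r]], fdr_max = config$fdr_max,
                     n_shuffles = config$n_shuffles_peaks,
                     min_run = config$min_run,
                     threshold_q = config$threshold_q,
                     seed = stage_seed(seed, paste0("peaks_", cond, "_", r))))
    pk <- if (length(psets) >= 2L) intersect_replicate_peaks(psets)
          else psets[[1]][, c("chrom", "start", "end")]
    peaks[[cond]] <- merge_intervals(pk)
  }
  shared_frac <- shared_peak_fraction(peaks$SD, peaks$CD)

  ## PRE overlap enrichment (SD peaks vs confident PREs)
  pres_hi <- select_pres(genome, min_confidence = 0.8)
  enrich <- NULL
  if (nrow(peaks$SD) && nrow(pres_hi))
    enrich <- permutation_enrichment(peaks$SD, pres_hi, genome,
                                     n_shuffles = config$n_shuffles_enrich,
                                     seed = stage_seed(seed, "enrich"))

  ## chromatin state proportions of bound genes
  bound <- peaks_to_genes(peaks$SD, genome, upstream = config$upstream)
  states <- NULL
  if (any(bound$bound))
    states <- chromatin_state_proportions(bound$gene_id[bound$bound], genome)

  ## per-gene occupancy differences between conditions
  occ_delta <- compare_occupancy(mean_track$CD, mean_track$SD, genome,
                                 upstream = config$upstream)

  ## expression post-statistics
  de <- simulate_expression_tables(genome, truth, sim_cfg)
  skew <- lapply(de, function(d)
    l2fc_skewness(d$l2fc[d$base_mean > 0])$skewness)
  degs <- lapply(de, function(d) d[d$q < 0.1, , drop = FALSE])
  repressed <- degs$SD_vs_CD$gene_id[degs$SD_vs_CD$l2fc < 0]
  equiv_frac <- reverted_frac <- NA_real_
  if (length(repressed) >= 3) {
    mut <- de$PclSD_vs_CD[de$PclSD_vs_CD$gene_id %in% repressed, ]
    eq <- equivalence_test(mut, fold_bound = config$fold_bound,
                           alpha_q = config$alpha_q)
    equiv_frac <- mean(eq$unchanged)
    reverted_frac <- mean(mut$l2fc > 0 & mut$q < 0.1)
  }

  ## regulon inference
  windows <- promoter_windows(genome, width = config$upstream)
  regulons <- list(); curves <- list(); tau_err <- c(); reg_jac <- c()
  for (tf in names(truth$motifs)) {
    hits <- scan_motif(genome, truth$motifs[[tf]])
    grid <- config$tau_grid
    if (is.null(grid)) grid <- seq(2, max(ceiling(max(hits$z)), 3), by = 0.5)
    curve <- threshold_curve(hits, windows, de$SD_vs_CD, grid)
    tau_star <- attr(curve, "tau_star")
    reg <- build_regulon(hits, windows, tau_star)
    reg$curve <- curve
    regulons[[tf]] <- reg
    curves[[tf]] <- curve
    tau_err[tf] <- tau_star - truth$tf_thresholds[[tf]]
    reg_jac[tf] <- set_jaccard(reg$genes, truth$true_regulons[[tf]])
  }
  overlap_tests <- if (length(regulons) >= 2L)
    regulon_overlap_tests(regulons, genome$genes$gene_id) else NULL

  ## truth recovery
  peak_jaccard <- vapply(c("CD", "SD"), function(cond)
    interval_jaccard(peaks[[cond]], truth$planted_peaks[[cond]]), numeric(1))
  changed <- names(truth$true_l2fc)[truth$true_l2fc != 0]
  union_reg <- unique(unlist(lapply(regulons, `[[`, "genes")))
  union_cover <- if (length(changed)) mean(changed %in% union_reg) else NA_real_

  report <- list(
    provenance = list(
      package = "tadaregulon",
      version = as.character(utils::packageVersion("tadaregulon")),
      seed = seed, config_hash = config_hash(config)),
    peaks = list(
      n_peaks_CD = nrow(peaks$CD), n_peaks_SD = nrow(peaks$SD),
      shared_fraction_SD_vs_CD = shared_frac),
    pre_enrichment = if (is.null(enrich)) NULL else list(
      observed = enrich$observed, null_mean = enrich$null_mean,
      fold = enrich$fold, p_empirical = enrich$p_empirical),
    chromatin_states = if (is.null(states)) NULL else
      setNames(as.list(states$ratio), states$state),
    occupancy = list(
      n_group1 = sum(occ_delta$group == "1", na.rm = TRUE),
      n_group2 = sum(occ_delta$group == "2", na.rm = TRUE)),
    expression = list(
      skewness = skew,
      n_degs = lapply(degs, nrow),
      frac_negative_degs = lapply(degs, function(d)
        if (nrow(d)) mean(d$l2fc < 0) else NA_real_),
      frac_unchanged_in_mutant = equiv_frac,
      frac_reverted_in_mutant = reverted_frac),
    regulons = list(
      sizes = lapply(regulons, function(r) length(r$genes)),
      tau_star = lapply(regulons, `[[`, "threshold_z"),
      overlap_odds_ratios = if (is.null(overlap_tests)) NULL else
        overlap_tests$odds_ratio),
    truth_recovery = list(
      peak_jaccard_CD = unname(peak_jaccard["CD"]),
      peak_jaccard_SD = unname(peak_jaccard["SD"]),
      regulon_jaccard = as.list(reg_jac),
      tau_error = as.list(tau_err),
      regulon_union_coverage_of_changed = union_cover))

  structure(list(report = report, genome = genome, truth = truth,
                 fragmap = fragmap, counts = counts, ratio = ratio,
                 mean_track = mean_track, peaks = peaks, de = de,
                 occ_delta = occ_delta, regulons = regulons,
                 overlap_tests = overlap_tests, bound = bound,
                 states = states, enrich = enrich, config = config),
            class = "PipelineRun")
}

#' @export
print.PipelineRun <- function(x, ...) {
  r <- x$report
  cat("PipelineRun (seed", r$provenance$seed, "):",
      r$peaks$n_peaks_CD, "CD /", r$peaks$n_peaks_SD, "SD peaks; skew(SD) =",
      signif(r$expression$skewness$SD_vs_CD, 3), "\n")
  invisible(x)
}

#' Write a run report as JSON (with optional TSV side tables)
#'
#' JSON keys keep their construction order so reports are comparable
#' byte-for-byte across runs of the same config.
#'
#' @param report a `RunReport` list (the `report` element of a
#'   `PipelineRun`, or the run itself).
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "PipelineRun")) report <- report$report
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", null = "null")
    TRUE
  }, error = function(e) stopf("cannot write report to %s: %s", path,
                               conditionMessage(e)))
  invisible(path)
}
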