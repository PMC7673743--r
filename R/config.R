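#' Simulation configuration
#'
#' Bundles every knob of the synthetic-genome generator. Defaults describe
#' the standard desk-scale study: two 500-kb chromosomes carrying 400
#' non-overlapping genes, GATC sites planted as a Poisson process at one per
#' 250 bp (the approximate density of a fly chromosome arm), occupancy peaks
#' that are shared between, gained on, or lost from the sugar-diet (SD)
#' condition relative to control diet (CD), and five transcription factors
#' (four activators, one repressor) whose regulon members carry a planted
#' negative log2 fold change.
#'
#' @param seed integer; master seed for all randomness.
#' @param n_chroms number of chromosomes.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param gatc_rate per-bp probability of a planted GATC site.
#' @param n_genes total genes across the genome.
#' @param n_peaks_shared,n_peaks_gained,n_peaks_lost occupancy peaks by
#'   condition behaviour (shared = both CD and SD, gained = SD only,
#'   lost = CD only).
#' @param peak_effect mean log2 enrichment of the fusion construct over Dam
#'   inside a peak; must be > 0.
#' @param read_depth expected total reads per sample.
#' @param n_tfs number of transcription factors (default 5).
#' @param regulon_effect mean true l2fc of repressed regulon members;
#'   negative for repression scenarios.
#' @param frac_null fraction of genes whose true l2fc is exactly 0.
#' @param se_scale multiplier on the gene-wise standard error of l2fc.
#' @param n_replicates replicates per condition per construct.
#' @return an object of class `SimConfig` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length_bp = 500000L,
                       gatc_rate = 0.004,
                       n_genes = 400L,
                       n_peaks_shared = 20L,
                       n_peaks_gained = 20L,
                       n_peaks_lost = 20L,
                       peak_effect = 2,
                       read_depth = 5e5,
                       n_tfs = 5L,
                       regulon_effect = -1,
                       frac_null = 0.7,
                       se_scale = 1,
                       n_replicates = 2L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length_bp = as.integer(chrom_length_bp),
              gatc_rate = gatc_rate, n_genes = as.integer(n_genes),
              n_peaks_shared = as.integer(n_peaks_shared),
              n_peaks_gained = as.integer(n_peaks_gained),
              n_peaks_lost = as.integer(n_peaks_lost),
              peak_effect = peak_effect, read_depth = read_depth,
              n_tfs = as.integer(n_tfs), regulon_effect = regulon_effect,
              frac_null = frac_null, se_scale = se_scale,
              n_replicates = as.integer(n_replicates))
  validate_sim_config(cfg)
  structure(cfg, class = "SimConfig")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_chroms", "chrom_length_bp", "n_genes", "n_peaks_shared",
              "n_peaks_gained", "n_peaks_lost", "n_tfs", "n_replicates")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) stopf("%s must be >= 0", f)
  if (cfg$gatc_rate < 0 || cfg$gatc_rate > 1)
    stopf("gatc_rate must be a probability in [0, 1]")
  if (cfg$frac_null < 0 || cfg$frac_null > 1)
    stopf("frac_null must be in [0, 1]")
  if (cfg$peak_effect <= 0) stopf("peak_effect must be > 0")
  if (cfg$read_depth <= 0) stopf("read_depth must be > 0")
  if (cfg$se_scale < 0) stopf("se_scale must be >= 0")
  invisible(cfg)
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", x$n_chroms, "chromosome(s) x", x$chrom_length_bp, "bp,",
      x$n_genes, "genes,", x$n_tfs, "TFs, seed", x$seed, "\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' A [sim_config()] plus per-stage analysis parameters, used by
#' [run_pipeline()]. Stage seeds all derive deterministically from the
#' single `seed` in the `SimConfig` via [stage_seed()].
#'
#' @param sim a `SimConfig`.
#' @param fdr_max peak-calling FDR cutoff.
#' @param n_shuffles_peaks shuffles for the peak-calling null.
#' @param n_shuffles_enrich shuffles for interval-overlap enrichment.
#' @param threshold_q quantile defining the peak signal threshold.
#' @param min_run minimum consecutive above-threshold fragments per peak.
#' @param fold_bound practical-equivalence fold bound (> 1).
#' @param alpha_q BH q cutoff for "unchanged" calls.
#' @param tau_grid candidate robust-z thresholds for regulon selection.
#' @param upstream promoter window width, bp upstream of the ORF start.
#' @param outdir optional output directory for stage artifacts.
#' @return an object of class `PipelineConfig`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            fdr_max = 0.01,
                            n_shuffles_peaks = 100L,
                            n_shuffles_enrich = 1000L,
                            threshold_q = 0.90,
                            min_run = 2L,
                            fold_bound = 1.5,
                            alpha_q = 0.1,
                            tau_grid = NULL,
                            upstream = 2000L,
                            outdir = NULL) {
  stopifnot(inherits(sim, "SimConfig"))
  if (fdr_max <= 0 || fdr_max > 1) stopf("fdr_max must be in (0, 1]")
  if (fold_bound <= 1) stopf("fold_bound must be > 1")
  structure(list(sim = sim, fdr_max = fdr_max,
                 n_shuffles_peaks = as.integer(n_shuffles_peaks),
                 n_shuffles_enrich = as.integer(n_shuffles_enrich),
                 threshold_q = threshold_q, min_run = as.integer(min_run),
                 fold_bound = fold_bound, alpha_q = alpha_q,
                 tau_grid = tau_grid, upstream = as.integer(upstream),
                 outdir = outdir),
            class = "PipelineConfig")
}
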