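#' Simulate DamID fragment counts for both constructs and conditions
#'
#' Dam-only counts per fragment are Poisson with rate proportional to
#' fragment length times an accessibility factor (promoter fragments of
#' expressed genes are 3x more accessible, giving the accessibility
#' read-out something to find). Fusion (Dam::Pcl) counts multiply the rate
#' by `2^peak_effect` inside the peaks planted for the matching condition,
#' then renormalise so every library's expected depth is `read_depth`;
#' the fusion/Dam contrast between peak and non-peak fragments is therefore
#' exactly `peak_effect` in log2 units. Two replicates per condition per
#' construct by default.
#'
#' @param genome a `GenomeModel` from [simulate_genome()].
#' @param truth the matching `SimTruth`.
#' @param config the [sim_config()] used.
#' @param fragmap optional precomputed [build_gatc_fragment_map()].
#' @return named list of `FragmentCountTrack`s with names like
#'   `Dam_CD_rep1`, `fusion_SD_rep2`.
#' @export
simulate_damid_counts <- function(genome, truth, config, fragmap = NULL) {
  if (is.null(fragmap)) fragmap <- build_gatc_fragment_map(genome)
  if (!nrow(fragmap)) stopf("empty fragment map")
  set.seed(stage_seed(config$seed, "damid"))

  len <- fragmap$end - fragmap$start
  access <- rep(1, nrow(fragmap))
  g <- genome$genes[genome$genes$expressed, , drop = FALSE]
  if (nrow(g)) {
    prom <- promoter_windows(genome, width = 2000L)
    prom <- prom[prom$gene_id %in% g$gene_id, , drop = FALSE]
    access[fragments_in_intervals(fragmap, prom)] <- 3
  }
  w_dam <- len * access

  peak_frag <- lapply(truth$planted_peaks, function(pk)
    fragments_in_intervals(fragmap, pk))

  tracks <- list()
  for (cond in c("CD", "SD")) {
    w_fus <- w_dam
    w_fus[peak_frag[[cond]]] <- w_fus[peak_frag[[cond]]] * 2^config$peak_effect
    for (rep_i in seq_len(config$n_replicates)) {
      for (construct in c("Dam", "fusion")) {
        w <- if (construct == "Dam") w_dam else w_fus
        lam <- config$read_depth * w / sum(w)
        counts <- rpois(length(lam), lam)
        id <- sprintf("%s_%s_rep%d", construct, cond, rep_i)
        tracks[[id]] <- structure(
          list(sample_id = id, condition = cond, construct = construct,
               counts = counts, library_size = sum(counts), fragmap = fragmap),
          class = "FragmentCountTrack")
      }
    }
  }
  tracks
}

# indices of fragments overlapping any interval in a 0-based df
fragments_in_intervals <- function(fragmap, intervals) {
  if (!nrow(intervals)) return(integer(0))
  hits <- integer(0)
  for (cn in unique(intervals$chrom)) {
    fi <- which(fragmap$chrom == cn)
    if (!length(fi)) next
    iv <- intervals[intervals$chrom == cn, ]
    ov <- IRanges::overlapsAny(ir0(fragmap$start[fi], fragmap$end[fi]),
                               ir0(iv$start, iv$end))
    hits <- c(hits, fi[ov])
  }
  sort(unique(hits))
}
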