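#' Shuffle-FDR peak calling on an occupancy track
#'
#' A signal threshold is taken as a quantile of the track values; observed
#' peaks are maximal runs of at least `min_run` consecutive fragments
#' strictly above it. The null expectation comes from permuting fragment
#' values within each chromosome `n_shuffles` times and counting runs of
#' each length; the false-discovery estimate for a run of length `n` is
#' `expected(runs >= n) / observed(runs >= n)`, and runs with an estimate
#' below `fdr_max` are reported as peaks on fragment coordinates.
#'
#' @param track an `OccupancyTrack`.
#' @param fdr_max maximum FDR estimate for a reported peak.
#' @param n_shuffles number of within-chromosome value permutations.
#' @param min_run minimum consecutive fragments above threshold.
#' @param threshold_q quantile of the value distribution used as threshold.
#' @param seed integer seed for the shuffles.
#' @return a `PeakSet` data.frame (`chrom`, `start`, `end`, `n_fragments`,
#'   `mean_signal`, `threshold_used`, `fdr`), sorted and disjoint, with
#'   provenance attributes.
#' @export
call_peaks_fdr <- function(track, fdr_max = 0.01, n_shuffles = 100L,
                           min_run = 2L, threshold_q = 0.95, seed = 1L) {
  stopifnot(inherits(track, "OccupancyTrack"))
  values <- track$values
  fragmap <- track$fragmap
  if (!all(is.finite(values))) stopf("track must be finite everywhere")
  if (length(values) < 10L * min_run)
    stopf("too few fragments (%d) for peak calling", length(values))
  thr <- unname(quantile(values, threshold_q))
  chrom <- fragmap$chrom
  set.seed(seed)

  runs_above <- function(v) {
    r <- rle(v > thr)
    r$lengths[r$values]
  }
  by_chrom <- split(values, chrom)
  obs_runs_chrom <- lapply(by_chrom, runs_above)

  # observed run positions, per chromosome
  empty <- structure(data.frame(chrom = character(0), start = integer(0),
                                end = integer(0), n_fragments = integer(0),
                                mean_signal = numeric(0),
                                threshold_used = numeric(0), fdr = numeric(0)),
                     class = c("PeakSet", "data.frame"),
                     threshold = thr, fdr_max = fdr_max,
                     n_shuffles = n_shuffles, seed = seed)
  obs_lengths <- unlist(obs_runs_chrom, use.names = FALSE)
  obs_lengths <- obs_lengths[obs_lengths >= min_run]
  if (!length(obs_lengths)) return(empty)

  null_lengths_total <- numeric(0)
  null_counts <- vapply(seq_len(n_shuffles), function(i) {
    lens <- unlist(lapply(by_chrom, function(v) runs_above(sample(v))),
                   use.names = FALSE)
    lens <- lens[lens >= min_run]
    null_lengths_total <<- c(null_lengths_total, lens)
    length(lens)
  }, numeric(1))

  obs_ge <- function(n) sum(obs_lengths >= n)
  exp_ge <- function(n) sum(null_lengths_total >= n) / n_shuffles
  fdr_of_len <- vapply(sort(unique(obs_lengths)),
                       function(n) exp_ge(n) / obs_ge(n), numeric(1))
  names(fdr_of_len) <- sort(unique(obs_lengths))

  rows <- list()
  for (cn in names(by_chrom)) {
    v <- by_chrom[[cn]]
    r <- rle(v > thr)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    fi <- which(fragmap$chrom == cn)
    for (j in which(r$values & r$lengths >= min_run)) {
      n <- r$lengths[j]
      fdr <- unname(fdr_of_len[as.character(n)])
      if (fdr >= fdr_max) next
      idx <- fi[starts_i[j]:ends_i[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cn, start = fragmap$start[idx[1L]],
        end = fragmap$end[idx[length(idx)]], n_fragments = n,
        mean_signal = mean(values[idx]), threshold_used = thr, fdr = fdr,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  structure(out, class = c("PeakSet", "data.frame"), threshold = thr,
            fdr_max = fdr_max, n_shuffles = n_shuffles, seed = seed)
}

#' Merge overlapping or bookended intervals
#'
#' Overlapping intervals and intervals that touch end-to-start (bookended,
#' the mergeBed default) collapse into one; output is sorted and disjoint.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return data.frame of merged intervals.
#' @export
merge_intervals <- function(intervals) {
  check_intervals(intervals)
  if (!nrow(intervals)) return(intervals[, c("chrom", "start", "end")])
  parts <- lapply(split(intervals, intervals$chrom), function(d)
    df0(IRanges::reduce(ir0(d$start, d$end)), chrom = d$chrom[1]))
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Base-pair intersection of replicate peak sets
#'
#' Returns the regions covered by *every* input set, i.e. the bp-wise
#' intersection across replicates.
#'
#' @param peaksets list (length >= 2) of interval data.frames.
#' @return data.frame of intersected intervals, sorted and disjoint.
#' @export
intersect_replicate_peaks <- function(peaksets) {
  if (!is.list(peaksets) || length(peaksets) < 2L)
    stopf("need at least two peak sets")
  for (p in peaksets) check_intervals(p, "peak")
  chroms <- unique(unlist(lapply(peaksets, function(p) unique(p$chrom))))
  rows <- list()
  for (cn in chroms) {
    irs <- lapply(peaksets, function(p) {
      d <- p[p$chrom == cn, ]
      IRanges::reduce(ir0(d$start, d$end))
    })
    inter <- Reduce(IRanges::intersect, irs)
    if (length(inter))
      rows[[length(rows) + 1L]] <- df0(inter, chrom = cn)
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# strand-aware gene window: gene span plus `upstream` bp 5' of the ORF start
gene_windows <- function(genes, upstream = 2000L) {
  plus <- genes$strand != "-"
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = ifelse(plus, pmin(genes$start, genes$orf_start - upstream),
                            genes$start),
             end = ifelse(plus, genes$end,
                          pmax(genes$end, genes$orf_start + upstream)),
             stringsAsFactors = FALSE)
}

#' Associate peaks to genes
#'
#' A gene is flagged bound if any peak overlaps its span extended
#' `upstream` bp 5' of the ORF start (strand-aware).
#'
#' @param peaks interval data.frame (e.g. a `PeakSet`).
#' @param genome a `GenomeModel` with `genes`.
#' @param upstream upstream extension in bp.
#' @return data.frame with `gene_id`, `n_peaks`, `bound`.
#' @export
peaks_to_genes <- function(peaks, genome, upstream = 2000L) {
  genes <- genome$genes
  win <- gene_windows(genes, upstream)
  win$start <- pmax(win$start, 0L)
  n_peaks <- integer(nrow(win))
  for (cn in unique(win$chrom)) {
    wi <- which(win$chrom == cn)
    pk <- peaks[peaks$chrom == cn, , drop = FALSE]
    if (!nrow(pk)) next
    n_peaks[wi] <- IRanges::countOverlaps(ir0(win$start[wi], win$end[wi]),
                                          ir0(pk$start, pk$end))
  }
  data.frame(gene_id = genes$gene_id, n_peaks = n_peaks, bound = n_peaks > 0L,
             stringsAsFactors = FALSE)
}

#' Per-gene occupancy difference between conditions
#'
#' For each gene, the mean log2 ratio over the fragments overlapping its
#' window (span plus upstream extension) is computed per condition; the
#' difference `delta = SD - CD` classifies the gene as group 1
#' (higher on SD, `delta >= min_abs_delta`), group 2 (lower on SD), or
#' unchanged. Genes overlapping no fragment are reported with missing
#' values and excluded from grouping.
#'
#' @param track_CD,track_SD `OccupancyTrack`s on the same fragment map.
#' @param genome a `GenomeModel`.
#' @param min_abs_delta minimum |delta| to call a change.
#' @param upstream upstream extension in bp.
#' @return data.frame with `gene_id`, `mean_ratio_CD`, `mean_ratio_SD`,
#'   `delta`, `group` in {"1","2","unchanged",NA}.
#' @export
compare_occupancy <- function(track_CD, track_SD, genome,
                              min_abs_delta = 0.5, upstream = 2000L) {
  stopifnot(inherits(track_CD, "OccupancyTrack"),
            inherits(track_SD, "OccupancyTrack"))
  fragmap <- track_CD$fragmap
  if (!identical(fragmap$start, track_SD$fragmap$start))
    stopf("tracks must share a fragment map")
  win <- gene_windows(genome$genes, upstream)
  win$start <- pmax(win$start, 0L)
  out <- data.frame(gene_id = win$gene_id,
                    mean_ratio_CD = NA_real_, mean_ratio_SD = NA_real_,
                    delta = NA_real_, group = NA_character_,
                    stringsAsFactors = FALSE)
  for (cn in unique(win$chrom)) {
    wi <- which(win$chrom == cn)
    fi <- which(fragmap$chrom == cn)
    if (!length(fi)) next
    hits <- IRanges::findOverlaps(ir0(win$start[wi], win$end[wi]),
                                  ir0(fragmap$start[fi], fragmap$end[fi]))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (k in unique(qh)) {
      idx <- fi[sh[qh == k]]
      out$mean_ratio_CD[wi[k]] <- mean(track_CD$values[idx])
      out$mean_ratio_SD[wi[k]] <- mean(track_SD$values[idx])
    }
  }
  out$delta <- out$mean_ratio_SD - out$mean_ratio_CD
  out$group <- ifelse(is.na(out$delta), NA_character_,
                      ifelse(out$delta >= min_abs_delta, "1",
                             ifelse(out$delta <= -min_abs_delta, "2", "unchanged")))
  out
}

#' Fraction of query peaks sharing any overlap with another peak set
#'
#' @param a,b interval data.frames.
#' @return fraction of peaks in `a` overlapping at least one peak in `b`.
#' @export
shared_peak_fraction <- function(a, b) {
  if (!nrow(a)) return(NA_real_)
  overlap_count(a, b) / nrow(a)
}
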