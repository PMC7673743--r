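#' Log2 fusion/Dam occupancy ratio at fragment resolution
#'
#' Both libraries are depth-normalised to counts per million before the
#' ratio is formed, and a pseudocount `psi` keeps every value finite:
#' `log2((cpm_fusion + psi) / (cpm_dam + psi))`. Replicate tracks are kept
#' separate; averaging, where wanted, happens downstream.
#'
#' @param fusion,dam `FragmentCountTrack`s on the same fragment map.
#' @param psi pseudocount added to each cpm (default 1).
#' @return an `OccupancyTrack`: list with per-fragment `values`, the
#'   `condition`, `psi` and the shared `fragmap`.
#' @export
compute_log_ratio <- function(fusion, dam, psi = 1.0) {
  stopifnot(inherits(fusion, "FragmentCountTrack"),
            inherits(dam, "FragmentCountTrack"))
  if (length(fusion$counts) != length(dam$counts) ||
      !identical(fusion$fragmap$start, dam$fragmap$start))
    stopf("fusion and dam tracks use different fragment maps")
  if (fusion$library_size <= 0 || dam$library_size <= 0)
    stopf("both libraries must have positive size")
  if (psi <= 0) stopf("psi must be > 0")
  cpm_f <- fusion$counts * 1e6 / fusion$library_size
  cpm_d <- dam$counts * 1e6 / dam$library_size
  structure(list(condition = fusion$condition,
                 sample_id = fusion$sample_id,
                 values = log2((cpm_f + psi) / (cpm_d + psi)),
                 psi = psi, fragmap = fusion$fragmap),
            class = "OccupancyTrack")
}

#' @export
print.OccupancyTrack <- function(x, ...) {
  cat("OccupancyTrack (", x$condition, "):", length(x$values),
      "fragments, range", sprintf("%.2f..%.2f", min(x$values), max(x$values)), "\n")
  invisible(x)
}

#' 1x genome-normalised accessibility coverage
#'
#' Converts Dam-only fragment counts to per-bp coverage scaled so the mean
#' per-bp coverage over the genome equals exactly 1 (the "1x genome"
#' normalisation used for accessibility read-outs):
#' `value_i = (counts_i / length_i) * genome_length / library_size`.
#'
#' @param dam a Dam-only `FragmentCountTrack`.
#' @param fragmap its fragment map (defaults to the track's own).
#' @return numeric per-fragment coverage vector.
#' @export
normalize_coverage_1x <- function(dam, fragmap = dam$fragmap) {
  if (dam$library_size <= 0) stopf("zero library size")
  fragmap_check(length(dam$counts), fragmap)
  len <- fragmap$end - fragmap$start
  genome_length <- attr(fragmap, "genome_length")
  if (is.null(genome_length)) genome_length <- sum(len)
  (dam$counts / len) * genome_length / dam$library_size
}

#' Mean signal profile around a set of interval centers
#'
#' Samples a per-fragment track in fixed bins across `[mid - W, mid + W)`
#' around the midpoint of every center interval and averages across
#' intervals. Each bin takes the value of the fragment containing the
#' position `mid + offset` (its labelled offset); bins falling off the
#' chromosome are ignored in the mean.
#'
#' @param track an `OccupancyTrack`, or a numeric vector paired with `fragmap`.
#' @param centers data.frame of intervals (`chrom`, `start`, `end`).
#' @param W window half-width in bp.
#' @param b bin size in bp; `2 * W / b` bins are produced.
#' @param fragmap fragment map when `track` is a bare numeric vector.
#' @return a `CoverageProfile`: data.frame with `offset` (bin start relative
#'   to center) and `mean_signal`, plus `n_intervals` attribute.
#' @export
metaprofile <- function(track, centers, W = 2500L, b = 50L, fragmap = NULL) {
  if (inherits(track, "OccupancyTrack")) {
    fragmap <- track$fragmap
    values <- track$values
  } else values <- track
  if (is.null(fragmap)) stopf("fragmap required for a bare numeric track")
  check_intervals(centers, "center")
  if (!nrow(centers)) stopf("centers must be nonempty")
  n_bins <- as.integer(2 * W / b)
  offsets <- -W + (seq_len(n_bins) - 1L) * b
  acc <- numeric(n_bins); nn <- integer(n_bins)
  chrom_len <- tapply(fragmap$end, fragmap$chrom, max)
  for (cn in unique(centers$chrom)) {
    fm_ix <- which(fragmap$chrom == cn)
    if (!length(fm_ix)) next
    bnd <- fragmap$start[fm_ix]
    L <- chrom_len[[cn]]
    mids <- (centers$start[centers$chrom == cn] +
             centers$end[centers$chrom == cn]) %/% 2L
    for (m in mids) {
      pos <- m + offsets
      ok <- pos >= 0L & pos < L
      if (!any(ok)) next
      fi <- findInterval(pos[ok], bnd)
      acc[ok] <- acc[ok] + values[fm_ix[fi]]
      nn[ok] <- nn[ok] + 1L
    }
  }
  prof <- data.frame(offset = offsets,
                     mean_signal = ifelse(nn > 0, acc / pmax(nn, 1L), NA_real_))
  structure(prof, class = c("CoverageProfile", "data.frame"),
            W = W, b = b, n_intervals = nrow(centers))
}
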