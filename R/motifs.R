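#' Robust z scores
#'
#' `z = (x - median) / (1.4826 * MAD)` with MAD the (unscaled) median
#' absolute deviation; the 1.4826 factor makes the scale consistent with
#' the standard deviation under normality. Invariant to positive affine
#' transforms of the input.
#'
#' @param scores numeric vector, length >= 3.
#' @return numeric z scores.
#' @export
robust_z <- function(scores) {
  if (length(scores) < 3L) stopf("need at least 3 scores")
  med <- median(scores)
  m <- mad(scores, constant = 1)
  if (m == 0)
    stopf("MAD is zero; use a fallback dispersion (e.g. IQR or SD)")
  (scores - med) / (1.4826 * m)
}

# reverse-complement of a log-odds PWM (rows A,C,G,T)
pwm_revcomp <- function(pwm) {
  pwm[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm))), drop = FALSE]
}

# scores at every valid start of an integer-coded sequence (N scores 0,
# i.e. as background under log-odds)
score_all_positions <- function(codes, pwm) {
  w <- ncol(pwm)
  Lp <- length(codes) - w + 1L
  if (Lp < 1L) return(numeric(0))
  pwm5 <- rbind(pwm, N = 0)
  s <- numeric(Lp)
  for (j in seq_len(w))
    s <- s + pwm5[cbind(codes[j:(j + Lp - 1L)], j)]
  s
}

#' Scan a genome with a position weight matrix
#'
#' Scores the motif's log-odds at every base position on both strands of
#' every chromosome. Robust z scores are computed against the full
#' distribution of scanned scores (both strands pooled); to bound memory
#' only the top `keep_frac` of positions are retained as hits, but the
#' z transform always reflects the complete scan.
#'
#' @param genome a `GenomeModel`.
#' @param motif a `MotifModel` from [make_motif()] (or any list with a
#'   4 x width log-odds `pwm` with rows A/C/G/T and a `tf_name`).
#' @param keep_frac fraction of top-scoring positions retained (default
#'   0.01; set to 1 to keep every position).
#' @return a `MotifHitTrack` data.frame (`tf_name`, `chrom`, `pos` 0-based,
#'   `strand`, `score`, `z`) with attributes `center`, `scale` (of the
#'   robust transform), `floor_score` and `n_scanned`.
#' @export
scan_motif <- function(genome, motif, keep_frac = 0.01) {
  pwm <- motif$pwm
  stopifnot(is.matrix(pwm), nrow(pwm) == 4L,
            identical(rownames(pwm), c("A", "C", "G", "T")))
  if (any(!is.finite(pwm))) stopf("pwm weights must be finite")
  pwm_rc <- pwm_revcomp(pwm)
  rownames(pwm_rc) <- c("A", "C", "G", "T")
  w <- ncol(pwm)
  chroms <- genome$chromosomes$name
  per <- list(); all_scores <- vector("list", 2L * length(chroms))
  k <- 0L
  for (ci in seq_along(chroms)) {
    L <- genome$chromosomes$length[ci]
    if (w > L) stopf("pwm wider than chromosome %s", chroms[ci])
    codes <- seq_to_codes(genome$seqs[[ci]])
    fwd <- score_all_positions(codes, pwm)
    rev_ <- score_all_positions(codes, pwm_rc)
    k <- k + 1L; all_scores[[k]] <- fwd
    k <- k + 1L; all_scores[[k]] <- rev_
    per[[ci]] <- list(fwd = fwd, rev = rev_)
  }
  pooled <- unlist(all_scores, use.names = FALSE)
  center <- median(pooled)
  scale_ <- 1.4826 * mad(pooled, constant = 1)
  if (scale_ == 0) {
    warning("degenerate score distribution (MAD = 0); z set to 0")
    scale_ <- Inf
  }
  floor_score <- if (keep_frac >= 1) -Inf
                 else unname(quantile(pooled, 1 - keep_frac))
  rows <- list()
  for (ci in seq_along(chroms)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") per[[ci]]$fwd else per[[ci]]$rev
      ix <- which(s >= floor_score)
      if (!length(ix)) next
      rows[[length(rows) + 1L]] <- data.frame(
        tf_name = motif$tf_name, chrom = chroms[ci], pos = ix - 1L,
        strand = strand, score = s[ix],
        z = (s[ix] - center) / scale_, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(tf_name = character(0), chrom = character(0),
                         pos = integer(0), strand = character(0),
                         score = numeric(0), z = numeric(0))
  rownames(out) <- NULL
  structure(out, class = c("MotifHitTrack", "data.frame"),
            center = center, scale = scale_, floor_score = floor_score,
            n_scanned = length(pooled), motif_width = w)
}
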