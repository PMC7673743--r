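#' Promoter windows upstream of the ORF start
#'
#' Strand-aware fixed windows: `[orf_start - width, orf_start)` on the
#' plus strand, `[orf_start, orf_start + width)` on the minus strand,
#' clipped to the chromosome.
#'
#' @param genome a `GenomeModel` with `genes` (`orf_start`, `strand`).
#' @param width window width in bp (default 2000).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
promoter_windows <- function(genome, width = 2000L) {
  g <- genome$genes
  lens <- chrom_lengths(genome)
  plus <- g$strand != "-"
  start <- ifelse(plus, g$orf_start - width, g$orf_start)
  end <- ifelse(plus, g$orf_start, g$orf_start + width)
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = pmax(as.integer(start), 0L),
             end = as.integer(pmin(end, lens[g$chrom])),
             stringsAsFactors = FALSE)
}

# per-gene maximum hit z inside its window (NA if no retained hit)
gene_max_z <- function(hits, windows) {
  out <- setNames(rep(NA_real_, nrow(windows)), windows$gene_id)
  if (!nrow(hits)) return(out)
  for (cn in unique(windows$chrom)) {
    wi <- which(windows$chrom == cn)
    h <- hits[hits$chrom == cn, ]
    if (!nrow(h)) next
    ov <- IRanges::findOverlaps(ir0(h$pos, h$pos + 1L),
                                ir0(windows$start[wi], windows$end[wi]))
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    mx <- tapply(h$z[qh], sh, max)
    out[wi[as.integer(names(mx))]] <- pmax(out[wi[as.integer(names(mx))]],
                                           as.numeric(mx), na.rm = TRUE)
  }
  out
}

#' Build a regulon from motif hits at a z threshold
#'
#' A gene belongs to the regulon iff it has at least one retained hit with
#' `z >= tau` whose start position lies inside its promoter window (either
#' strand).
#'
#' @param hits a `MotifHitTrack`.
#' @param windows promoter windows from [promoter_windows()].
#' @param tau finite z threshold (or -Inf for all genes with any hit).
#' @return a `Regulon` list: `tf_name`, `threshold_z`, `genes`, `curve`.
#' @export
build_regulon <- function(hits, windows, tau) {
  if (is.na(tau)) stopf("tau must not be NA")
  mz <- gene_max_z(hits, windows)
  genes <- names(mz)[!is.na(mz) & mz >= tau]
  structure(list(tf_name = if (nrow(hits)) hits$tf_name[1] else NA_character_,
                 threshold_z = tau, genes = genes, curve = NULL),
            class = "Regulon")
}

#' @export
print.Regulon <- function(x, ...) {
  cat("Regulon", x$tf_name, ": ", length(x$genes), "genes at z >=",
      signif(x$threshold_z, 4), "\n")
  invisible(x)
}

#' Expression-vs-threshold curve and automatic threshold choice
#'
#' For every candidate threshold tau the regulon is formed and the mean,
#' SD and signal score `t(tau) = |mean l2fc| * sqrt(n) / sd` of its
#' members' l2fc are recorded. The selected threshold `tau*` maximises
#' `t(tau)` among thresholds whose regulon keeps at least `n_min` members
#' — an automated stand-in for choosing the point of maximum signal
#' relative to noise by eye; the full curve is returned so the choice can
#' always be overridden.
#'
#' @param hits a `MotifHitTrack`.
#' @param windows promoter windows.
#' @param de a `DETable` covering the gene universe.
#' @param tau_grid ordered numeric grid of candidate thresholds.
#' @param n_min minimum regulon size for an eligible threshold (default 20).
#' @return a `ThresholdCurve` data.frame (`tau`, `n`, `mean_l2fc`,
#'   `sd_l2fc`, `se_l2fc`, `t`) with attribute `tau_star`.
#' @export
threshold_curve <- function(hits, windows, de, tau_grid, n_min = 20L) {
  stopifnot(is.numeric(tau_grid), !is.unsorted(tau_grid))
  mz <- gene_max_z(hits, windows)
  l2fc <- setNames(de$l2fc, de$gene_id)[names(mz)]
  rows <- lapply(tau_grid, function(tau) {
    member <- !is.na(mz) & mz >= tau
    x <- l2fc[member]
    n <- sum(!is.na(x)); x <- x[!is.na(x)]
    m <- if (n) mean(x) else NA_real_
    s <- if (n > 1) sd(x) else NA_real_
    data.frame(tau = tau, n = n, mean_l2fc = m, sd_l2fc = s,
               se_l2fc = if (n > 1) s / sqrt(n) else NA_real_,
               t = if (n > 1 && !is.na(s) && s > 0) abs(m) * sqrt(n) / s else 0)
  })
  curve <- do.call(rbind, rows)
  if (all(curve$n == 0)) stopf("every threshold in the grid yields an empty regulon")
  eligible <- curve$n >= n_min
  if (!any(eligible)) {
    warning("no threshold keeps n >= n_min; relaxing to nonempty regulons")
    eligible <- curve$n > 0
  }
  tau_star <- curve$tau[eligible][which.max(curve$t[eligible])]
  structure(curve, class = c("ThresholdCurve", "data.frame"),
            tau_star = tau_star, n_min = n_min)
}

#' Pairwise Fisher tests of regulon overlap
#'
#' For every unordered pair of regulons a 2x2 table over the gene universe
#' (in both, A only, B only, neither) is tested with a two-sided Fisher
#' exact test; the reported odds ratio is the sample cross-product ratio
#' `ad/bc`. Q-values are BH across all pairs.
#'
#' @param regulons list of `Regulon`s (or named list of gene-id vectors).
#' @param universe character vector: the gene universe.
#' @return data.frame with `tf_a`, `tf_b`, `in_both`, `a_only`, `b_only`,
#'   `neither`, `odds_ratio`, `p`, `q`.
#' @export
regulon_overlap_tests <- function(regulons, universe) {
  if (!length(universe)) stopf("empty gene universe")
  sets <- lapply(regulons, function(r) {
    g <- if (inherits(r, "Regulon")) r$genes else r
    intersect(g, universe)
  })
  nm <- names(sets)
  if (is.null(nm)) nm <- vapply(regulons, function(r)
    if (inherits(r, "Regulon")) r$tf_name else NA_character_, character(1))
  if (length(sets) < 2L) stopf("need at least two regulons")
  prs <- utils::combn(seq_along(sets), 2L)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    i <- prs[1, k]; j <- prs[2, k]
    A <- universe %in% sets[[i]]; B <- universe %in% sets[[j]]
    a <- sum(A & B); b <- sum(A & !B); c_ <- sum(!A & B); d <- sum(!A & !B)
    or <- if (b * c_ > 0) (a * d) / (b * c_)
          else if (a * d > 0) Inf else NaN
    p <- fisher.test(matrix(c(a, b, c_, d), 2L))$p.value
    data.frame(tf_a = nm[i], tf_b = nm[j], in_both = a, a_only = b,
               b_only = c_, neither = d, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}
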