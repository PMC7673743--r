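#' Shuffle intervals uniformly within their own chromosomes
#'
#' Each interval keeps its length and chromosome and receives an
#' independent uniform start on the valid range; overlaps among shuffled
#' intervals are permitted.
#'
#' @param intervals interval data.frame.
#' @param genome a `GenomeModel` (chromosome lengths), or a named vector of
#'   chromosome lengths.
#' @param seed optional integer seed.
#' @return data.frame of shuffled intervals.
#' @export
shuffle_intervals <- function(intervals, genome, seed = NULL) {
  check_intervals(intervals)
  if (!is.null(seed)) set.seed(seed)
  lens <- chrom_lengths(genome)
  L <- lens[intervals$chrom]
  w <- intervals$end - intervals$start
  if (any(is.na(L))) stopf("interval on unknown chromosome")
  if (any(w > L)) stopf("interval longer than its chromosome")
  new_start <- floor(runif(nrow(intervals), min = 0, max = L - w + 1))
  out <- intervals
  out$start <- as.integer(new_start)
  out$end <- as.integer(new_start + w)
  out
}

chrom_lengths <- function(genome) {
  if (is.numeric(genome)) return(genome)
  setNames(genome$chromosomes$length, genome$chromosomes$name)
}

#' Count query intervals overlapping a reference set
#'
#' @param query,reference interval data.frames.
#' @return integer: number of query intervals overlapping >= 1 bp of any
#'   reference interval.
#' @export
overlap_count <- function(query, reference) {
  if (!nrow(query) || !nrow(reference)) return(0L)
  n <- 0L
  for (cn in unique(query$chrom)) {
    q <- query[query$chrom == cn, ]
    r <- reference[reference$chrom == cn, ]
    if (!nrow(r)) next
    n <- n + sum(IRanges::overlapsAny(ir0(q$start, q$end), ir0(r$start, r$end)))
  }
  n
}

#' Monte Carlo permutation enrichment of interval overlaps
#'
#' Compares the observed number of query intervals overlapping the
#' reference with the counts obtained after placing the *query* uniformly
#' at random on its own chromosomes `n_shuffles` times. The empirical
#' p-value uses the add-one rule and is one-sided for enrichment
#' (mirrored for depletion in `p_depletion`).
#'
#' @param query,reference interval data.frames (both nonempty).
#' @param genome a `GenomeModel` or named chromosome-length vector.
#' @param n_shuffles number of random placements (default 1000).
#' @param seed integer seed.
#' @return an `EnrichmentResult` list: `observed`, `null_mean`, `null_sd`,
#'   `fold`, `p_empirical`, `p_depletion`, `n_shuffles`, `seed`.
#' @export
permutation_enrichment <- function(query, reference, genome,
                                   n_shuffles = 1000L, seed = 1L) {
  if (!nrow(query) || !nrow(reference)) stopf("query and reference must be nonempty")
  if (n_shuffles < 1L) stopf("n_shuffles must be >= 1")
  observed <- overlap_count(query, reference)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_shuffles), function(i)
    overlap_count(shuffle_intervals(query, genome), reference), numeric(1))
  null_mean <- mean(null_counts)
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = sd(null_counts),
                 fold = if (null_mean > 0) observed / null_mean else Inf,
                 p_empirical = (1 + sum(null_counts >= observed)) / (1 + n_shuffles),
                 p_depletion = (1 + sum(null_counts <= observed)) / (1 + n_shuffles),
                 n_shuffles = n_shuffles, seed = seed),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: observed %d, null %.2f +/- %.2f, fold %.2f, p = %.4g (%d shuffles)\n",
              x$observed, x$null_mean, x$null_sd, x$fold, x$p_empirical,
              x$n_shuffles))
  invisible(x)
}

#' High-confidence PREs of one class
#'
#' @param genome a `GenomeModel` with a `pres` table.
#' @param pre_class class to select, or NULL for all classes.
#' @param min_confidence minimum prediction confidence (default 0.8).
#' @return interval data.frame.
#' @export
select_pres <- function(genome, pre_class = NULL, min_confidence = 0.8) {
  p <- genome$pres
  keep <- p$confidence >= min_confidence
  if (!is.null(pre_class)) keep <- keep & p$pre_class %in% pre_class
  p[keep, , drop = FALSE]
}

#' Observed/expected gene proportions across chromatin states
#'
#' Each gene is assigned the chromatin state at its transcription start
#' site; the proportion of bound genes in each state is divided by the
#' genome-wide proportion of genes in that state.
#'
#' @param bound_genes character vector of bound gene ids.
#' @param genome a `GenomeModel` with `chromatin_states`.
#' @return a `StateProportionTable` data.frame: `state`, `observed`,
#'   `expected`, `ratio`; attribute `n_excluded` counts genes without a
#'   state.
#' @export
chromatin_state_proportions <- function(bound_genes, genome) {
  genes <- genome$genes
  tss <- ifelse(genes$strand != "-", genes$start, genes$end - 1L)
  st <- genome$chromatin_states
  state_of <- rep(NA_character_, nrow(genes))
  for (cn in unique(genes$chrom)) {
    gi <- which(genes$chrom == cn)
    si <- which(st$chrom == cn)
    if (!length(si)) next
    ov <- IRanges::findOverlaps(ir0(tss[gi], tss[gi] + 1L),
                                ir0(st$start[si], st$end[si]))
    state_of[gi[S4Vectors::queryHits(ov)]] <- st$state[si[S4Vectors::subjectHits(ov)]]
  }
  n_excluded <- sum(is.na(state_of))
  if (n_excluded > 0)
    warning(sprintf("%d gene(s) without a chromatin state excluded", n_excluded))
  states <- c("red", "yellow", "blue", "green", "black")
  all_tab <- table(factor(state_of, levels = states))
  bound_state <- state_of[genes$gene_id %in% bound_genes]
  bound_tab <- table(factor(bound_state, levels = states))
  observed <- as.numeric(bound_tab) / max(sum(bound_tab), 1L)
  expected <- as.numeric(all_tab) / max(sum(all_tab), 1L)
  structure(data.frame(state = states, observed = observed, expected = expected,
                       ratio = ifelse(expected > 0, observed / expected, NA_real_),
                       stringsAsFactors = FALSE),
            class = c("StateProportionTable", "data.frame"),
            n_excluded = n_excluded)
}
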