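#' Moment skewness of a log fold-change distribution
#'
#' Skewness is computed from the second and third central moments with
#' denominator n and no bias correction:
#' `skewness = m3 / m2^(3/2)`, `m_r = sum((x - mean)^r) / n`. A long
#' negative tail (widespread repression) gives negative skewness. Intended
#' to be run over all detected genes, not only significant ones.
#'
#' @param values numeric l2fc values (NA dropped), length >= 3.
#' @return a `SkewnessReport` list: `n`, `m2`, `m3`, `skewness`.
#' @export
l2fc_skewness <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 3L) stopf("need at least 3 values")
  mu <- mean(x)
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  if (m2 == 0) stopf("skewness undefined for constant input (m2 = 0)")
  structure(list(n = n, m2 = m2, m3 = m3, skewness = m3 / m2^1.5),
            class = "SkewnessReport")
}

#' @export
print.SkewnessReport <- function(x, ...) {
  cat(sprintf("SkewnessReport: n = %d, skewness = %.3f (m2 = %.4g, m3 = %.4g)\n",
              x$n, x$skewness, x$m2, x$m3))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_i = min over {j : p_j >= p_i} of
#' p_j * m / rank_j`, capped at 1.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return numeric q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must be in [0, 1] with no NAs")
  p.adjust(pvalues, method = "BH")
}

#' Practical-equivalence ("significantly unchanged") test
#'
#' Tests, per gene, the composite null of a true change of at least
#' `fold_bound`-fold in either direction, against the alternative that the
#' true l2fc lies inside the region of practical equivalence
#' `(-Delta, Delta)` with `Delta = log2(fold_bound)`. Under the normality
#' assumption on the l2fc estimate with its gene-wise SE this is the
#' two-one-sided-tests (TOST) max-p:
#' `p = max(Phi((l2fc - Delta)/se), Phi((-l2fc - Delta)/se))`.
#' Rejection is positive evidence the gene is *not* substantially changed.
#'
#' @param table a `DETable` data.frame with `l2fc` and `se` (and `gene_id`).
#' @param fold_bound equivalence bound as a fold change (> 1; default 1.5).
#' @param alpha_q BH q cutoff for the `unchanged` flag (default 0.1).
#' @return an `EquivalenceResult` data.frame: `gene_id`, `l2fc`, `se`,
#'   `p_equiv`, `q_equiv`, `unchanged`; attribute `rope_l2fc` = Delta.
#' @export
equivalence_test <- function(table, fold_bound = 1.5, alpha_q = 0.1) {
  if (fold_bound <= 1) stopf("fold_bound must be > 1")
  stopifnot(all(c("l2fc", "se") %in% names(table)))
  bad <- which(!is.finite(table$se) | table$se <= 0)
  if (length(bad))
    stopf("nonpositive SE for gene(s): %s",
          paste(head(if (!is.null(table$gene_id)) table$gene_id[bad] else bad, 5L),
                collapse = ", "))
  delta <- log2(fold_bound)
  p_equiv <- pmax(pnorm((table$l2fc - delta) / table$se),
                  pnorm((-table$l2fc - delta) / table$se))
  q_equiv <- bh_fdr(p_equiv)
  out <- data.frame(gene_id = if (!is.null(table$gene_id)) table$gene_id
                    else seq_len(nrow(table)),
                    l2fc = table$l2fc, se = table$se,
                    p_equiv = p_equiv, q_equiv = q_equiv,
                    unchanged = q_equiv < alpha_q, stringsAsFactors = FALSE)
  structure(out, class = c("EquivalenceResult", "data.frame"),
            rope_l2fc = delta, alpha_q = alpha_q)
}

#' Per-gene IP/input enrichment
#'
#' Log2 ratio of cpm-normalised immunoprecipitate over input with a
#' pseudocount; positive values flag cell-type enrichment, negative
#' depletion.
#'
#' @param ip_counts,input_counts named numeric vectors over the same gene
#'   universe.
#' @param psi pseudocount added to each cpm.
#' @return data.frame with `gene_id`, `log2_enrichment`, `status`.
#' @export
ip_input_enrichment <- function(ip_counts, input_counts, psi = 1) {
  if (is.null(names(ip_counts)) || is.null(names(input_counts)) ||
      !setequal(names(ip_counts), names(input_counts)) ||
      length(ip_counts) != length(input_counts))
    stopf("IP and input must share one gene universe")
  input_counts <- input_counts[names(ip_counts)]
  if (sum(ip_counts) <= 0 || sum(input_counts) <= 0)
    stopf("library sizes must be positive")
  cpm_ip <- ip_counts * 1e6 / sum(ip_counts)
  cpm_in <- input_counts * 1e6 / sum(input_counts)
  le <- log2((cpm_ip + psi) / (cpm_in + psi))
  data.frame(gene_id = names(ip_counts), log2_enrichment = unname(le),
             status = ifelse(le > 0, "enriched",
                             ifelse(le < 0, "depleted", "neutral")),
             stringsAsFactors = FALSE)
}

#' Equally populated rank bins
#'
#' Assigns each value to one of `k` bins by rank so that bin sizes differ
#' by at most one; ties are broken by stable input order.
#'
#' @param values numeric vector (length >= k).
#' @param k number of bins (default 7).
#' @return integer bin index per value, 1 (lowest) .. k (highest).
#' @export
bin_equally_populated <- function(values, k = 7L) {
  if (k <= 0L) stopf("k must be positive")
  n <- length(values)
  if (n < k) stopf("need at least k values")
  rk <- integer(n)
  rk[order(values)] <- seq_len(n)   # order() is stable for ties
  as.integer(ceiling(rk * k / n))
}

#' Wald z differential test for synthetic tables
#'
#' Fallback per-gene test `z = l2fc / se`, two-sided normal p, used only
#' for generator-made tables; real DE fits are consumed, not refitted.
#'
#' @param table data.frame with `l2fc` and `se`.
#' @return the table with `p` and `q` (BH) columns replaced.
#' @export
wald_de <- function(table) {
  z <- table$l2fc / table$se
  table$p <- 2 * pnorm(-abs(z))
  table$q <- bh_fdr(table$p)
  table
}
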