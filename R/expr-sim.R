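#' Simulate differential-expression result tables
#'
#' Emulates the per-gene summary a count-based DE fit would report, without
#' refitting it: the observed l2fc is the true planted l2fc plus
#' `Normal(0, SE_g)` noise, with gene-wise standard errors drawn from
#' `SE_g = se_scale * (0.1 + 0.2 * Exponential(1))` — a positive family
#' whose right tail mimics low-count genes. P-values are two-sided normal
#' tests of l2fc against 0 (a Wald z), q-values Benjamini-Hochberg.
#'
#' Two contrasts are produced: `SD_vs_CD` carries the planted regulon
#' repression; `PclSD_vs_CD` emulates the mutant in which every true
#' effect is abolished (true l2fc identically 0).
#'
#' @param genome a `GenomeModel`.
#' @param truth the matching `SimTruth` (uses `true_l2fc`).
#' @param config the [sim_config()] used.
#' @param se_floor set `se_scale = 0` in the config for the noise-free limit.
#' @return named list of `DETable` data.frames with columns `gene_id`,
#'   `base_mean`, `l2fc`, `se`, `p`, `q`.
#' @export
simulate_expression_tables <- function(genome, truth, config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "expression"))
  gene_id <- genome$genes$gene_id
  n <- length(gene_id)
  base_mean <- rlnorm(n, meanlog = 4, sdlog = 1)
  contrasts <- list(SD_vs_CD = truth$true_l2fc[gene_id],
                    PclSD_vs_CD = setNames(numeric(n), gene_id))
  lapply(contrasts, function(mu) {
    se <- config$se_scale * (0.1 + 0.2 * rexp(n))
    l2fc <- mu + if (config$se_scale > 0) rnorm(n, 0, se) else 0
    z <- ifelse(se > 0, l2fc / se, ifelse(l2fc == 0, 0, Inf * sign(l2fc)))
    p <- 2 * pnorm(-abs(z))
    structure(data.frame(gene_id = gene_id, base_mean = base_mean,
                         l2fc = l2fc, se = se, p = p, q = bh_fdr(p),
                         stringsAsFactors = FALSE),
              class = c("DETable", "data.frame"))
  })
}
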