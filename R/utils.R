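#' @importFrom stats median pnorm quantile rnorm rpois rexp runif rlnorm sd
#'   fisher.test p.adjust setNames mad
#' @importFrom utils head tail write.table read.delim
NULL

# All genomic coordinates in this package are 0-based half-open [start, end),
# as in BED/bedGraph.  These helpers convert to/from the 1-based closed
# IRanges convention used internally for interval algebra.

ir0 <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

df0 <- function(ir, chrom = NULL) {
  out <- data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  if (!is.null(chrom)) out <- cbind(chrom = chrom, out)
  out
}

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(x$start >= x$end)
  if (length(bad))
    stopf("malformed %s(s) with start >= end at rows: %s", what,
          paste(head(bad, 5L), collapse = ", "))
  invisible(x)
}

# Split interval data.frame into a per-chromosome list of IRanges
split_ir0 <- function(x) {
  lapply(split(x, x$chrom), function(d) ir0(d$start, d$end))
}

#' Derive a deterministic per-stage seed from a global seed
#'
#' Stage seeds are a fixed arithmetic function of the global seed and the
#' stage name so that re-running any stage in isolation reproduces the
#' pipeline's stream. Kept below 2^31 - 1.
#'
#' @param seed integer global seed
#' @param stage character stage name
#' @return integer seed
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
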