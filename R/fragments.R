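#' Build the GATC fragment map of a genome
#'
#' DamID signal is natively resolved on the fragments between consecutive
#' GATC motifs. Fragment boundaries are placed at the *start* coordinate of
#' every GATC occurrence (forward scan; the motif is its own reverse
#' complement, so one strand suffices), plus the chromosome ends, so that
#' fragments tile each chromosome exactly with no gaps or overlaps. A
#' chromosome with no GATC yields the single fragment [0, L).
#'
#' @param genome a `GenomeModel` (or any list with `chromosomes` and `seqs`).
#' @return a `GATCFragmentMap`: data.frame with columns `fragment_id`
#'   (1-based global integer), `chrom`, `start`, `end` (0-based half-open),
#'   plus a `genome_length` attribute.
#' @export
build_gatc_fragment_map <- function(genome) {
  chroms <- genome$chromosomes
  out <- vector("list", nrow(chroms))
  for (ci in seq_len(nrow(chroms))) {
    s <- genome$seqs[[ci]]
    L <- chroms$length[ci]
    if (L == 0L) stopf("chromosome %s has empty sequence", chroms$name[ci])
    b <- Biostrings::start(Biostrings::matchPattern("GATC", s)) - 1L
    starts <- c(0L, b)
    ends <- c(b, L)
    keep <- starts < ends        # a GATC at position 0 would duplicate [0,..)
    out[[ci]] <- data.frame(chrom = chroms$name[ci],
                            start = starts[keep], end = ends[keep],
                            stringsAsFactors = FALSE)
  }
  fm <- do.call(rbind, out)
  fm <- cbind(fragment_id = seq_len(nrow(fm)), fm)
  rownames(fm) <- NULL
  structure(fm, class = c("GATCFragmentMap", "data.frame"),
            genome_length = sum(chroms$length))
}

fragmap_check <- function(a_n, fragmap) {
  if (a_n != nrow(fragmap))
    stopf("track length (%d) does not match fragment map (%d fragments)",
          a_n, nrow(fragmap))
}

#' Assign sequencing read starts to GATC fragments
#'
#' Each read is extended 3'-ward from its start position to `max_ext` bp or
#' to the closest GATC boundary past the start in read orientation,
#' whichever comes first; every fragment overlapped by the extended read is
#' incremented. Plus-strand reads extend rightward from `start`; minus-strand
#' reads occupy their start base and extend leftward to the largest boundary
#' at or before it. Unstranded input is treated as plus.
#'
#' @param reads data.frame with columns `chrom`, `start` (0-based) and
#'   optionally `strand` ("+"/"-").
#' @param fragmap a [build_gatc_fragment_map()] result.
#' @param max_ext maximum extension in bp (default 300).
#' @param sample_id,condition,construct metadata carried on the track.
#' @return a `FragmentCountTrack`: list with `counts` (integer per
#'   fragment), `library_size`, metadata, and the `fragmap`.
#' @export
assign_reads_to_fragments <- function(reads, fragmap, max_ext = 300L,
                                      sample_id = "sample", condition = NA,
                                      construct = NA) {
  stopifnot(is.data.frame(reads), all(c("chrom", "start") %in% names(reads)))
  if (is.null(reads$strand)) reads$strand <- "+"
  bad <- !reads$chrom %in% unique(fragmap$chrom)
  if (any(bad))
    stopf("unknown chromosome(s) in reads at rows: %s",
          paste(head(which(bad), 5L), collapse = ", "))
  counts <- integer(nrow(fragmap))
  for (cn in unique(reads$chrom)) {
    fm <- fragmap[fragmap$chrom == cn, ]
    r <- reads[reads$chrom == cn, ]
    if (any(r$start < 0L | r$start >= fm$end[nrow(fm)]))
      stopf("read start outside chromosome bounds on %s", cn)
    bnd <- fm$start                       # fragment left boundaries, first is 0
    # fragment index containing each read start
    fi <- findInterval(r$start, bnd)
    plus <- r$strand != "-"
    lo <- hi <- integer(nrow(r))
    # plus: [start, min(start+max_ext, next boundary after start))
    nxt <- ifelse(fi < nrow(fm), c(bnd[-1], fm$end[nrow(fm)])[fi], fm$end[nrow(fm)])
    lo[plus] <- r$start[plus]
    hi[plus] <- pmin(r$start[plus] + max_ext, nxt[plus])
    # minus: [max(start+1-max_ext, boundary at/before start), start+1)
    lo[!plus] <- pmax(r$start[!plus] + 1L - max_ext, bnd[fi[!plus]])
    hi[!plus] <- r$start[!plus] + 1L
    i1 <- findInterval(lo, bnd)
    i2 <- findInterval(pmax(hi - 1L, lo), bnd)
    for (k in seq_len(nrow(r))) {
      idx <- fm$fragment_id[i1[k]:i2[k]]
      counts[idx] <- counts[idx] + 1L
    }
  }
  structure(list(sample_id = sample_id, condition = condition,
                 construct = construct, counts = counts,
                 library_size = sum(counts), fragmap = fragmap),
            class = "FragmentCountTrack")
}

#' @export
print.FragmentCountTrack <- function(x, ...) {
  cat("FragmentCountTrack", x$sample_id, "(", x$construct, ",", x$condition,
      "):", length(x$counts), "fragments,", x$library_size, "reads\n")
  invisible(x)
}
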