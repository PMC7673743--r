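# Plain-format writers for stage artifacts. Everything is standard text
# (FASTA / GFF3 / BED / bedGraph / TSV) so any stage can be re-run on real
# data produced elsewhere.

#' Write the genome as FASTA
#' @param genome a `GenomeModel`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path)
  invisible(path)
}

#' Write gene annotation as GFF3 (1-based closed, per the standard)
#' @param genome a `GenomeModel`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genes_gff3 <- function(genome, path) {
  g <- genome$genes
  lines <- c("##gff-version 3",
             sprintf("%s\ttadaregulon\tgene\t%d\t%d\t.\t%s\t.\tID=%s;orf_start=%d",
                     g$chrom, g$start + 1L, g$end, g$strand, g$gene_id,
                     g$orf_start + 1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write an interval table as BED (optionally with extra columns)
#' @param intervals data.frame with `chrom`, `start`, `end` plus extras.
#' @param path output path.
#' @param extra character vector of extra column names to append.
#' @return the path, invisibly.
#' @export
write_bed <- function(intervals, path, extra = setdiff(names(intervals),
                                                       c("chrom", "start", "end"))) {
  d <- intervals[, c("chrom", "start", "end", extra), drop = FALSE]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write an occupancy track as bedGraph (0-based half-open)
#' @param track an `OccupancyTrack` (or numeric vector with `fragmap`).
#' @param path output path.
#' @param fragmap fragment map for bare numeric tracks.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(track, path, fragmap = NULL) {
  if (inherits(track, "OccupancyTrack")) {
    fragmap <- track$fragmap; values <- track$values
  } else values <- track
  d <- data.frame(fragmap$chrom, fragmap$start, fragmap$end,
                  signif(values, 6))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write fragment counts as TSV (fragment_id, chrom, start, end, count)
#' @param track a `FragmentCountTrack`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_counts_tsv <- function(track, path) {
  d <- cbind(track$fragmap[, c("fragment_id", "chrom", "start", "end")],
             count = track$counts)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fragment count TSV back into a `FragmentCountTrack`
#' @param path TSV written by [write_counts_tsv()].
#' @param sample_id,condition,construct metadata for the track.
#' @return a `FragmentCountTrack`.
#' @export
read_counts_tsv <- function(path, sample_id = basename(path),
                            condition = NA, construct = NA) {
  d <- read.delim(path)
  fragmap <- structure(d[, c("fragment_id", "chrom", "start", "end")],
                       class = c("GATCFragmentMap", "data.frame"),
                       genome_length = sum(tapply(d$end, d$chrom, max)))
  structure(list(sample_id = sample_id, condition = condition,
                 construct = construct, counts = as.integer(d$count),
                 library_size = sum(d$count), fragmap = fragmap),
            class = "FragmentCountTrack")
}

#' Write a DE table as TSV
#' @param de a `DETable` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_de_tsv <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
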