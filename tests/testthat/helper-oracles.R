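# Shared fixtures and independent brute-force oracles.  Every oracle here
# is deliberately naive (string search, O(n*m) loops, hand-rolled step-up)
# so it checks the implementation by a different route.

# --- fixtures ---------------------------------------------------------------

# a GenomeModel wrapped around explicit sequences, without the simulator
toy_genome <- function(seqs, genes = NULL) {
  seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("chr", seq_along(seqs))
  if (is.null(genes))
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), orf_start = integer(0),
                        expressed = logical(0))
  list(chromosomes = data.frame(name = names(seqs),
                                length = Biostrings::width(seqs),
                                stringsAsFactors = FALSE),
       seqs = seqs, genes = genes)
}

# fragment-count track with given counts on a given fragment map
toy_track <- function(counts, fragmap, construct = "Dam", condition = "CD",
                      sample_id = "toy") {
  structure(list(sample_id = sample_id, condition = condition,
                 construct = construct, counts = as.integer(counts),
                 library_size = sum(counts), fragmap = fragmap),
            class = "FragmentCountTrack")
}

# occupancy track directly from values
toy_occupancy <- function(values, fragmap, condition = "CD") {
  structure(list(condition = condition, sample_id = "toy", values = values,
                 psi = 1, fragmap = fragmap),
            class = "OccupancyTrack")
}

# a fragment map of n equal fragments of width w on one chromosome
flat_fragmap <- function(n, w = 100L, chrom = "chr1") {
  structure(data.frame(fragment_id = seq_len(n), chrom = chrom,
                       start = (seq_len(n) - 1L) * w, end = seq_len(n) * w,
                       stringsAsFactors = FALSE),
            class = c("GATCFragmentMap", "data.frame"),
            genome_length = n * w)
}

random_intervals <- function(n, L = 10000L, chrom = "chr1", max_len = 300L) {
  s <- sample.int(L - max_len, n, replace = TRUE) - 1L
  w <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = chrom, start = s, end = s + w)
}

small_sim <- function(seed = 3, ...) {
  args <- list(seed = seed, n_chroms = 1L, chrom_length_bp = 100000L,
               n_genes = 40L, n_peaks_shared = 3L, n_peaks_gained = 3L,
               n_peaks_lost = 3L, n_tfs = 2L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# --- oracles ----------------------------------------------------------------

# substring count by regex lookahead-free scan on the raw character string
oracle_gatc_starts <- function(seq_string) {
  hits <- integer(0); from <- 1L
  repeat {
    m <- regexpr("GATC", substr(seq_string, from, nchar(seq_string)), fixed = TRUE)
    if (m == -1L) break
    hits <- c(hits, from + m - 1L)
    from <- from + m            # allow overlapping (GATC cannot overlap itself)
  }
  hits - 1L                     # 0-based
}

# O(reads x fragments) interval-overlap read assignment
oracle_assign <- function(reads, fragmap, max_ext = 300L) {
  counts <- integer(nrow(fragmap))
  for (k in seq_len(nrow(reads))) {
    fm <- fragmap[fragmap$chrom == reads$chrom[k], ]
    bnd <- fm$start
    s <- reads$start[k]
    if (is.null(reads$strand) || reads$strand[k] != "-") {
      nb <- bnd[bnd > s]
      hi <- min(s + max_ext, if (length(nb)) nb[1] else fm$end[nrow(fm)],
                fm$end[nrow(fm)])
      lo <- s
    } else {
      pb <- bnd[bnd <= s]
      lo <- max(s + 1L - max_ext, pb[length(pb)])
      hi <- s + 1L
    }
    for (j in seq_len(nrow(fm)))
      if (fm$start[j] < hi && fm$end[j] > lo)
        counts[fm$fragment_id[j]] <- counts[fm$fragment_id[j]] + 1L
  }
  counts
}

# boolean-mask union of intervals on one small chromosome
oracle_merge_mask <- function(intervals, L) {
  mask <- logical(L)
  for (k in seq_len(nrow(intervals)))
    mask[(intervals$start[k] + 1):intervals$end[k]] <- TRUE
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values] - 1L, end = ends[r$values])
}

# O(n*m) any-overlap count
oracle_overlap_count <- function(query, reference) {
  n <- 0L
  for (i in seq_len(nrow(query))) {
    hit <- FALSE
    for (j in seq_len(nrow(reference)))
      if (query$chrom[i] == reference$chrom[j] &&
          query$start[i] < reference$end[j] &&
          query$end[i] > reference$start[j]) { hit <- TRUE; break }
    n <- n + hit
  }
  n
}

# per-position log-odds score, naive loop
oracle_pwm_score <- function(seq_string, pwm, pos0) {
  letters_ <- strsplit(seq_string, "")[[1]]
  s <- 0
  for (j in seq_len(ncol(pwm))) {
    l <- letters_[pos0 + j]
    s <- s + if (l == "N") 0 else pwm[l, j]
  }
  unname(s)
}

# hand-rolled BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m); out[o] <- q
  out
}
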