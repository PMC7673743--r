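ALPHABET <- c("A", "C", "G", "T")
GATC_CODES <- c(3L, 1L, 4L, 2L)  # G, A, T, C

codes_to_seq <- function(x) Biostrings::DNAString(paste(ALPHABET[x], collapse = ""))

seq_to_codes <- function(s) {
  v <- utf8ToInt(as.character(s))
  code <- integer(128)
  code[utf8ToInt("ACGTN")] <- c(1L, 2L, 3L, 4L, 5L)
  out <- code[v]
  if (any(out == 0L)) stopf("sequence alphabet outside ACGTN")
  out
}

# 0-based start positions of GATC in an integer-coded sequence
find_gatc_codes <- function(x) {
  L <- length(x)
  if (L < 4L) return(integer(0))
  i <- seq_len(L - 3L)
  which(x[i] == 3L & x[i + 1L] == 1L & x[i + 2L] == 4L & x[i + 3L] == 2L) - 1L
}

# Destroy every GATC occurrence whose footprint is not fully wanted,
# never touching bases inside `protected` (0-based half-open intervals).
scrub_gatc <- function(x, protected = NULL) {
  prot <- logical(length(x))
  if (!is.null(protected) && nrow(protected)) {
    for (r in seq_len(nrow(protected)))
      prot[(protected$start[r] + 1L):protected$end[r]] <- TRUE
  }
  for (iter in 1:20) {
    occ <- find_gatc_codes(x)
    if (!length(occ)) return(x)
    for (p in occ) {
      idx <- (p + 1L):(p + 4L)           # 1-based footprint
      free <- idx[!prot[idx]]
      if (!length(free)) stopf("GATC occurrence fully inside protected motif")
      j <- free[1L]
      x[j] <- (x[j] %% 4L) + 1L          # cycle to a different base
    }
  }
  stopf("scrub_gatc failed to converge")
}

#' Build a position weight matrix from a consensus sequence
#'
#' Log-odds weights (log2 of base probability over background) with the
#' consensus base at probability `p_match` and the remaining probability
#' split evenly. An exact consensus match therefore attains the maximal
#' score, and each mismatch costs a fixed, large penalty.
#'
#' @param consensus character consensus, alphabet ACGT.
#' @param tf_name transcription factor name.
#' @param p_match probability mass on the consensus base per column.
#' @param background background base frequencies (must sum to 1).
#' @return a `MotifModel`: list with `tf_name`, `pwm` (4 x width log-odds
#'   matrix, rows A/C/G/T), `background`, `consensus`.
#' @export
make_motif <- function(consensus, tf_name, p_match = 0.91,
                       background = rep(0.25, 4)) {
  stopifnot(abs(sum(background) - 1) < 1e-8)
  codes <- seq_to_codes(consensus)
  if (any(codes > 4L)) stopf("consensus must be ACGT only")
  w <- length(codes)
  probs <- matrix((1 - p_match) / 3, nrow = 4, ncol = w,
                  dimnames = list(ALPHABET, NULL))
  probs[cbind(codes, seq_len(w))] <- p_match
  pwm <- log2(probs / background)
  structure(list(tf_name = tf_name, pwm = pwm, background = background,
                 consensus = toupper(consensus)),
            class = "MotifModel")
}

# random width-w consensus containing no GATC substring
random_consensus <- function(w) {
  repeat {
    codes <- sample.int(4L, w, replace = TRUE)
    if (!length(find_gatc_codes(codes))) return(paste(ALPHABET[codes], collapse = ""))
  }
}

#' Simulate a toy genome with planted ground truth
#'
#' Builds a multi-chromosome genome whose statistical structure matches
#' what the downstream occupancy and regulon analyses assume: i.i.d.
#' uniform background sequence with GATC sites planted as a Poisson
#' process (the background is scrubbed of spontaneous GATCs so the
#' fragment structure is exactly controlled); non-overlapping genes laid
#' out in equal slots with a 2-kb promoter upstream of the ORF start;
#' occupancy peaks planted as runs of 5-8 consecutive GATC fragments over
#' host genes, classed as shared between conditions, gained on SD, or
#' lost on SD; PRE-like intervals centered on most peaks plus random
#' background PREs; a five-colour chromatin-state tiling in which
#' peak-host gene slots are "blue" (Polycomb) chromatin; and five TF
#' motifs whose consensus sites are planted in the promoters of their
#' true regulon members, driving a planted negative log2 fold change.
#'
#' Each TF's achieved planted z threshold (the robust z of its consensus
#' score against the genome-wide score background) is recorded in the
#' returned truth for parameter-recovery checks.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (a `GenomeModel`) and `truth`
#'   (a `SimTruth`). All coordinates 0-based half-open.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "genome"))

  n_chroms <- config$n_chroms
  L <- config$chrom_length_bp
  chrom_names <- paste0("chr", seq_len(n_chroms))
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = n_chroms + 1)))

  promoter_w <- 2000L
  margin <- 50L
  slot_min <- margin + promoter_w + 450L

  codes <- list(); genes_l <- list(); slots_l <- list()
  for (ci in seq_len(n_chroms)) {
    n_per <- per_chrom[ci]
    x <- sample.int(4L, L, replace = TRUE)
    x <- scrub_gatc(x)
    codes[[ci]] <- x
    if (n_per == 0L) { slots_l[[ci]] <- integer(0); next }
    slot <- L %/% n_per
    if (slot < slot_min)
      stopf("chromosome %s too short for %d genes (need >= %d bp each)",
            chrom_names[ci], n_per, slot_min)
    slot_starts <- (seq_len(n_per) - 1L) * slot
    glen <- sample(300:440, n_per, replace = TRUE)
    strand <- sample(c("+", "-"), n_per, replace = TRUE)
    gstart <- ifelse(strand == "+", slot_starts + margin + promoter_w,
                     slot_starts + margin)
    gend <- gstart + glen
    orf <- ifelse(strand == "+", gstart, gend - 1L)
    genes_l[[ci]] <- data.frame(
      chrom = chrom_names[ci], strand = strand,
      start = as.integer(gstart), end = as.integer(gend),
      orf_start = as.integer(orf), slot_start = as.integer(slot_starts),
      slot_end = as.integer(pmin(slot_starts + slot, L)),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes_l)
  if (is.null(genes)) genes <- data.frame(chrom = character(0), strand = character(0),
                                          start = integer(0), end = integer(0),
                                          orf_start = integer(0), slot_start = integer(0),
                                          slot_end = integer(0))
  n_genes <- nrow(genes)
  if (n_genes) {
    genes$gene_id <- sprintf("gene_%04d", seq_len(n_genes))
    genes$expressed <- runif(n_genes) < 0.8
  } else {
    genes$gene_id <- character(0); genes$expressed <- logical(0)
  }

  ## --- true regulons and expression effects -------------------------------
  n_pool <- round((1 - config$frac_null) * n_genes)
  pool <- if (n_pool > 0) sample(genes$gene_id, n_pool) else character(0)
  tf_names <- paste0("TF", seq_len(config$n_tfs))
  true_regulons <- setNames(vector("list", config$n_tfs), tf_names)
  if (config$n_tfs > 0 && n_pool > 0) {
    # changed genes sit in ~2 overlapping regulons: the TF network acts
    # collectively, and the regulon union covers the changed set
    n_member <- pmin(ifelse(runif(n_pool) < 0.25, 3L, 2L), config$n_tfs)
    for (i in seq_len(n_pool)) {
      tfs <- sample.int(config$n_tfs, n_member[i])
      for (t in tfs) true_regulons[[t]] <- c(true_regulons[[t]], pool[i])
    }
  }
  true_l2fc <- setNames(numeric(n_genes), genes$gene_id)
  if (n_pool > 0)
    true_l2fc[pool] <- rnorm(n_pool, mean = config$regulon_effect, sd = 0.3)

  ## --- motifs planted in regulon promoters --------------------------------
  motif_w <- 10L
  motifs <- list()
  if (config$n_tfs > 0) {
    cons <- character(0)
    while (length(cons) < config$n_tfs) {
      cnd <- random_consensus(motif_w)
      if (!cnd %in% cons) cons <- c(cons, cnd)
    }
    motifs <- lapply(seq_len(config$n_tfs),
                     function(t) make_motif(cons[t], tf_names[t]))
    names(motifs) <- tf_names
  }
  promoter_of <- function(g) {
    if (g$strand == "+") c(g$orf_start - promoter_w, g$orf_start)
    else c(g$orf_start, g$orf_start + promoter_w)
  }
  protected <- list()
  chrom_idx <- match(genes$chrom, chrom_names)
  for (t in seq_along(motifs)) {
    mot_codes <- seq_to_codes(motifs[[t]]$consensus)
    for (gid in true_regulons[[t]]) {
      gi <- match(gid, genes$gene_id)
      win <- promoter_of(genes[gi, ])
      ci <- chrom_idx[gi]
      win[1] <- max(win[1], 0L); win[2] <- min(win[2], L)
      taken <- Filter(function(p) p$chrom == ci &&
                        p$start < win[2] && p$end > win[1], protected)
      for (try in 1:25) {
        pos <- sample(win[1]:(win[2] - motif_w), 1L)
        clash <- any(vapply(taken, function(p) pos < p$end && pos + motif_w > p$start,
                            logical(1)))
        if (!clash) break
      }
      codes[[ci]][(pos + 1L):(pos + motif_w)] <- mot_codes
      protected[[length(protected) + 1L]] <-
        list(chrom = ci, start = pos, end = pos + motif_w, tf = tf_names[t], gene = gid)
    }
  }
  prot_df <- if (length(protected))
    data.frame(chrom = vapply(protected, `[[`, 0, "chrom"),
               start = vapply(protected, `[[`, 0, "start"),
               end = vapply(protected, `[[`, 0, "end"))
  else data.frame(chrom = integer(0), start = integer(0), end = integer(0))

  ## --- plant GATC sites (after motif editing, background kept GATC-free) --
  gatc_pos <- vector("list", n_chroms)
  for (ci in seq_len(n_chroms)) {
    codes[[ci]] <- scrub_gatc(codes[[ci]], prot_df[prot_df$chrom == ci, , drop = FALSE])
    n_sites <- rpois(1L, L * config$gatc_rate)
    if (n_sites > 0 && L >= 4L) {
      cand <- sort(sample.int(L - 3L, min(n_sites, L - 3L)) - 1L)
      # respect motif footprints and >= 4 bp spacing
      pr <- prot_df[prot_df$chrom == ci, , drop = FALSE]
      if (nrow(pr)) {
        keep <- rep(TRUE, length(cand))
        for (r in seq_len(nrow(pr)))
          keep <- keep & !(cand < pr$end[r] & cand + 4L > pr$start[r])
        cand <- cand[keep]
      }
      if (length(cand) > 1L) cand <- cand[c(TRUE, diff(cand) >= 4L)]
      for (p in cand)
        codes[[ci]][(p + 1L):(p + 4L)] <- GATC_CODES
      gatc_pos[[ci]] <- cand
    } else gatc_pos[[ci]] <- integer(0)
  }

  ## --- planted occupancy peaks on GATC-fragment runs ----------------------
  n_peaks <- config$n_peaks_shared + config$n_peaks_gained + config$n_peaks_lost
  peak_df <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                        host_gene = character(0), class = character(0))
  if (n_peaks > 0) {
    # hosts on alternating slots so planted peaks never collide
    odd <- unlist(lapply(split(seq_len(n_genes), genes$chrom), function(ix)
      ix[seq_along(ix) %% 2L == 1L]), use.names = FALSE)
    if (length(odd) < n_peaks)
      stopf("genome too small to host %d non-colliding peaks", n_peaks)
    hosts <- sample(odd, n_peaks)
    classes <- rep(c("shared", "gained", "lost"),
                   c(config$n_peaks_shared, config$n_peaks_gained, config$n_peaks_lost))
    rows <- vector("list", n_peaks)
    for (i in seq_len(n_peaks)) {
      gi <- hosts[i]; ci <- chrom_idx[gi]
      b <- gatc_pos[[ci]]
      if (length(b) < 10L)
        stopf("chromosome %s has too few GATC fragments to plant peaks", chrom_names[ci])
      fr_start <- c(0L, b); fr_end <- c(b, L)
      win0 <- if (genes$strand[gi] == "+") genes$orf_start[gi] - promoter_w
              else genes$orf_start[gi]
      i0 <- which(fr_start >= win0)[1L]
      if (is.na(i0)) i0 <- length(fr_start)
      k <- sample(5:8, 1L)
      i0 <- min(i0, length(fr_start) - k + 1L)
      rows[[i]] <- data.frame(chrom = chrom_names[ci], start = fr_start[i0],
                              end = fr_end[i0 + k - 1L],
                              host_gene = genes$gene_id[gi], class = classes[i],
                              stringsAsFactors = FALSE)
    }
    peak_df <- do.call(rbind, rows)
  }
  planted_peaks <- list(
    CD = peak_df[peak_df$class %in% c("shared", "lost"), c("chrom", "start", "end"), drop = FALSE],
    SD = peak_df[peak_df$class %in% c("shared", "gained"), c("chrom", "start", "end"), drop = FALSE])
  planted_peaks <- lapply(planted_peaks, function(d) {
    d <- d[order(d$chrom, d$start), , drop = FALSE]; rownames(d) <- NULL; d })

  ## --- chromatin states: peak-host slots are blue Polycomb chromatin ------
  host_set <- peak_df$host_gene
  states_l <- list()
  other_states <- c("red", "yellow", "green", "black")
  for (ci in seq_len(n_chroms)) {
    g <- genes[genes$chrom == chrom_names[ci], , drop = FALSE]
    if (!nrow(g)) {
      states_l[[ci]] <- data.frame(chrom = chrom_names[ci], start = 0L, end = L,
                                   state = "black", stringsAsFactors = FALSE)
      next
    }
    lab <- ifelse(g$gene_id %in% host_set, "blue",
                  sample(c(other_states, "blue"), nrow(g), replace = TRUE,
                         prob = c(rep(0.2375, 4), 0.05)))
    d <- data.frame(chrom = chrom_names[ci], start = g$slot_start, end = g$slot_end,
                    state = lab, stringsAsFactors = FALSE)
    if (max(g$slot_end) < L)
      d <- rbind(d, data.frame(chrom = chrom_names[ci], start = max(g$slot_end),
                               end = L, state = "black", stringsAsFactors = FALSE))
    states_l[[ci]] <- d
  }
  chromatin_states <- do.call(rbind, states_l)
  rownames(chromatin_states) <- NULL

  ## --- PREs: most peaks carry a high-confidence PRE, plus background ------
  pres_l <- list()
  if (nrow(peak_df)) {
    with_pre <- runif(nrow(peak_df)) < 0.8
    if (any(with_pre)) {
      ctr <- (peak_df$start + peak_df$end) %/% 2L
      half <- as.integer(runif(sum(with_pre), 150, 300))
      pres_l[[1]] <- data.frame(
        chrom = peak_df$chrom[with_pre],
        start = pmax(0L, ctr[with_pre] - half),
        end = pmin(L, ctr[with_pre] + half),
        pre_class = sample(c("intergenic", "enhancer"), sum(with_pre),
                           replace = TRUE, prob = c(0.6, 0.4)),
        confidence = runif(sum(with_pre), 0.8, 1), stringsAsFactors = FALSE)
    }
  }
  n_bg_pres <- 40L * n_chroms
  bg_len <- as.integer(runif(n_bg_pres, 300, 600))
  bg_start <- vapply(seq_len(n_bg_pres), function(i)
    sample.int(L - bg_len[i], 1L) - 1L, integer(1))
  pres_l[[length(pres_l) + 1L]] <- data.frame(
    chrom = sample(chrom_names, n_bg_pres, replace = TRUE),
    start = bg_start, end = bg_start + bg_len,
    pre_class = sample(c("intergenic", "enhancer", "promoter", "other"),
                       n_bg_pres, replace = TRUE),
    confidence = runif(n_bg_pres, 0.2, 1), stringsAsFactors = FALSE)
  pres <- do.call(rbind, pres_l)
  pres <- pres[order(pres$chrom, pres$start), ]
  rownames(pres) <- NULL

  ## --- assemble ------------------------------------------------------------
  seqs <- Biostrings::DNAStringSet(vapply(codes, function(x)
    paste(ALPHABET[x], collapse = ""), character(1)))
  names(seqs) <- chrom_names
  genome <- structure(list(
    chromosomes = data.frame(name = chrom_names, length = L,
                             stringsAsFactors = FALSE),
    seqs = seqs,
    genes = genes[, c("gene_id", "chrom", "strand", "start", "end",
                      "orf_start", "expressed")],
    chromatin_states = chromatin_states,
    pres = pres), class = "GenomeModel")

  ## record each TF's achieved planted z threshold by scanning its own genome
  tf_thresholds <- setNames(rep(NA_real_, length(motifs)), names(motifs))
  for (t in seq_along(motifs)) {
    hits <- scan_motif(genome, motifs[[t]], keep_frac = 0.001)
    s_max <- sum(apply(motifs[[t]]$pwm, 2, max))
    tf_thresholds[t] <- (s_max - attr(hits, "center")) / attr(hits, "scale") - 1e-6
  }

  truth <- structure(list(
    planted_peaks = planted_peaks, peak_table = peak_df,
    target_genes = unique(host_set),
    true_regulons = true_regulons, true_l2fc = true_l2fc,
    tf_thresholds = tf_thresholds, motifs = motifs,
    planted_sites = protected), class = "SimTruth")

  list(genome = genome, truth = truth)
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat("GenomeModel:", nrow(x$chromosomes), "chromosome(s),",
      sum(x$chromosomes$length), "bp,", nrow(x$genes), "genes,",
      nrow(x$pres), "PREs\n")
  invisible(x)
}
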