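test_that("the same config reproduces every artifact exactly", {
  cfg <- small_sim(seed = 5)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome$seqs), as.character(b$genome$seqs))
  expect_identical(a$genome$genes, b$genome$genes)
  expect_identical(a$truth$planted_peaks, b$truth$planted_peaks)
  expect_identical(a$truth$true_l2fc, b$truth$true_l2fc)
  # a different seed changes the sequence
  c_ <- simulate_genome(small_sim(seed = 6))
  expect_false(identical(as.character(a$genome$seqs), as.character(c_$genome$seqs)))
})

test_that("gatc_rate 0 yields a GATC-free genome", {
  cfg <- small_sim(seed = 2, gatc_rate = 0, n_peaks_shared = 0,
                   n_peaks_gained = 0, n_peaks_lost = 0)
  sim <- simulate_genome(cfg)
  for (s in as.character(sim$genome$seqs))
    expect_equal(length(oracle_gatc_starts(s)), 0L)
})

test_that("GATC site counts match the Poisson planting rate", {
  cfg <- small_sim(seed = 4, chrom_length_bp = 200000L, gatc_rate = 0.004)
  sim <- simulate_genome(cfg)
  for (s in as.character(sim$genome$seqs)) {
    n <- length(oracle_gatc_starts(s))
    expected <- 200000 * 0.004
    expect_lt(abs(n - expected), 3 * sqrt(expected) + 3)
  }
})

test_that("genes are non-overlapping, inside bounds, with valid ORF starts", {
  sim <- simulate_genome(small_sim(seed = 8))
  g <- sim$genome$genes
  expect_true(all(g$start < g$end))
  expect_true(all(g$orf_start >= g$start & g$orf_start <= g$end))
  expect_true(all(g$end <= sim$genome$chromosomes$length[1]))
  for (cn in unique(g$chrom)) {
    d <- g[g$chrom == cn, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
})

test_that("chromatin states tile each chromosome without gaps or overlap", {
  sim <- simulate_genome(small_sim(seed = 12))
  st <- sim$genome$chromatin_states
  expect_true(all(st$state %in% c("red", "yellow", "blue", "green", "black")))
  for (cn in unique(st$chrom)) {
    d <- st[st$chrom == cn, ]
    d <- d[order(d$start), ]
    expect_equal(d$start[1], 0L)
    expect_equal(d$end[nrow(d)],
                 sim$genome$chromosomes$length[sim$genome$chromosomes$name == cn])
    if (nrow(d) > 1) expect_equal(d$start[-1], d$end[-nrow(d)])
  }
})

test_that("planted peaks lie on GATC-fragment boundaries and PREs are valid", {
  sim <- simulate_genome(small_sim(seed = 13))
  fm <- build_gatc_fragment_map(sim$genome)
  for (cond in c("CD", "SD")) {
    pk <- sim$truth$planted_peaks[[cond]]
    expect_true(all(pk$start %in% c(fm$start)))
    expect_true(all(pk$end %in% c(fm$end)))
  }
  p <- sim$genome$pres
  expect_true(all(p$confidence >= 0 & p$confidence <= 1))
  expect_true(all(p$pre_class %in% c("intergenic", "enhancer", "promoter", "other")))
  expect_true(all(p$start >= 0 & p$end <= sim$genome$chromosomes$length[1]))
})

test_that("every planted motif site is an exact consensus match in its promoter", {
  sim <- simulate_genome(small_sim(seed = 14))
  seqs <- sim$genome$seqs
  chrom_names <- sim$genome$chromosomes$name
  for (site in sim$truth$planted_sites) {
    cons <- sim$truth$motifs[[site$tf]]$consensus
    found <- as.character(Biostrings::subseq(seqs[[site$chrom]],
                                             site$start + 1L, site$end))
    expect_equal(found, cons)
    # and inside the member gene's promoter window
    w <- promoter_windows(sim$genome)
    w <- w[w$gene_id == site$gene, ]
    expect_true(site$start >= w$start && site$end <= w$end)
  }
})

test_that("undersized chromosomes are rejected with a sizing error", {
  expect_error(simulate_genome(small_sim(seed = 1, chrom_length_bp = 10000L)),
               "too short")
})
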