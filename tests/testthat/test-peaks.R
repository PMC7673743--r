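test_that("an all-zero track produces no peaks", {
  fm <- flat_fragmap(100)
  pk <- call_peaks_fdr(toy_occupancy(rep(0, 100), fm), seed = 1)
  expect_equal(nrow(pk), 0L)
})

test_that("a planted high run among noise is called as exactly one peak", {
  fm <- flat_fragmap(1000)
  set.seed(17)
  v <- rnorm(1000)
  v[301:320] <- 5
  pk <- call_peaks_fdr(toy_occupancy(v, fm), fdr_max = 0.01, n_shuffles = 100,
                       threshold_q = 0.95, seed = 17)
  # run-enumeration oracle on the same threshold: the planted stretch is the
  # unique maximal run of >= 20 above-threshold fragments
  thr <- unname(quantile(v, 0.95))
  r <- rle(v > thr)
  long_runs <- which(r$values & r$lengths >= 20)
  expect_equal(length(long_runs), 1L)
  expect_true(nrow(pk) >= 1L)
  big <- pk[which.max(pk$n_fragments), ]
  expect_lte(big$start, fm$start[301])
  expect_gte(big$end, fm$end[320])
  expect_lt(big$fdr, 0.01)
})

test_that("expected/observed FDR is non-increasing in run length", {
  fm <- flat_fragmap(500)
  set.seed(23)
  v <- rnorm(500)
  v[100:140] <- v[100:140] + 3   # a broad enriched region with varied runs
  pk <- call_peaks_fdr(toy_occupancy(v, fm), fdr_max = 1.1, n_shuffles = 50,
                       seed = 23)
  if (nrow(pk) > 1) {
    agg <- tapply(pk$fdr, pk$n_fragments, unique)
    expect_true(all(diff(unlist(agg)[order(as.integer(names(agg)))]) <= 1e-12))
  }
  expect_error(call_peaks_fdr(toy_occupancy(rnorm(5), flat_fragmap(5))),
               "too few fragments")
})

test_that("interval merging handles overlap, bookended touch, and random sets", {
  m <- merge_intervals(data.frame(chrom = "chr1", start = c(0L, 5L), end = c(10L, 20L)))
  expect_equal(unname(as.matrix(m[, c("start", "end")])), matrix(c(0L, 20L), 1))
  m2 <- merge_intervals(data.frame(chrom = "chr1", start = c(0L, 10L), end = c(10L, 20L)))
  expect_equal(m2$start, 0L); expect_equal(m2$end, 20L)
  expect_error(merge_intervals(data.frame(chrom = "chr1", start = 5L, end = 5L)),
               "malformed")
  set.seed(31)
  iv <- random_intervals(1000)
  got <- merge_intervals(iv)
  want <- oracle_merge_mask(iv, 10000L)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
})

test_that("replicate intersection is idempotent, empty for disjoint, and mask-exact", {
  a <- data.frame(chrom = "chr1", start = c(0L, 100L), end = c(50L, 200L))
  expect_equal(intersect_replicate_peaks(list(a, a))[, c("start", "end")],
               a[, c("start", "end")])
  b <- data.frame(chrom = "chr1", start = 300L, end = 400L)
  expect_equal(nrow(intersect_replicate_peaks(list(a, b))), 0L)
  expect_error(intersect_replicate_peaks(list(a)), "at least two")
  set.seed(37)
  sets <- replicate(3, random_intervals(200), simplify = FALSE)
  got <- intersect_replicate_peaks(sets)
  masks <- lapply(sets, function(s) {
    m <- logical(10000)
    for (k in seq_len(nrow(s))) m[(s$start[k] + 1):s$end[k]] <- TRUE
    m
  })
  inter <- Reduce(`&`, masks)
  r <- rle(inter); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  expect_equal(got$start, starts[r$values] - 1L)
  expect_equal(got$end, ends[r$values])
})

test_that("peaks map to genes through the strand-aware upstream window", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                      strand = c("+", "-"), start = c(10000L, 30000L),
                      end = c(12000L, 32000L), orf_start = c(10000L, 32000L),
                      expressed = TRUE)
  g <- list(chromosomes = data.frame(name = "chr1", length = 50000L),
            genes = genes)
  # peak inside the gene body
  expect_true(peaks_to_genes(data.frame(chrom = "chr1", start = 11000L,
                                        end = 11100L), g)$bound[1])
  # + strand: 1.5 kb upstream of the ORF start is bound, 2.5 kb is not
  expect_true(peaks_to_genes(data.frame(chrom = "chr1", start = 8450L,
                                        end = 8550L), g)$bound[1])
  expect_false(peaks_to_genes(data.frame(chrom = "chr1", start = 7450L,
                                         end = 7550L), g)$bound[1])
  # - strand: upstream means higher coordinates
  expect_true(peaks_to_genes(data.frame(chrom = "chr1", start = 33400L,
                                        end = 33500L), g)$bound[2])
  expect_false(peaks_to_genes(data.frame(chrom = "chr1", start = 34100L,
                                         end = 34200L), g)$bound[2])
  # brute-force overlap oracle on random peaks
  set.seed(41)
  pk <- random_intervals(300, L = 50000L)
  got <- peaks_to_genes(pk, g)
  win <- data.frame(chrom = "chr1", start = c(8000L, 30000L), end = c(12000L, 34000L))
  want <- vapply(1:2, function(i)
    oracle_overlap_count(win[i, , drop = FALSE], pk) > 0, logical(1))
  expect_equal(got$bound, want)
})

test_that("occupancy deltas classify gained and lost planted peaks", {
  cfg <- small_sim(seed = 51)
  sim <- simulate_genome(cfg)
  fm <- build_gatc_fragment_map(sim$genome)
  counts <- simulate_damid_counts(sim$genome, sim$truth, cfg, fm)
  cd <- compute_log_ratio(counts$fusion_CD_rep1, counts$Dam_CD_rep1)
  sd_ <- compute_log_ratio(counts$fusion_SD_rep1, counts$Dam_SD_rep1)
  dd <- compare_occupancy(cd, sd_, sim$genome)
  tab <- sim$truth$peak_table
  gained_hosts <- tab$host_gene[tab$class == "gained"]
  lost_hosts <- tab$host_gene[tab$class == "lost"]
  expect_true(all(dd$group[dd$gene_id %in% gained_hosts] == "1"))
  expect_true(all(dd$group[dd$gene_id %in% lost_hosts] == "2"))
  # identical tracks: all deltas zero
  dd0 <- compare_occupancy(cd, cd, sim$genome)
  expect_true(all(dd0$delta == 0, na.rm = TRUE))
  expect_true(all(dd0$group[!is.na(dd0$group)] == "unchanged"))
  # negating both tracks negates the deltas
  neg <- function(tr) { tr$values <- -tr$values; tr }
  ddn <- compare_occupancy(neg(cd), neg(sd_), sim$genome)
  expect_equal(ddn$delta, -dd$delta)
})
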