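chrlen <- c(chr1 = 10000L)

test_that("shuffling preserves lengths and is forced when there is no freedom", {
  iv <- data.frame(chrom = "chr1", start = 0L, end = 10000L)
  s <- shuffle_intervals(iv, chrlen, seed = 1)
  expect_equal(c(s$start, s$end), c(0L, 10000L))
  set.seed(2)
  iv2 <- random_intervals(50)
  s2 <- shuffle_intervals(iv2, chrlen)
  expect_equal(sort(s2$end - s2$start), sort(iv2$end - iv2$start))
  expect_true(all(s2$start >= 0 & s2$end <= 10000))
  expect_error(shuffle_intervals(data.frame(chrom = "chr1", start = 0L,
                                            end = 20000L), chrlen), "longer")
})

test_that("shuffled midpoints are uniform over the valid range", {
  iv <- data.frame(chrom = "chr1", start = 100L, end = 300L)  # length 200
  set.seed(3)
  mids <- replicate(10000, {
    s <- shuffle_intervals(iv, chrlen)
    (s$start + s$end) / 2
  })
  # valid midpoint range is [100, 9900]
  expect_gt(suppressWarnings(ks.test(mids, "punif", 100, 9900))$p.value, 0.01)
})

test_that("overlap counting matches the pairwise oracle", {
  ref <- data.frame(chrom = "chr1", start = c(100L, 5000L), end = c(1000L, 6000L))
  inside <- data.frame(chrom = "chr1", start = c(200L, 5100L), end = c(300L, 5200L))
  expect_equal(overlap_count(inside, ref), 2L)
  disjoint <- data.frame(chrom = "chr1", start = 8000L, end = 8100L)
  expect_equal(overlap_count(disjoint, ref), 0L)
  set.seed(5)
  q <- random_intervals(200); r <- random_intervals(100)
  expect_equal(overlap_count(q, r), oracle_overlap_count(q, r))
})

test_that("permutation enrichment detects a half-genome reference analytically", {
  # reference covers the first half of the chromosome in one block; short
  # query intervals placed inside it overlap with probability ~ coverage
  # fraction (0.5) under the null, so observing all 15 has p ~ 0.5^15
  ref <- data.frame(chrom = "chr1", start = 0L, end = 5000L)
  q <- data.frame(chrom = "chr1", start = seq(100L, 4580L, by = 320L),
                  end = seq(100L, 4580L, by = 320L) + 100L)
  er <- permutation_enrichment(q, ref, chrlen, n_shuffles = 1000, seed = 7)
  expect_equal(er$observed, nrow(q))
  expect_gt(er$fold, 1)
  expect_lte(er$p_empirical, 0.002)
  expect_error(permutation_enrichment(q[0, ], ref, chrlen), "nonempty")
  expect_error(permutation_enrichment(q, ref, chrlen, n_shuffles = 0), "n_shuffles")
})

test_that("a query drawn by the shuffler itself shows fold near one", {
  set.seed(8)
  ref <- random_intervals(40)
  q <- shuffle_intervals(random_intervals(100), chrlen)
  er <- permutation_enrichment(q, ref, chrlen, n_shuffles = 500, seed = 9)
  expect_lt(abs(er$observed - er$null_mean), 4 * er$null_sd)
  expect_gt(er$p_empirical, 0.005)
  # add-one rule keeps the empirical p strictly positive
  expect_gt(er$p_empirical, 0)
})

test_that("chromatin state ratios follow the observed/expected definition", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:10), chrom = "chr1",
                      strand = "+", start = seq(0L, 9000L, by = 1000L),
                      end = seq(0L, 9000L, by = 1000L) + 500L,
                      orf_start = seq(0L, 9000L, by = 1000L), expressed = TRUE)
  st <- data.frame(chrom = "chr1",
                   start = seq(0L, 9000L, by = 1000L),
                   end = seq(1000L, 10000L, by = 1000L),
                   state = c(rep("blue", 2), rep("red", 3), rep("yellow", 2),
                             rep("green", 2), "black"))
  g <- list(chromosomes = data.frame(name = "chr1", length = 10000L),
            genes = genes, chromatin_states = st)
  # all genes bound -> every ratio 1
  tab <- chromatin_state_proportions(genes$gene_id, g)
  expect_true(all(abs(tab$ratio[tab$expected > 0] - 1) < 1e-12))
  # bound set entirely in blue (genome fraction 0.2) -> blue ratio 5
  tab2 <- chromatin_state_proportions(c("g01", "g02"), g)
  expect_equal(tab2$ratio[tab2$state == "blue"], 5)
  expect_equal(sum(tab2$observed), 1)
  expect_equal(sum(tab2$expected), 1)
})

test_that("simulated Pcl targets sit in blue chromatin above all other states", {
  cfg <- small_sim(seed = 61)
  sim <- simulate_genome(cfg)
  tab <- chromatin_state_proportions(sim$truth$target_genes, sim$genome)
  blue <- tab$ratio[tab$state == "blue"]
  expect_equal(which.max(tab$ratio), which(tab$state == "blue"))
  expect_gt(blue, 1)
})
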