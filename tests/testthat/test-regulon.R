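test_that("promoter windows are strand-aware and clipped", {
  genes <- data.frame(gene_id = c("p", "m", "edge"), chrom = "chr1",
                      strand = c("+", "-", "+"),
                      start = c(5000L, 5000L, 400L), end = c(6000L, 6000L, 600L),
                      orf_start = c(5000L, 5000L, 500L), expressed = TRUE)
  g <- list(chromosomes = data.frame(name = "chr1", length = 10000L), genes = genes)
  w <- promoter_windows(g, width = 2000L)
  expect_equal(c(w$start[1], w$end[1]), c(3000L, 5000L))
  expect_equal(c(w$start[2], w$end[2]), c(5000L, 7000L))
  expect_equal(c(w$start[3], w$end[3]), c(0L, 500L))   # clipped at chromosome start
})

test_that("regulon membership thresholds on max promoter z and is monotone", {
  windows <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                        start = c(0L, 1000L, 2000L), end = c(1000L, 2000L, 3000L))
  hits <- data.frame(tf_name = "T", chrom = "chr1",
                     pos = c(10L, 500L, 1500L, 2500L), strand = "+",
                     score = 1, z = c(2, 7, 4, 9))
  expect_setequal(build_regulon(hits, windows, 5)$genes, c("a", "c"))
  expect_setequal(build_regulon(hits, windows, -Inf)$genes, c("a", "b", "c"))
  expect_equal(build_regulon(hits, windows, 100)$genes, character(0))
  # tau1 < tau2 implies regulon(tau2) subset of regulon(tau1)
  for (tau in c(0, 3, 6, 8)) {
    r1 <- build_regulon(hits, windows, tau)$genes
    r2 <- build_regulon(hits, windows, tau + 1)$genes
    expect_true(all(r2 %in% r1))
  }
})

test_that("threshold curves are monotone in size and recover a planted threshold", {
  set.seed(91)
  n <- 200
  windows <- data.frame(gene_id = sprintf("g%03d", 1:n), chrom = "chr1",
                        start = (0:(n - 1)) * 100L, end = (1:n) * 100L)
  # 60 members get a strong hit at z = 6; 60 decoy genes carry hits at z = 4
  # with null expression (diluting any lower threshold); background z ~ N(0,1)
  members <- sprintf("g%03d", 1:60)
  hits <- data.frame(tf_name = "T", chrom = "chr1",
                     pos = c((0:59) * 100L + 50L, (60:119) * 100L + 50L,
                             (0:(n - 1)) * 100L + 10L),
                     strand = "+", score = 1,
                     z = c(rep(6, 60), rep(4, 60), rnorm(n)))
  de <- data.frame(gene_id = windows$gene_id, base_mean = 100,
                   l2fc = ifelse(windows$gene_id %in% members,
                                 rnorm(n, -1, 0.3), rnorm(n, 0, 0.3))[1:n],
                   se = 0.2, p = 0.5, q = 0.5)
  curve <- threshold_curve(hits, windows, de, seq(0, 7, by = 0.5), n_min = 20)
  expect_true(all(diff(curve$n) <= 0))
  # any threshold that excludes the decoys but keeps the members is optimal
  expect_gt(attr(curve, "tau_star"), 4)
  expect_lte(attr(curve, "tau_star"), 6)
  expect_error(threshold_curve(hits, windows, de, c(50, 60)), "empty regulon")
})

test_that("a flat expression table gives no spuriously selected threshold signal", {
  set.seed(92)
  n <- 200
  windows <- data.frame(gene_id = sprintf("g%03d", 1:n), chrom = "chr1",
                        start = (0:(n - 1)) * 100L, end = (1:n) * 100L)
  peaked <- numeric(0)
  for (s in 1:20) {
    hits <- data.frame(tf_name = "T", chrom = "chr1",
                       pos = (0:(n - 1)) * 100L + 10L, strand = "+",
                       score = 1, z = rnorm(n))
    de <- data.frame(gene_id = windows$gene_id, base_mean = 100,
                     l2fc = rnorm(n, 0, 0.3), se = 0.2, p = 0.5, q = 0.5)
    curve <- suppressWarnings(
      threshold_curve(hits, windows, de, seq(-2, 2, 0.5), n_min = 20))
    peaked <- c(peaked, max(curve$t[curve$n >= 20]))
  }
  # the signal score under the null stays far below the planted-case values
  expect_lt(mean(peaked > 4), 0.25)
})

test_that("regulon overlap tables, odds ratios and Fisher p match exact oracles", {
  universe <- sprintf("g%03d", 1:100)
  A <- universe[1:30]; B <- universe[c(1:12, 31:58)]    # |A|=30 |B|=40 overlap 12
  r <- regulon_overlap_tests(list(A = A, B = B), universe)
  expect_equal(r$in_both, 12L)
  expect_equal(r$odds_ratio, 1.0)                        # 12*42 = 18*28
  B2 <- universe[c(1:20, 31:50)]                         # overlap 20
  r2 <- regulon_overlap_tests(list(A = A, B = B2), universe)
  expect_equal(r2$odds_ratio, 5.0)
  # two-sided Fisher p by explicit hypergeometric enumeration
  enum_p <- function(a, b, c_, d) {
    n <- a + b + c_ + d; rowA <- a + b; colA <- a + c_
    av <- max(0, rowA + colA - n):min(rowA, colA)
    pr <- dhyper(av, colA, n - colA, rowA)
    sum(pr[pr <= dhyper(a, colA, n - colA, rowA) * (1 + 1e-7)])
  }
  expect_equal(r2$p, enum_p(20, 10, 20, 50), tolerance = 1e-9)
  # identical regulons: infinite sample OR, minimal p for the margins
  r3 <- regulon_overlap_tests(list(A = A, B = A), universe)
  expect_equal(r3$odds_ratio, Inf)
  expect_equal(r3$p, enum_p(30, 0, 0, 70), tolerance = 1e-9)
  expect_error(regulon_overlap_tests(list(A = A, B = B), character(0)), "universe")
})
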