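test_that("moment skewness follows the denominator-n formula", {
  expect_equal(l2fc_skewness(c(-1, 0, 1))$skewness, 0)
  r <- l2fc_skewness(c(0, 0, 0, 1))
  expect_equal(r$m2, 0.1875)
  expect_equal(r$m3, 0.09375)
  expect_equal(r$skewness, 2 / sqrt(3), tolerance = 1e-12)
  # odd moment: negation flips the sign
  set.seed(71)
  x <- rexp(200)
  expect_equal(l2fc_skewness(-x)$skewness, -l2fc_skewness(x)$skewness)
  expect_error(l2fc_skewness(rep(2, 10)), "constant")
  expect_error(l2fc_skewness(c(1, 2)), "at least 3")
})

test_that("skewness agrees with the e1071 type-1 estimator", {
  skip_if_not_installed("e1071")
  set.seed(72)
  for (i in 1:5) {
    x <- rnorm(50) + rexp(50)
    expect_equal(l2fc_skewness(x)$skewness, e1071::skewness(x, type = 1),
                 tolerance = 1e-12)
  }
})

test_that("equivalence test follows the TOST max-p form", {
  delta <- log2(1.5)
  # at the null boundary the test can never reject
  tab <- data.frame(gene_id = "a", l2fc = delta, se = 0.17)
  expect_gte(equivalence_test(tab)$p_equiv, 0.5)
  # analytic value at l2fc = 0, se = 0.2
  tab2 <- data.frame(gene_id = "b", l2fc = 0, se = 0.2)
  expect_equal(equivalence_test(tab2)$p_equiv, pnorm(-delta / 0.2),
               tolerance = 1e-9)
  expect_equal(pnorm(-delta / 0.2), 0.00173, tolerance = 0.01)
  # uninformative data (huge SE) converge to p = 0.5, never "unchanged"
  tab3 <- data.frame(gene_id = "c", l2fc = 0.3, se = 1e6)
  expect_equal(equivalence_test(tab3)$p_equiv, 0.5, tolerance = 1e-4)
  # |l2fc| >= delta can never be called unchanged, whatever the SE
  grid <- expand.grid(l2fc = c(-2, -delta, delta, 1, 3), se = c(0.01, 0.2, 5))
  p <- equivalence_test(cbind(gene_id = seq_len(nrow(grid)), grid))$p_equiv
  expect_true(all(p >= 0.5))
  expect_error(equivalence_test(data.frame(gene_id = "x", l2fc = 0, se = 0)),
               "nonpositive")
  expect_error(equivalence_test(tab, fold_bound = 0.9), "fold_bound")
})

test_that("BH q-values match a hand-rolled step-up on fixed and random input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  set.seed(73)
  for (i in 1:200) {
    p <- runif(sample(2:50, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in sorted order
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "p-values")
})

test_that("IP/input enrichment is a depth-invariant cpm log ratio", {
  genes <- sprintf("g%02d", 1:20)
  ip <- setNames(rep(1000, 20), genes)
  expect_true(all(ip_input_enrichment(ip, ip)$log2_enrichment == 0))
  # planted 8x in IP at high counts -> log2 enrichment near 3
  ip2 <- setNames(c(rep(80000, 5), rep(10000, 15)), genes)
  inp <- setNames(rep(10000, 20), genes)
  e <- ip_input_enrichment(ip2, inp)
  expect_equal(e$log2_enrichment[1:5] - e$log2_enrichment[6:10][1], rep(3, 5),
               tolerance = 0.01)
  # scaling input depth alone leaves enrichment unchanged
  e2 <- ip_input_enrichment(ip2, inp * 7)
  expect_equal(e$log2_enrichment, e2$log2_enrichment, tolerance = 1e-9)
  expect_error(ip_input_enrichment(ip2, inp[1:10]), "universe")
})

test_that("equal-population binning distributes ranks with <= 1 size spread", {
  expect_equal(tabulate(bin_equally_populated(rnorm(14), 7)), rep(2L, 7))
  b <- bin_equally_populated(rnorm(15), 7)
  expect_equal(sort(tabulate(b), decreasing = TRUE), c(3L, rep(2L, 6)))
  x <- sort(rnorm(100))
  expect_true(all(diff(bin_equally_populated(x, 7)) >= 0))
  # ties broken by stable input order
  expect_equal(bin_equally_populated(rep(1, 4), 2), c(1L, 1L, 2L, 2L))
  expect_error(bin_equally_populated(rnorm(10), 0), "positive")
  expect_error(bin_equally_populated(rnorm(3), 7), "at least")
})
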