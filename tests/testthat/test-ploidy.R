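test_that("the G1 peak is the lowest qualifying density mode", {
  single <- generate_flow_sample(5000, 0, arrested = TRUE,
                                 escape_fraction = 0, seed = 81)
  expect_equal(g1_peak(single), 100, tolerance = 2)
  # asynchronous haploids: G1 at 100 dominates, G2 at 200 present
  async <- generate_flow_sample(10000, 0, g2_share = 0.3, seed = 82)
  expect_equal(g1_peak(async), 100, tolerance = 3)
  # equal bimodal peaks: the lower one is returned by rule
  set.seed(83)
  bimodal <- c(rnorm(5000, 100, 8), rnorm(5000, 200, 16))
  expect_equal(g1_peak(bimodal), 100, tolerance = 3)
  expect_error(g1_peak(rnorm(500, 100, 8)), "1000")
})

test_that("threshold k-means equals brute force over all 2-partitions", {
  set.seed(84)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    peaks <- setNames(
      c(rnorm(ceiling(n / 2), 100, 5), rnorm(floor(n / 2), 200, 10)),
      paste0("col", seq_len(n))
    )
    calls <- call_ploidy(peaks)
    oracle <- oracle_kmeans2(peaks)
    expect_equal(calls$wss_k2, oracle$wss, tolerance = 1e-9)
    # same partition (up to label swap)
    grp <- calls$assignments == 1L
    expect_true(identical(unname(grp), oracle$groups) ||
                  identical(unname(grp), !oracle$groups))
  }
})

test_that("ploidy calls follow genome size and ignore input order", {
  peaks <- c(a = 98, b = 100, c = 102, d = 198, e = 205)
  calls <- call_ploidy(peaks)
  expect_equal(unname(calls$assignments), c(1L, 1L, 1L, 2L, 2L))
  expect_lt(calls$wss_k2, calls$wss_k1)
  shuffled <- peaks[c(4, 1, 5, 3, 2)]
  calls2 <- call_ploidy(shuffled)
  expect_equal(calls2$assignments[names(peaks)], calls$assignments)
  # two colonies: one per cluster, zero WSS
  two <- call_ploidy(c(x = 100, y = 200))
  expect_equal(two$wss_k2, 0)
  expect_equal(unname(two$assignments), c(1L, 2L))
  expect_error(call_ploidy(c(x = 100, y = 100, z = 100)), "separation")
  # anchors allow single-colony assignment
  one <- call_ploidy(c(lone = 197), anchors = c(100, 200))
  expect_equal(unname(one$assignments), 2L)
})

test_that("arrested diploid fractions invert the escape model", {
  pure_h <- generate_flow_sample(20000, 0, arrested = TRUE,
                                 escape_fraction = 0, seed = 85)
  expect_equal(diploid_fraction(pure_h, 100, 0), 0)
  pure_d <- generate_flow_sample(20000, 1, arrested = TRUE,
                                 escape_fraction = 0, seed = 86)
  # a ~0.1% Gaussian tail of the 2c peak falls below the 1.5c gate
  expect_equal(diploid_fraction(pure_d, 100, 0), 1, tolerance = 0.005)
  # escape-corrected closed loop at a 50:50 mixture
  est <- vapply(1:20, function(i) {
    s <- generate_flow_sample(30000, 0.5, arrested = TRUE,
                              escape_fraction = 0.1, seed = 860 + i)
    diploid_fraction(s, 100, 0.1)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 3 * sd(est) / sqrt(length(est)))
  expect_lt(max(abs(est - 0.5)), 0.015)
  # unarrested samples are refused
  async <- generate_flow_sample(2000, 0.5, seed = 87)
  expect_error(diploid_fraction(async, 100), "arrested")
})

test_that("estimated fraction rises monotonically with the true mixture", {
  est <- vapply(seq(0, 1, 0.1), function(d) {
    s <- generate_flow_sample(30000, d, arrested = TRUE,
                              escape_fraction = 0.1,
                              seed = 880 + round(100 * d))
    diploid_fraction(s, 100, 0.1)
  }, numeric(1))
  expect_true(all(diff(est) > -0.005))
  expect_equal(est, seq(0, 1, 0.1), tolerance = 0.02)
})

test_that("frequency change is a plain difference with domain checks", {
  expect_equal(frequency_change(0.5, 0.5), 0)
  expect_equal(frequency_change(0.2, 0.7), 0.5)
  expect_error(frequency_change(-0.1, 0.5))
})

test_that("coverage ratios flag whole-chromosome gains algebraically", {
  ref <- setNames(c(230, 813, 316, 1532, 577, 270, 1091, 563,
                    440, 745, 666, 1078, 924, 784, 1091, 948) * 1e3,
                  paste0("chr", utils::as.roman(1:16)))
  # euploid: counts proportional to reference
  euploid <- coverage_ratios(ref * 3, ref)
  expect_equal(euploid$ratio, rep(1, 16), tolerance = 1e-12)
  expect_false(any(euploid$flagged))
  # haploid with chromosome IX doubled
  counts <- ref
  counts["chrIX"] <- 2 * counts["chrIX"]
  cr <- coverage_ratios(counts, ref)
  expected_ix <- 2 * sum(ref) / (sum(ref) + ref[["chrIX"]])
  expect_equal(cr$ratio[cr$chromosome == "chrIX"], expected_ix,
               tolerance = 1e-12)
  expect_gt(expected_ix, 1.4)
  expect_true(cr$flagged[cr$chromosome == "chrIX"])
  expect_false(any(cr$flagged[cr$chromosome != "chrIX"]))
  # permuting chromosomes permutes ratios identically
  perm <- sample(16)
  cr_perm <- coverage_ratios(counts[perm], ref[perm])
  expect_equal(cr_perm$ratio[match(cr$chromosome, cr_perm$chromosome)],
               cr$ratio, tolerance = 1e-12)
  expect_error(coverage_ratios(counts, ref * 0), "positive")
})
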