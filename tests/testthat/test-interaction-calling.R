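test_that("subsampling is exact, forced when degenerate, and hypergeometric in mean", {
  one <- ditag_counts(data.table::data.table(frag1 = 1L, frag2 = 2L,
                                             count = 10L))
  expect_identical(subsample_to_depth(one, 10L), one)            # no-op
  expect_equal(subsample_to_depth(one, 4L, seed = 1)$pairs$count, 4L)

  two <- ditag_counts(data.table::data.table(
    frag1 = c(1L, 3L), frag2 = c(2L, 4L), count = c(60L, 40L)))
  draws <- vapply(1:2000, function(s) {
    sub <- subsample_to_depth(two, 50L, seed = s)
    expect_equal(sub$total_reads, 50L)
    sum(sub$pairs[frag1 == 1L, count])
  }, numeric(1))
  # hypergeometric moments: mean 30, var 50*0.6*0.4*(50/99)
  se <- sqrt(50 * 0.6 * 0.4 * 50 / 99 / length(draws))
  expect_lt(abs(mean(draws) - 30), 3 * se)
  expect_error(subsample_to_depth(two, 200L), "exceeds")
})

test_that("relative coverage matches hand-summed marginals and sums to one", {
  one <- ditag_counts(data.table::data.table(frag1 = 1L, frag2 = 2L,
                                             count = 7L))
  expect_equal(unname(relative_coverage(one)), c(0.5, 0.5))

  toy <- ditag_counts(data.table::data.table(
    frag1 = c(1L, 1L, 2L), frag2 = c(2L, 3L, 3L), count = c(4L, 6L, 10L)))
  cv <- relative_coverage(toy)
  expect_equal(unname(cv[c("1", "2", "3")]),
               c(10, 14, 16) / 40)  # marginals over 2N = 40
  expect_equal(sum(cv), 1, tolerance = 1e-12)

  set.seed(2)
  rnd <- ditag_counts(data.table::data.table(
    frag1 = sample(1:50, 200, TRUE), frag2 = sample(51:100, 200, TRUE),
    count = sample(1:20, 200, TRUE)))
  expect_equal(sum(relative_coverage(rnd)), 1, tolerance = 1e-12)
})

test_that("binomial background p-values match the direct-summation oracle", {
  # craft coverage so that one pair has p_ij = 0.01 exactly, with N = 100
  counts <- ditag_counts(data.table::data.table(
    frag1 = c(1L, 3L), frag2 = c(2L, 4L), count = c(5L, 95L)))
  cov <- c("1" = sqrt(0.005), "2" = sqrt(0.005), "3" = 0.2, "4" = 0.2)
  calls <- binomial_background_test(counts, coverage = cov)
  expect_equal(calls[frag1 == 1L, expected], 100 * 0.01)
  expect_equal(calls[frag1 == 1L, pvalue],
               binom_upper_oracle(5, 100, 0.01), tolerance = 1e-12)

  # exactness across magnitudes (relative error < 1e-10 for N <= 1e4)
  for (case in list(c(1e3, 0.005, 12), c(1e4, 0.002, 40), c(1e4, 0.3, 3100))) {
    N <- case[1]; p <- case[2]; k <- case[3]
    counts <- ditag_counts(data.table::data.table(
      frag1 = c(1L, 3L), frag2 = c(2L, 4L), count = c(k, N - k)))
    cov <- c(sqrt(p / 2), sqrt(p / 2), 0.2, 0.2)
    names(cov) <- 1:4
    got <- binomial_background_test(counts, coverage = cov)[frag1 == 1L, pvalue]
    expect_equal(got, binom_upper_oracle(k, N, p), tolerance = 1e-10)
  }
})

test_that("binomial background p-values agree with a Monte-Carlo tail", {
  set.seed(31)
  N <- 500; p <- 0.02; k <- 20
  mc <- mean(rbinom(10000, N, p) >= k)
  counts <- ditag_counts(data.table::data.table(
    frag1 = c(1L, 3L), frag2 = c(2L, 4L), count = c(k, N - k)))
  cov <- setNames(c(sqrt(p / 2), sqrt(p / 2), 0.2, 0.2), 1:4)
  got <- binomial_background_test(counts, coverage = cov)[frag1 == 1L, pvalue]
  se <- sqrt(got * (1 - got) / 10000)
  expect_lt(abs(got - mc), 3 * se + 1e-6)
})

test_that("BH adjustment matches the step-up oracle exactly", {
  expect_equal(bh_adjust(0.03), 0.03)                       # m = 1
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(17)
  for (rep in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-13)
  }
})

test_that("log-space BH agrees with p.adjust where both are representable", {
  set.seed(4)
  p <- c(runif(50), 10^-runif(20, 2, 200))
  lq <- promhic:::bh_adjust_log(log(p))
  expect_equal(exp(lq), p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("promoter thresholds separate planted bimodal significances", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    sig <- c(runif(200, 0, 2), runif(200, 6, 10))
    th <- promoter_threshold(sig)
    hits <- hits + (th$method == "inflection" &&
                      th$threshold_s > 2 && th$threshold_s < 6)
  }
  expect_gte(hits, 19L)
})

test_that("promoter threshold falls back when the construction is untrustworthy", {
  set.seed(1)
  expect_equal(promoter_threshold(runif(5, 0, 8))$method, "global_fallback")
  expect_equal(promoter_threshold(rep(3.3, 50))$method, "global_fallback")
  expect_equal(promoter_threshold(runif(5, 0, 8))$threshold_s, -log10(0.05))
  # monotone single population: no reproducible antimode
  for (s in 1:10) {
    set.seed(s)
    expect_equal(promoter_threshold(runif(400, 0, 4))$method,
                 "global_fallback")
  }
})

test_that("promoter threshold is invariant to duplicating the interaction list", {
  set.seed(7)
  sig <- c(runif(150, 0, 2), runif(150, 6, 10))
  t1 <- promoter_threshold(sig)
  t2 <- promoter_threshold(rep(sig, 2))
  expect_equal(t1$threshold_s, t2$threshold_s)
  expect_equal(t1$method, t2$method)
})

test_that("pooling replicates equals testing the summed table", {
  set.seed(21)
  map <- toy_map(frag_len = 1000L, n_frags = 40L, bait_ids = c(2L, 15L))
  mk <- function() data.table::data.table(
    frag1 = sample(1:39, 150, TRUE), frag2 = 40L,
    count = sample(1:30, 150, TRUE))
  r1 <- ditag_counts(mk()); r2 <- ditag_counts(mk())
  pooled <- ditag_counts(rbind(r1$pairs, r2$pairs))
  a <- suppressMessages(call_significant(list(r1, r2), map))
  b <- suppressMessages(call_significant(pooled, map))
  expect_equal(a$calls, b$calls)
  expect_equal(a$thresholds, b$thresholds)
})

test_that("calls are partitioned into promoter-genome and promoter-promoter", {
  map <- toy_map(frag_len = 1000L, n_frags = 10L, bait_ids = c(1L, 4L))
  counts <- ditag_counts(data.table::data.table(
    frag1 = c(1L, 1L, 5L), frag2 = c(4L, 7L, 8L), count = c(5L, 5L, 5L)))
  res <- suppressMessages(call_significant(counts, map))
  expect_equal(res$calls[frag1 == 1L & frag2 == 4L, category],
               "promoter_promoter")
  expect_equal(res$calls[frag1 == 1L & frag2 == 7L, category],
               "promoter_genome")
  expect_false(any(res$calls$frag1 == 5L))  # no-bait pair dropped
})

test_that("sex-chromosome exclusion removes configured chromosomes", {
  fr <- data.table::data.table(
    chrom = rep(c("chr1", "chrX"), each = 5L),
    start = rep(seq(0L, 4000L, by = 1000L), 2L),
    end = rep(seq(1000L, 5000L, by = 1000L), 2L))
  map <- fragment_map(fr, bait_ids = c(1L, 6L))
  counts <- ditag_counts(data.table::data.table(
    frag1 = c(1L, 6L), frag2 = c(3L, 8L), count = c(10L, 10L)))
  res <- suppressMessages(
    call_significant(counts, map, exclude_chroms = "chrX"))
  expect_true(all(res$calls$frag1 != 6L))
})

test_that("background p-values are super-uniform on factorizable backgrounds", {
  frac <- sapply(41:45, function(s) {
    cfg <- simulation_config(seed = s, n_chromosomes = 1L,
                             chrom_length = 1.3e6, n_baits = 1L,
                             capture_only = FALSE, min_cis_distance = 0,
                             decay_offset = 1e12, n_shared = 0L,
                             n_test_specific = 0L, n_ref_specific = 0L)
    map <- simulate_fragment_map(cfg)
    counts <- simulate_ditags(map, cfg, "test")
    p <- binomial_background_test(counts)$pvalue
    c(mean(p < 0.01), mean(p < 0.05), length(p))
  })
  m <- mean(frac[3, ])
  expect_lte(mean(frac[1, ]), 0.01 + 3 * sqrt(0.01 * 0.99 / m))
  expect_lte(mean(frac[2, ]), 0.05 + 3 * sqrt(0.05 * 0.95 / m))
})
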