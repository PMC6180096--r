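test_that("homotypic labels require the mark on both ends and are symmetric", {
  map <- toy_map(frag_len = 1000L, n_frags = 10L, n_chrom = 1L,
                 bait_ids = c(1L, 4L))
  # peaks: H3K27me3 in fragments 1, 2 and 4; CTCF in fragments 1 and 2
  k27 <- quick_peaks("H3K27me3", c(100, 1500, 3200), c(300, 1700, 3400))
  ctcf <- quick_peaks("CTCF", c(150, 1100), c(250, 1300))
  inter <- data.table::data.table(frag1 = c(1L, 1L, 1L),
                                  frag2 = c(2L, 3L, 4L))
  lab <- classify_homotypic(inter, list(k27, ctcf), map)
  expect_equal(lab$H3K27me3, c(TRUE, FALSE, TRUE))
  expect_equal(lab$CTCF, c(TRUE, FALSE, FALSE))
  # pair 1-2 is homotypic for both marks simultaneously
  expect_true(lab[frag1 == 1L & frag2 == 2L, H3K27me3 & CTCF])
  expect_equal(lab$is_promoter_promoter, c(FALSE, FALSE, TRUE))
  # symmetry in the ends
  lab_swap <- classify_homotypic(
    data.table::data.table(frag1 = inter$frag2, frag2 = inter$frag1),
    list(k27, ctcf), map)
  expect_equal(lab_swap$H3K27me3, lab$H3K27me3)
  # empty peak set -> no labels for that mark
  none <- classify_homotypic(inter, list(quick_peaks("H3K9me3",
                                                     integer(0), integer(0))),
                             map)
  expect_false(any(none$H3K9me3))
})

test_that("cell-specific fractions are per-mark percentages with a baseline", {
  labels <- data.table::data.table(
    frag1 = 1:10, frag2 = 21:30,
    H3K27me3 = rep(c(TRUE, FALSE), each = 5L),
    is_promoter_promoter = FALSE)
  # 10 interactions; H3K27me3-homotypic = pairs 1:5; specific = pairs 1,2,6,7
  spec <- data.table::data.table(frag1 = c(1L, 2L, 6L, 7L),
                                 frag2 = c(21L, 22L, 26L, 27L))
  out <- cell_specific_fraction(labels, spec)
  expect_equal(out[mark == "all", percent_specific], 40)
  expect_equal(out[mark == "H3K27me3", percent_specific], 40)
  # empty differential set -> 0 percent everywhere
  out0 <- cell_specific_fraction(labels,
                                 data.table::data.table(frag1 = integer(),
                                                        frag2 = integer()))
  expect_equal(out0$percent_specific, c(0, 0))
  # no homotypic pairs -> NA
  labels$H3K27me3 <- FALSE
  expect_true(is.na(cell_specific_fraction(labels, spec)[
    mark == "H3K27me3", percent_specific]))
})

test_that("three-state enhancer rules match the hand-derived fixture", {
  # H3K4me1 candidates on chr1 (TSS at 50,000):
  #  A [1000,2000)   overlaps K27ac only            -> active
  #  B [3000,4000)   overlaps K27me3 only           -> poised
  #  C [5000,6000)   overlaps both                  -> poised (K27me3 wins)
  #  D [7000,8000)   overlaps neither               -> intermediate
  #  E [49400,49800) end 600 bp from TSS            -> excluded
  #  F [50100,50900) TSS-proximal (100 bp)          -> excluded
  #  G [52000,52600) 1000 bp past TSS               -> kept (boundary >= 1 kb)
  k4 <- quick_peaks("H3K4me1",
                    c(1000, 3000, 5000, 7000, 49400, 50100, 52000),
                    c(2000, 4000, 6000, 8000, 49800, 50900, 52600))
  ac <- quick_peaks("H3K27ac", c(1500, 5500, 52100), c(2500, 5600, 52200))
  me <- quick_peaks("H3K27me3", c(3900, 5900), c(4500, 6100))
  tss <- data.table::data.table(chrom = "chr1", start = 50000L, end = 50001L)
  enh <- classify_enhancers(k4, ac, me, tss)
  expect_equal(nrow(enh), 5L)
  expect_equal(enh[start == 1000L, state], "active")
  expect_equal(enh[start == 3000L, state], "poised")
  expect_equal(enh[start == 5000L, state], "poised")
  expect_equal(enh[start == 7000L, state], "intermediate")
  expect_equal(enh[start == 52000L, state], "active")
  # retained peaks are partitioned across the three states
  expect_equal(sum(table(enh$state)), nrow(enh))
})

test_that("stringent enhancers follow intersect, merge and size rules", {
  # full agreement on [0,1000)
  d <- quick_peaks("DNase", 0, 1000)
  k4 <- quick_peaks("H3K4me1", 0, 1000)
  ac <- quick_peaks("H3K27ac", 0, 1000)
  out <- stringent_active_enhancers(d, k4, ac)
  expect_equal(out[, .(start, end)],
               data.table::data.table(start = 0L, end = 1000L))
  expect_true(all(out$stringent))

  # two intersection pieces [0,150) and [350,600): gap 200 < 300 -> merged
  d <- quick_peaks("DNase", c(0, 350), c(150, 600))
  k4 <- quick_peaks("H3K4me1", 0, 600)
  ac <- quick_peaks("H3K27ac", 0, 600)
  out <- stringent_active_enhancers(d, k4, ac)
  expect_equal(out[, .(start, end)],
               data.table::data.table(start = 0L, end = 600L))

  # gap of exactly 300 is not merged; the 80 bp piece is size-filtered
  d <- quick_peaks("DNase", c(0, 450, 2000), c(150, 600, 2080))
  k4 <- quick_peaks("H3K4me1", 0, 3000)
  ac <- quick_peaks("H3K27ac", 0, 3000)
  out <- stringent_active_enhancers(d, k4, ac)
  expect_equal(out$start, c(0L, 450L))
  expect_equal(out$end, c(150L, 600L))

  # oversized intervals (> 3 kb) are dropped; pairwise separation >= merge
  d <- quick_peaks("DNase", 0, 5000)
  out <- stringent_active_enhancers(d, quick_peaks("H3K4me1", 0, 5000),
                                    quick_peaks("H3K27ac", 0, 5000))
  expect_equal(nrow(out), 0L)
})

test_that("peak signal density is count over total reads times length", {
  peaks <- quick_peaks("H3K27ac", c(0, 5000), c(1000, 5500))
  expect_equal(peak_signal_density(c(0L, 100L), 1e6, peaks),
               c(0, 100 / (1e6 * 500)))
  expect_equal(peak_signal_density(c(100L, 100L), 1e6, peaks),
               c(1e-7, 100 / (1e6 * 500)))
  # doubling the total halves every density
  expect_equal(peak_signal_density(c(50L, 80L), 2e6, peaks),
               peak_signal_density(c(50L, 80L), 1e6, peaks) / 2)
})

test_that("peak matching is injective, exact on identity, and balanced", {
  dens <- c(1e-7, 2e-7, 8e-7)
  a <- quick_peaks("A", c(0, 5000, 9000), c(1000, 5400, 11000),
                   signal_density = dens)
  m <- match_peaks(a, a, caliper = Inf)
  expect_equal(m$index_a, m$index_b)
  expect_equal(m$distance, rep(0, 3), tolerance = 1e-6)

  # two-peak fixture with an obvious assignment
  b <- quick_peaks("B", c(0, 9000), c(1050, 10950),
                   signal_density = c(1.1e-7, 7.9e-7))
  m <- match_peaks(a, b, caliper = Inf)
  expect_equal(m[index_b == 1L, index_a], 1L)
  expect_equal(m[index_b == 2L, index_a], 3L)
  expect_equal(anyDuplicated(m$index_a), 0L)

  # covariate balance after matching on shifted length distributions
  set.seed(8)
  la <- as.integer(rnorm(300, 1000, 150)); la <- pmax(la, 100L)
  lb <- as.integer(rnorm(300, 1400, 150)); lb <- pmax(lb, 100L)
  pa <- quick_peaks("A", s <- seq(0, by = 5000, length.out = 300), s + la,
                    signal_density = runif(300, 1e-8, 1e-7))
  pb <- quick_peaks("B", s2 <- seq(0, by = 5000, length.out = 300), s2 + lb,
                    signal_density = runif(300, 1e-8, 1e-7))
  m <- match_peaks(pa, pb, caliper = 0.25)
  expect_gt(nrow(m), 0L)
  len_a <- (pa$intervals$end - pa$intervals$start)[m$index_a]
  len_b <- (pb$intervals$end - pb$intervals$start)[m$index_b]
  pooled_sd <- sd(c(la, lb))
  expect_lt(abs(mean(len_a) - mean(len_b)), 0.25 * pooled_sd)
})

test_that("TF-enhancer overlap fractions count overlapping peaks", {
  enh <- data.table::data.table(chrom = "chr1",
                                start = c(0L, 10000L, 20000L),
                                end = c(1000L, 11000L, 21000L),
                                state = "active", stringent = TRUE)
  # 8 TF peaks, 3 overlapping enhancers
  tf <- quick_peaks("TFAP2C",
                    c(100, 10100, 20100, 3e4, 4e4, 5e4, 6e4, 7e4),
                    c(200, 10200, 20200, 3e4 + 100, 4e4 + 100, 5e4 + 100,
                      6e4 + 100, 7e4 + 100))
  ov <- tf_enhancer_overlap(tf, enh)
  expect_equal(ov$fraction, 0.375)
  expect_equal(ov$bound_factors, c(TRUE, TRUE, TRUE))
  # disjoint and fully-contained cases
  expect_equal(tf_enhancer_overlap(quick_peaks("X", 9e5, 9e5 + 10), enh)$fraction, 0)
  expect_equal(tf_enhancer_overlap(quick_peaks("X", 100, 150), enh)$fraction, 1)
  # no TF peaks -> undefined
  expect_true(is.na(tf_enhancer_overlap(quick_peaks("X", integer(0),
                                                    integer(0)), enh)$fraction))
})

test_that("enhancer-promoter joins map other-ends to genes and back", {
  map <- toy_map(frag_len = 1000L, n_frags = 10L, n_chrom = 1L,
                 bait_ids = c(1L, 4L))
  # gene01 on bait 1; interactions 1-6 and 1-8; active enhancer in fragment 6
  inter <- data.table::data.table(frag1 = c(1L, 1L), frag2 = c(6L, 8L))
  enh <- data.table::data.table(chrom = "chr1", start = 5200L, end = 5600L,
                                state = "poised", stringent = FALSE)
  k27 <- quick_peaks("H3K27me3", 300, 600)   # marks bait fragment 1
  j <- interaction_enhancer_join(inter, enh, map, promoter_marks = list(k27))
  expect_equal(j$gene_enhancers$gene, "gene01")
  expect_equal(nrow(j$gene_enhancers), 1L)
  expect_equal(j$gene_enhancers$state, "poised")
  expect_true(j$enhancer_promoters$promoter_H3K27me3)
  # a gene with no interactions has no enhancers
  expect_false("gene02" %in% j$gene_enhancers$gene)
  # definitional poised-contact fraction on this fixture: 1/1
  ep <- j$enhancer_promoters[state == "poised"]
  expect_equal(mean(ep$promoter_H3K27me3), 1)
})
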