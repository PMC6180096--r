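# Significant-interaction calling. The background is the coverage-product
# (random-ligation) binomial model: a read pair lands on fragments (i, j)
# with probability p_ij = 2 c_i c_j, where c_i is fragment i's relative
# coverage. Observed counts are tested against Binomial(N, p_ij) upper tails,
# adjusted by Benjamini-Hochberg, and finally filtered by a per-promoter
# significance threshold derived from each promoter's cumulative significance
# curve.

#' Binomial background test for fragment-pair counts
#'
#' For every observed pair, the null read probability is
#' `p_ij = min(1, 2 c_i c_j)` with expected count `N p_ij`; the p-value is
#' the binomial upper tail `P(X >= N_ij)`. Computation is carried in log
#' space so that deep tails do not underflow, and q-values are
#' Benjamini-Hochberg over all tested pairs.
#'
#' @param counts a [ditag_counts()].
#' @param coverage relative coverage from [relative_coverage()]; defaults to
#'   the coverage of `counts` itself.
#' @return `data.table` with columns `frag1, frag2, observed, expected,
#'   pvalue, qvalue, log_pvalue, log_qvalue, significance`
#'   (`significance = -log10 q`).
#' @export
binomial_background_test <- function(counts, coverage = relative_coverage(counts)) {
  p <- counts$pairs
  N <- counts$total_reads
  ci <- unname(coverage[as.character(p$frag1)])
  cj <- unname(coverage[as.character(p$frag2)])
  ci[is.na(ci)] <- 0; cj[is.na(cj)] <- 0
  p_bg <- pmin(1, 2 * ci * cj)
  if (any(p_bg == 0 & p$count > 0)) {
    warning("pairs with zero background probability but positive counts")
  }
  logp <- pbinom(p$count - 1L, N, p_bg, lower.tail = FALSE, log.p = TRUE)
  logq <- bh_adjust_log(logp)
  data.table(frag1 = p$frag1, frag2 = p$frag2,
             observed = p$count, expected = N * p_bg,
             pvalue = exp(logp), qvalue = exp(logq),
             log_pvalue = logp, log_qvalue = logq,
             significance = -logq / log(10))
}

#' Promoter-specific significance threshold
#'
#' Implements the per-promoter threshold construction: take the cumulative
#' distribution of the promoter's interaction significances (`s = -log10 q`)
#' on a uniform grid, form its first derivative (the significance density),
#' smooth it with a short moving average, and place the threshold at the
#' inflection of that derivative - the point where its curvature (second
#' finite difference) turns from negative to positive, i.e. where the decline
#' from the bulk of weak interactions has levelled off. Among such
#' inflections, the one closest to the curve's antimode (the first
#' near-empty region after the main mode, found on a more heavily smoothed
#' density) is chosen, searching from below.
#'
#' The promoter falls back to a global threshold of `-log10(fallback_q)`
#' when it has fewer than `min_interactions` interactions, when its
#' significance distribution shows no antimode (density at the candidate
#' antimode above `bimodal_ratio` times the modal density), or when no
#' curvature sign change exists below the antimode.
#'
#' @param significances numeric vector of `-log10 q` values for one
#'   promoter's interactions, or a table with a `significance` column.
#' @param grid_points number of grid points for the cumulative curve.
#' @param smoothing_window moving-average width (odd) for the derivative.
#' @param min_interactions minimum number of interactions for the
#'   inflection construction.
#' @param fallback_q global q-value cutoff used by the fallback.
#' @param bimodal_ratio maximum antimode/mode density ratio for the
#'   inflection construction to be trusted.
#' @param method `"inflection"` (curvature sign change of the smoothed
#'   derivative, the literal construction) or `"derivative_minimum"` (place
#'   the threshold at the antimode itself).
#' @return list with `threshold_s`, `method` (`"inflection"` or
#'   `"global_fallback"`), and `n_interactions`.
#' @export
promoter_threshold <- function(significances, grid_points = 256L,
                               smoothing_window = 5L, min_interactions = 10L,
                               fallback_q = 0.05, bimodal_ratio = 0.1,
                               method = c("inflection", "derivative_minimum")) {
  method <- match.arg(method)
  s <- if (is.numeric(significances)) significances else significances$significance
  s <- s[is.finite(s)]
  floor_s <- -log10(fallback_q)
  fallback <- list(threshold_s = floor_s, method = "global_fallback",
                   n_interactions = length(s))
  if (length(s) < min_interactions || diff(range(s)) < 1e-9) return(fallback)

  brk <- seq(0, max(s), length.out = grid_points + 1L)
  mid <- (brk[-1L] + brk[-length(brk)]) / 2
  dens <- tabulate(pmin(findInterval(s, brk, rightmost.closed = TRUE),
                        grid_points), grid_points) / length(s)
  d_smooth <- moving_average(dens, smoothing_window)
  heavy_window <- max(smoothing_window, 2L * (grid_points %/% 32L) + 1L)
  heavy <- moving_average(dens, heavy_window)

  mode_i <- which.max(heavy)
  if (mode_i >= grid_points) return(fallback)
  zero <- which(heavy[(mode_i + 1L):grid_points] <= 1e-15) + mode_i
  if (!length(zero)) return(fallback)
  first_run <- zero[seq_len(match(TRUE, diff(zero) != 1L,
                                  nomatch = length(zero)))]
  antimode <- as.integer(round(median(first_run)))
  if (heavy[antimode] > bimodal_ratio * heavy[mode_i]) return(fallback)

  if (method == "derivative_minimum") {
    return(list(threshold_s = max(mid[antimode], floor_s),
                method = "inflection", n_interactions = length(s)))
  }

  # curvature of the smoothed derivative; candidates are the ends of
  # negative-to-positive sign-change runs (the derivative has levelled off)
  d2 <- c(0, diff(d_smooth, differences = 2L), 0)
  nz <- which(abs(d2) > 1e-15)
  cand <- integer(0)
  if (length(nz) >= 2L) {
    sg <- sign(d2[nz])
    changes <- which(sg[-length(sg)] < 0 & sg[-1L] > 0)
    cand <- vapply(changes, function(j) {
      k <- j + 1L
      while (k < length(nz) && nz[k + 1L] == nz[k] + 1L && sg[k + 1L] > 0) {
        k <- k + 1L
      }
      nz[k]
    }, integer(1L))
  }
  cand <- cand[cand <= antimode]
  if (!length(cand)) return(fallback)
  pick <- cand[which.min(abs(cand - antimode))]
  list(threshold_s = max(mid[pick], floor_s), method = "inflection",
       n_interactions = length(s))
}

#' Call significant promoter interactions
#'
#' Pools replicate ditag tables by count summation, runs the binomial
#' background test, estimates a per-promoter threshold for every bait from
#' the significances of all interactions touching that bait, and keeps
#' interactions whose significance is at or above their bait's threshold
#' (for promoter-promoter pairs: above either end's threshold). Pairs with
#' no bait end are excluded from calling.
#'
#' @param replicates a [ditag_counts()] or list of replicate tables.
#' @param map a [fragment_map()] carrying the bait annotation.
#' @param exclude_chroms chromosomes removed before testing (e.g.
#'   `c("chrX", "chrY")` for sex-chromosome exclusion); `NULL` keeps all.
#' @param min_distance optional minimum cis midpoint distance in bp; pairs
#'   closer than this are removed before testing (0 keeps all).
#' @param ... passed to [promoter_threshold()].
#' @return list of class `interaction_calls`: `calls` (test results plus
#'   `bait1`, `bait2`, `category` = promoter_genome/promoter_promoter,
#'   `distance`, `passes`), `thresholds` (per-bait table), `total_reads`.
#' @export
call_significant <- function(replicates, map, exclude_chroms = NULL,
                             min_distance = 0, ...) {
  counts <- pool_replicates(replicates)
  fr <- map$fragments
  pairs <- counts$pairs
  if (!is.null(exclude_chroms)) {
    drop <- fr$fragment_id[fr$chrom %in% exclude_chroms]
    pairs <- pairs[!(frag1 %in% drop) & !(frag2 %in% drop)]
  }
  dist <- fragment_distance(map, pairs$frag1, pairs$frag2)
  if (min_distance > 0) {
    keep <- !is.finite(dist) | dist >= min_distance
    pairs <- pairs[keep]; dist <- dist[keep]
  }
  counts <- ditag_counts(pairs, condition = counts$condition)
  dist <- fragment_distance(map, counts$pairs$frag1, counts$pairs$frag2)

  calls <- binomial_background_test(counts)
  calls[, `:=`(bait1 = fr$bait[frag1], bait2 = fr$bait[frag2],
               distance = dist)]
  n_nobait <- calls[, sum(!bait1 & !bait2)]
  if (n_nobait > 0L) {
    message(sprintf("call_significant: dropping %d pair(s) with no bait end",
                    n_nobait))
  }
  calls <- calls[bait1 | bait2]
  calls[, category := fifelse(bait1 & bait2, "promoter_promoter",
                              "promoter_genome")]

  thresholds <- rbindlist(lapply(bait_ids(map), function(b) {
    s <- calls[frag1 == b | frag2 == b, significance]
    if (!length(s)) return(NULL)
    th <- promoter_threshold(s, ...)
    data.table(bait_id = b, threshold_s = th$threshold_s,
               method = th$method, n_interactions = th$n_interactions)
  }))
  empty <- setdiff(bait_ids(map), thresholds$bait_id)
  if (length(empty)) {
    message(sprintf("call_significant: %d bait(s) with zero interactions",
                    length(empty)))
  }
  thr <- setNames(thresholds$threshold_s, thresholds$bait_id)
  t1 <- ifelse(calls$bait1, thr[as.character(calls$frag1)], Inf)
  t2 <- ifelse(calls$bait2, thr[as.character(calls$frag2)], Inf)
  calls[, passes := significance >= pmin(t1, t2, na.rm = TRUE)]
  structure(list(calls = calls[], thresholds = thresholds,
                 total_reads = counts$total_reads,
                 condition = counts$condition),
            class = "interaction_calls")
}

#' @export
print.interaction_calls <- function(x, ...) {
  cat(sprintf(
    "interaction_calls '%s': %d tested pairs, %d significant (%d promoter-promoter)\n",
    x$condition, nrow(x$calls), sum(x$calls$passes),
    sum(x$calls$passes & x$calls$category == "promoter_promoter")))
  invisible(x)
}

#' Write calls in an ibed-like layout
#'
#' Tab-delimited: bait fragment coordinates and gene, other-end coordinates,
#' observed, expected, p, q, significance and threshold pass flag.
#'
#' @param calls an `interaction_calls` object.
#' @param map the [fragment_map()] used for calling.
#' @param path output path.
#' @param significant_only write only threshold-passing calls.
#' @export
write_ibed <- function(calls, map, path, significant_only = TRUE) {
  fr <- map$fragments
  dt <- calls$calls
  if (significant_only) dt <- dt[passes == TRUE]
  bait <- fifelse(dt$bait1, dt$frag1, dt$frag2)
  oe <- fifelse(dt$bait1, dt$frag2, dt$frag1)
  genes <- if (!is.null(map$bait_genes)) {
    map$bait_genes[, paste(gene, collapse = ";"), by = fragment_id]
  } else data.table(fragment_id = integer(), V1 = character())
  out <- data.table(
    bait_chrom = fr$chrom[bait], bait_start = fr$start[bait],
    bait_end = fr$end[bait],
    bait_name = genes$V1[match(bait, genes$fragment_id)],
    oe_chrom = fr$chrom[oe], oe_start = fr$start[oe], oe_end = fr$end[oe],
    observed = dt$observed, expected = signif(dt$expected, 6),
    pvalue = dt$pvalue, qvalue = dt$qvalue,
    significance = signif(dt$significance, 6),
    category = dt$category, passes = as.integer(dt$passes))
  fwrite(out, path, sep = "\t")
  invisible(path)
}
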