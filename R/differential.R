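# Differential interaction calling between two conditions. The test
# condition's counts are compared against expected values taken from the
# reference condition, scaled by the total captured reads of each condition:
# p = n_ref / N_ref and n_test ~ Binomial(N_test, p) under the null. Pairs
# detected in only one condition receive a pseudocount of 1 in the condition
# with the missing value. Multiple testing is controlled by a covariate-
# weighted (independent hypothesis weighting style) Benjamini-Hochberg
# procedure at a 5% false discovery rate.

#' One-directional differential interaction test
#'
#' Tests enrichment in the `test` condition relative to `ref` over the union
#' of pairs observed in either table. Run a second time with the roles
#' swapped to obtain the other specificity direction.
#'
#' @param test,ref [ditag_counts()] objects over the same fragment map.
#' @return `data.table` with `frag1, frag2, n_test, n_ref` (post-pseudocount),
#'   `N_test, N_ref, log2_ratio, pvalue, log_pvalue`.
#' @export
differential_test <- function(test, ref) {
  N_test <- test$total_reads
  N_ref <- ref$total_reads
  if (N_ref == 0) stop("reference table has no reads")
  u <- merge(test$pairs, ref$pairs, by = c("frag1", "frag2"), all = TRUE,
             suffixes = c("_test", "_ref"))
  u[is.na(count_test), count_test := 0L]
  u[is.na(count_ref), count_ref := 0L]
  u <- u[count_test + count_ref > 0L]
  # pseudocount only where exactly one condition has a missing value
  u[count_ref == 0L & count_test > 0L, count_ref := 1L]
  u[count_test == 0L & count_ref > 0L, count_test := 1L]
  p0 <- u$count_ref / N_ref
  logp <- pbinom(u$count_test - 1L, N_test, pmin(p0, 1), lower.tail = FALSE,
                 log.p = TRUE)
  data.table(frag1 = u$frag1, frag2 = u$frag2,
             n_test = u$count_test, n_ref = u$count_ref,
             N_test = N_test, N_ref = N_ref,
             log2_ratio = log2((u$count_test / N_test) / (u$count_ref / N_ref)),
             pvalue = exp(logp), log_pvalue = logp)
}

#' Covariate-weighted FDR adjustment (simplified IHW)
#'
#' Splits the covariate into `n_bins` quantile bins and learns one
#' non-negative weight per bin, constrained to mean 1 over tests, by
#' cross-fold grid search: per-bin non-null proportions are estimated on the
#' training folds (Storey-type, lambda = 0.5), a one-parameter exponent
#' family of weight vectors built from them is scored by the number of
#' weighted-BH discoveries it yields on the training folds (averaged over a
#' fixed small ladder of FDR levels), and the winning weights are
#' applied to the held-out fold. Weighted q-values are Benjamini-Hochberg on
#' `p / w`. With `n_bins = 1` all weights are exactly 1 and the result
#' equals plain BH.
#'
#' Non-finite covariate values (e.g. trans-pair distances) are placed in a
#' bin of their own.
#'
#' @param pvalues numeric p-values.
#' @param covariate per-test covariate, independent of p under the null.
#' @param n_bins number of quantile bins (>= 1).
#' @param alpha nominal FDR level the weights are tuned for.
#' @param n_folds cross-fitting folds.
#' @param seed seed for the fold assignment.
#' @return list of class `ihw_result`: `qvalues` (weighted), `weights`
#'   (per-bin, mean 1 over tests), `bins` (per-test bin index), `bin_edges`,
#'   `alpha`, `per_test_weight`.
#' @export
ihw_adjust <- function(pvalues, covariate = NULL, n_bins = 8L, alpha = 0.05,
                       n_folds = 5L, seed = 1L) {
  m <- length(pvalues)
  stopifnot(all(pvalues >= 0 & pvalues <= 1), n_bins >= 1L)
  if (n_bins > 1L && m < 10L * n_bins) {
    warning("fewer than 10 tests per bin; collapsing to one bin")
    n_bins <- 1L
  }
  if (n_bins == 1L || is.null(covariate)) {
    q <- bh_adjust(pvalues)
    return(structure(list(qvalues = q, weights = 1, bins = rep(1L, m),
                          bin_edges = c(-Inf, Inf), alpha = alpha,
                          per_test_weight = rep(1, m)),
                     class = "ihw_result"))
  }
  stopifnot(length(covariate) == m)
  finite <- is.finite(covariate)
  edges <- unique(quantile(covariate[finite],
                           probs = seq(0, 1, length.out = n_bins + 1L),
                           names = FALSE))
  bins <- rep(1L, m)
  bins[finite] <- cut(covariate[finite], breaks = edges,
                      include.lowest = TRUE, labels = FALSE)
  if (any(!finite)) bins[!finite] <- max(bins[finite]) + 1L
  G <- max(bins)

  weighted_bh <- function(p, w) bh_adjust(pmin(p / w, 1))
  lambda_grid <- c(0, 0.5, 1, 2, 4)
  # weights are scored on a fixed ladder of FDR levels so that the learned
  # weights - and hence the discovery set - are monotone in the level the
  # caller later thresholds at
  level_ladder <- c(0.02, 0.05, 0.1)
  eps <- 0.05

  pi1_hat <- function(p, b) {
    vapply(seq_len(G), function(g) {
      pg <- p[b == g]
      if (!length(pg)) return(0)
      pi0 <- min(1, mean(pg > 0.5) / 0.5)
      max(0, 1 - pi0)
    }, numeric(1))
  }
  normalise <- function(w_raw, b) {
    mg <- tabulate(b, G)
    w <- w_raw / sum(mg * w_raw) * sum(mg)
    w
  }

  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), m))
  per_w <- numeric(m)
  w_by_fold <- matrix(1, n_folds, G)
  for (f in seq_len(n_folds)) {
    train <- fold != f
    pi1 <- pi1_hat(pvalues[train], bins[train])
    score <- vapply(lambda_grid, function(lam) {
      w <- normalise((pi1 + eps)^lam, bins[train])
      qtr <- weighted_bh(pvalues[train], w[bins[train]])
      mean(vapply(level_ladder, function(a) sum(qtr <= a), numeric(1)))
    }, numeric(1))
    lam <- lambda_grid[which.max(score)]   # ties resolve toward plain BH
    w_hold <- normalise((pi1 + eps)^lam, bins[!train])
    per_w[!train] <- w_hold[bins[!train]]
  }
  qvalues <- weighted_bh(pvalues, per_w)
  # reported summary weights: per-bin mean of the applied weights,
  # renormalised to the exact mean-1 budget
  w_bar <- vapply(seq_len(G), function(g) mean(per_w[bins == g]), numeric(1))
  w_bar <- normalise(w_bar, bins)
  structure(list(qvalues = qvalues, weights = w_bar, bins = bins,
                 bin_edges = edges, alpha = alpha, per_test_weight = per_w),
            class = "ihw_result")
}

#' Call cell-type-specific differential interactions
#'
#' Runs [differential_test()] in both directions (test vs ref and ref vs
#' test), applies [ihw_adjust()] with `log10` pair distance as the covariate
#' (trans pairs in their own bin) to each direction, and returns the pairs
#' with weighted `q <= alpha`, labelled `test_specific` or `ref_specific`.
#' A pair significant in both directions (possible only at the discreteness
#' floor) is assigned to the direction with the smaller q-value.
#'
#' @param test,ref [ditag_counts()] objects.
#' @param map the common [fragment_map()].
#' @param alpha FDR level.
#' @param n_bins,n_folds,seed passed to [ihw_adjust()].
#' @param match_depth subsample the deeper table to the shallower one's
#'   depth before testing.
#' @return list of class `differential_calls`: `table` (all tested pairs
#'   with both directions' p and q, `direction`, `significant`), `alpha`,
#'   plus the two `ihw_result` objects.
#' @export
call_differential <- function(test, ref, map, alpha = 0.05, n_bins = 8L,
                              n_folds = 5L, seed = 1L, match_depth = FALSE) {
  if (match_depth) {
    target <- min(test$total_reads, ref$total_reads)
    test <- subsample_to_depth(test, target, seed = seed)
    ref <- subsample_to_depth(ref, target, seed = seed + 1L)
  }
  fwd <- differential_test(test, ref)
  bwd <- differential_test(ref, test)
  bwd <- bwd[, .(frag1, frag2, log2_ratio_rev = log2_ratio,
                 pvalue_rev = pvalue, log_pvalue_rev = log_pvalue)]
  tab <- merge(fwd, bwd, by = c("frag1", "frag2"))
  dist <- fragment_distance(map, tab$frag1, tab$frag2)
  covariate <- log10(dist + 1)
  ihw_fwd <- ihw_adjust(tab$pvalue, covariate, n_bins = n_bins,
                        alpha = alpha, n_folds = n_folds, seed = seed)
  ihw_rev <- ihw_adjust(tab$pvalue_rev, covariate, n_bins = n_bins,
                        alpha = alpha, n_folds = n_folds, seed = seed)
  tab[, `:=`(distance = dist, qvalue = ihw_fwd$qvalues,
             qvalue_rev = ihw_rev$qvalues)]
  sig_fwd <- tab$qvalue <= alpha
  sig_rev <- tab$qvalue_rev <= alpha
  both <- sig_fwd & sig_rev
  sig_fwd[both] <- tab$qvalue[both] <= tab$qvalue_rev[both]
  sig_rev[both] <- !sig_fwd[both]
  tab[, direction := fifelse(sig_fwd, "test_specific",
                             fifelse(sig_rev, "ref_specific", "none"))]
  tab[, significant := direction != "none"]
  structure(list(table = tab[], alpha = alpha, ihw_test = ihw_fwd,
                 ihw_ref = ihw_rev,
                 conditions = c(test = test$condition, ref = ref$condition)),
            class = "differential_calls")
}

#' @export
print.differential_calls <- function(x, ...) {
  tb <- table(x$table$direction)
  cat(sprintf(
    "differential_calls (%s vs %s): %d pairs tested; %d test-specific, %d ref-specific at q <= %g\n",
    x$conditions[["test"]], x$conditions[["ref"]], nrow(x$table),
    sum(x$table$direction == "test_specific"),
    sum(x$table$direction == "ref_specific"), x$alpha))
  invisible(x)
}

#' Write a differential interaction table
#'
#' @param diff a `differential_calls` object.
#' @param path output path.
#' @param significant_only keep only significant pairs.
#' @export
write_differential <- function(diff, path, significant_only = FALSE) {
  dt <- diff$table
  if (significant_only) dt <- dt[significant == TRUE]
  fwrite(dt[, .(frag1, frag2, n_test, n_ref, N_test, N_ref, distance,
                log2_ratio, pvalue, qvalue, pvalue_rev, qvalue_rev,
                direction)], path, sep = "\t")
  invisible(path)
}
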