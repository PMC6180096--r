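# Expression integration: FPKM thresholding, between-condition expression
# ratios for interaction-defined gene groups, k-means clustering of
# expression profiles, cluster enrichment of annotated gene sets, and the
# group-comparison statistics used alongside them.

#' Expression filter on log2 FPKM
#'
#' A gene is retained when its maximum `log2(FPKM)` over samples reaches the
#' threshold (zero FPKM counts as `-Inf`). Typical thresholds: -1 for
#' standard datasets, -3 for low-depth knockout series.
#'
#' @param fpkm numeric matrix, genes x samples, FPKM (>= 0), rownames = genes.
#' @param log2_fpkm_threshold threshold on `log2(FPKM)`.
#' @return named logical vector (the expressed mask).
#' @export
filter_expressed <- function(fpkm, log2_fpkm_threshold = -1) {
  stopifnot(is.matrix(fpkm), all(fpkm >= 0), is.finite(log2_fpkm_threshold))
  lg <- suppressWarnings(log2(fpkm))
  lg[fpkm == 0] <- -Inf
  apply(lg, 1L, max) >= log2_fpkm_threshold
}

#' Per-gene log2 expression ratio between two samples
#'
#' @param fpkm FPKM matrix.
#' @param numerator_sample,denominator_sample column names.
#' @param pseudo pseudo-count added to both FPKM values.
#' @return named numeric vector of `log2((num + pseudo)/(den + pseudo))`.
#' @export
expression_log2_ratio <- function(fpkm, numerator_sample, denominator_sample,
                                  pseudo = 0.01) {
  stopifnot(numerator_sample %in% colnames(fpkm),
            denominator_sample %in% colnames(fpkm))
  log2((fpkm[, numerator_sample] + pseudo) /
         (fpkm[, denominator_sample] + pseudo))
}

#' Box-plot summary with 1.5 x IQR whiskers
#'
#' Median and quartiles (default quantile convention), with whiskers at the
#' last data points within 1.5 times the interquartile range of the box.
#'
#' @param x numeric vector.
#' @return list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`, `n`.
#' @export
boxplot_stats <- function(x) {
  x <- x[is.finite(x)]
  qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- qs[3L] - qs[1L]
  lo <- x[x >= qs[1L] - 1.5 * iqr]
  hi <- x[x <= qs[3L] + 1.5 * iqr]
  list(median = qs[2L], q1 = qs[1L], q3 = qs[3L],
       whisker_low = if (length(lo)) min(lo) else NA_real_,
       whisker_high = if (length(hi)) max(hi) else NA_real_,
       n = length(x))
}

#' Compare expression ratios between gene groups
#'
#' Per-group box-plot summaries plus Welch two-sample t-tests for every
#' group pair, Benjamini-Hochberg corrected across the comparison family.
#' Groups with fewer than two members get a summary but no test.
#'
#' @param ratios named numeric vector (e.g. from
#'   [expression_log2_ratio()]).
#' @param gene_groups named list of gene-name vectors.
#' @return list with `summaries` (`data.table`) and `tests` (`data.table`
#'   of pairwise Welch tests with `p_adjusted`).
#' @export
group_ratio_comparison <- function(ratios, gene_groups) {
  stopifnot(!is.null(names(ratios)), length(gene_groups) >= 1L)
  vals <- lapply(gene_groups, function(g) ratios[intersect(g, names(ratios))])
  summaries <- rbindlist(lapply(names(vals), function(nm) {
    c(list(group = nm), boxplot_stats(vals[[nm]]))
  }))
  combos <- if (length(vals) >= 2L) utils::combn(names(vals), 2L) else NULL
  tests <- if (!is.null(combos)) {
    rbindlist(apply(combos, 2L, function(pair) {
      a <- vals[[pair[1L]]]; b <- vals[[pair[2L]]]
      if (length(a) < 2L || length(b) < 2L) return(NULL)
      tt <- t.test(a, b)   # Welch by default
      data.table(group1 = pair[1L], group2 = pair[2L],
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), pvalue = tt$p.value)
    }))
  } else data.table()
  if (nrow(tests)) tests[, p_adjusted := bh_adjust(pvalue)]
  list(summaries = summaries, tests = tests)
}

#' K-means clustering of expression profiles
#'
#' Profiles are per-gene z-scores of `log2(FPKM + pseudo)` across the
#' ordered samples; Lloyd's algorithm is run with `n_restarts` seeded random
#' initialisations and the lowest-inertia solution is kept. Genes failing
#' the expression mask or with zero profile variance are dropped (the
#' latter are reported by message).
#'
#' @param fpkm FPKM matrix.
#' @param samples_order column order defining the profile; defaults to all
#'   columns.
#' @param k number of clusters.
#' @param seed RNG seed (results are deterministic given the seed).
#' @param n_restarts random restarts.
#' @param pseudo pseudo-count for the log transform.
#' @param expressed_mask logical mask from [filter_expressed()]; defaults
#'   to all genes.
#' @return list of class `cluster_model`: `assignment` (named integer),
#'   `centroids` (k x samples), `inertia`, `profiles`, `k`, `seed`.
#' @export
kmeans_profiles <- function(fpkm, samples_order = colnames(fpkm), k = 7L,
                            seed = 1L, n_restarts = 25L, pseudo = 0.01,
                            expressed_mask = NULL) {
  stopifnot(all(samples_order %in% colnames(fpkm)))
  x <- fpkm[, samples_order, drop = FALSE]
  if (!is.null(expressed_mask)) x <- x[expressed_mask, , drop = FALSE]
  lx <- log2(x + pseudo)
  mu <- rowMeans(lx)
  sdv <- apply(lx, 1L, sd)
  degenerate <- sdv == 0 | is.na(sdv)
  if (any(degenerate)) {
    message(sprintf("kmeans_profiles: dropping %d zero-variance gene(s)",
                    sum(degenerate)))
  }
  z <- (lx[!degenerate, , drop = FALSE] - mu[!degenerate]) / sdv[!degenerate]
  stopifnot(nrow(z) >= k)
  set.seed(seed)
  # Lloyd restarts can transiently empty a cluster; the best-inertia
  # solution over restarts is kept, so those runs are harmless
  km <- suppressWarnings(kmeans(z, centers = k, algorithm = "Lloyd",
                                nstart = n_restarts, iter.max = 200L))
  structure(list(assignment = setNames(km$cluster, rownames(z)),
                 centroids = km$centers, inertia = km$tot.withinss,
                 profiles = z, k = k, seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: %d genes in %d clusters (inertia %.2f)\n",
              length(x$assignment), x$k, x$inertia))
  invisible(x)
}

#' Cluster enrichment of annotated gene sets
#'
#' `enrichment(f, c) = (|annotated_f in cluster c| / |cluster c|) /
#' (|annotated_f| / |all clustered genes|)` - the representation of factor-
#' annotated genes in each cluster relative to their overall abundance.
#'
#' @param model a `cluster_model` (or named assignment vector).
#' @param annotated_genes named list: factor -> gene names (subsets of the
#'   clustered genes).
#' @return numeric matrix factor x cluster; empty clusters give `NA`.
#' @export
cluster_enrichment <- function(model, annotated_genes) {
  assign <- if (inherits(model, "cluster_model")) model$assignment else model
  k <- max(assign)
  total <- length(assign)
  csize <- tabulate(assign, k)
  out <- matrix(NA_real_, length(annotated_genes), k,
                dimnames = list(names(annotated_genes), seq_len(k)))
  for (f in names(annotated_genes)) {
    genes <- intersect(annotated_genes[[f]], names(assign))
    if (!length(genes)) next
    overall <- length(genes) / total
    inC <- tabulate(assign[genes], k)
    out[f, ] <- ifelse(csize > 0L, (inC / csize) / overall, NA_real_)
  }
  out
}

#' Chi-squared and two-proportion tests for categorical tables
#'
#' Pearson chi-squared without continuity correction on a 2 x k table
#' (df = k - 1), plus the two-proportion z-test when k = 2. Expected cells
#' below 1 raise a warning flag in the output.
#'
#' @param counts 2 x k matrix of non-negative integers.
#' @return list with `chisq` (statistic, df, pvalue, low_expected flag) and,
#'   for 2 x 2 tables, `proportions` (statistic, pvalue).
#' @export
categorical_tests <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == 2L, all(counts >= 0))
  cs <- suppressWarnings(chisq.test(counts, correct = FALSE))
  out <- list(chisq = list(statistic = unname(cs$statistic),
                           df = unname(cs$parameter),
                           pvalue = cs$p.value,
                           low_expected = any(cs$expected < 1)))
  if (ncol(counts) == 2L) {
    pt <- suppressWarnings(prop.test(counts[, 1L], rowSums(counts),
                                     correct = FALSE))
    out$proportions <- list(statistic = unname(pt$statistic),
                            pvalue = pt$p.value)
  }
  out
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' @param values numeric responses.
#' @param groups group labels (>= 2 groups, each with >= 2 values).
#' @return list with `F`, `pvalue`, and `tukey` (`data.table` of pairwise
#'   differences with studentised-range adjusted p-values).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2L, all(table(groups) >= 2L))
  fit <- aov(values ~ groups)
  sm <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$groups
  list(F = sm[["F value"]][1L], pvalue = sm[["Pr(>F)"]][1L],
       tukey = data.table(comparison = rownames(tk),
                          diff = tk[, "diff"], p_adjusted = tk[, "p adj"]))
}
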