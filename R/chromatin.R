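# Chromatin-mark overlays on interactions: homotypic classification (both
# ends of an interaction carrying the same mark), three-state enhancer
# annotation from H3K4me1/H3K27ac/H3K27me3, a stringent active-enhancer
# definition from DNase/H3K4me1/H3K27ac intersection, covariate-matched peak
# selection, and joins between enhancers and the promoter interactome.

#' Construct a peak set
#'
#' @param intervals interval table (chrom/start/end, optional name/score).
#' @param mark mark or factor name (e.g. `"H3K27me3"`, `"CTCF"`).
#' @param signal_density optional per-peak signal density.
#' @return list of class `peak_set` with `mark` and `intervals` (the
#'   intervals gain a `signal_density` column when supplied).
#' @export
peak_set <- function(intervals, mark, signal_density = NULL) {
  dt <- copy(as.data.table(intervals))
  stopifnot(all(dt$start < dt$end))
  if (!is.null(signal_density)) {
    stopifnot(length(signal_density) == nrow(dt), all(signal_density >= 0))
    dt[, signal_density := ..signal_density]
  }
  setorder(dt, chrom, start, end)
  structure(list(mark = mark, intervals = dt[]), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d peaks\n", x$mark, nrow(x$intervals)))
  invisible(x)
}

#' ChIP-seq signal density of peaks
#'
#' Normalises the read count at each peak by the library's total read count
#' and the peak length: `density = count / (total_reads * length)`.
#'
#' @param peak_read_counts integer reads per peak.
#' @param total_reads total mapped reads of the library.
#' @param peaks a [peak_set()] or interval table (for peak lengths).
#' @return numeric densities (reads per read per bp).
#' @export
peak_signal_density <- function(peak_read_counts, total_reads, peaks) {
  iv <- if (inherits(peaks, "peak_set")) peaks$intervals else as.data.table(peaks)
  stopifnot(total_reads >= 1, nrow(iv) == length(peak_read_counts),
            all(iv$end > iv$start))
  peak_read_counts / (total_reads * (iv$end - iv$start))
}

# fragment ids whose interval overlaps >= min_bp of any peak in the set
marked_fragments <- function(map, peaks, min_bp = 1L) {
  iv <- if (inherits(peaks, "peak_set")) peaks$intervals else as.data.table(peaks)
  if (!nrow(iv)) return(integer(0))
  hits <- GenomicRanges::findOverlaps(as_granges(map$fragments), as_granges(iv),
                                      minoverlap = min_bp)
  unique(map$fragments$fragment_id[S4Vectors::queryHits(hits)])
}

#' Classify homotypic interactions
#'
#' An interaction is homotypic for a mark when both of its fragments overlap
#' at least one peak of that mark (by at least `min_bp`). A pair may be
#' homotypic for several marks at once; classification is symmetric in the
#' two ends.
#'
#' @param interactions table with `frag1`, `frag2` columns (e.g. the calls
#'   of [call_significant()]).
#' @param peaksets list of [peak_set()] objects.
#' @param map the [fragment_map()].
#' @param min_bp minimum fragment/peak overlap.
#' @return `data.table` with `frag1`, `frag2`, one logical column per mark,
#'   and `is_promoter_promoter`.
#' @export
classify_homotypic <- function(interactions, peaksets, map, min_bp = 1L) {
  dt <- as.data.table(interactions)[, .(frag1, frag2)]
  fr <- map$fragments
  out <- copy(dt)
  for (ps in peaksets) {
    marked <- marked_fragments(map, ps, min_bp = min_bp)
    out[, (ps$mark) := frag1 %in% marked & frag2 %in% marked]
  }
  out[, is_promoter_promoter := fr$bait[frag1] & fr$bait[frag2]]
  out[]
}

#' Cell-specific fraction of (homotypic) interactions
#'
#' For each mark, the percentage of the mark's homotypic interactions that
#' are cell-specific, plus an `all` baseline over the whole interaction
#' universe. Marks with zero homotypic pairs are reported as `NA`.
#'
#' @param labels output of [classify_homotypic()].
#' @param specific_pairs table of cell-specific pairs (`frag1`, `frag2`).
#' @return `data.table(mark, n_interactions, n_specific, percent_specific)`.
#' @export
cell_specific_fraction <- function(labels, specific_pairs) {
  sp <- as.data.table(specific_pairs)[, .(frag1, frag2)]
  key <- paste(labels$frag1, labels$frag2)
  specific <- key %in% paste(sp$frag1, sp$frag2)
  marks <- setdiff(names(labels), c("frag1", "frag2", "is_promoter_promoter"))
  rows <- lapply(c("all", marks), function(mk) {
    sel <- if (mk == "all") rep(TRUE, nrow(labels)) else labels[[mk]]
    n <- sum(sel)
    ns <- sum(sel & specific)
    data.table(mark = mk, n_interactions = n, n_specific = ns,
               percent_specific = if (n > 0L) 100 * ns / n else NA_real_)
  })
  rbindlist(rows)
}

# gap between a peak interval and a set of TSS points (0 when the TSS falls
# inside the half-open interval)
tss_points <- function(tss) {
  iv <- if (inherits(tss, "peak_set")) tss$intervals else as.data.table(tss)
  if ("strand" %in% names(iv)) {
    fifelse(iv$strand == "-", iv$end - 1L, iv$start)
  } else if (all(iv$end - iv$start == 1L)) {
    iv$start
  } else {
    as.integer(floor((iv$start + iv$end) / 2))
  }
}

#' Three-state enhancer classification
#'
#' H3K4me1 peaks are classified by the literal rule set: overlapping H3K27ac
#' but not H3K27me3 = `active`; overlapping H3K27me3 (regardless of
#' H3K27ac) = `poised`; overlapping neither = `intermediate`. Peaks whose
#' closest end lies within `tss_exclusion_bp` of a transcription start site
#' (overlap counts as distance 0) are excluded before classification.
#'
#' @param h3k4me1,h3k27ac,h3k27me3 [peak_set()] objects.
#' @param tss TSS intervals; strand-aware when a `strand` column is present,
#'   otherwise 1-bp intervals are taken at their start and wider intervals
#'   at their midpoint.
#' @param tss_exclusion_bp exclusion radius around TSSs in bp.
#' @param min_bp minimum overlap for the classification rules.
#' @return `data.table` of enhancer elements: interval columns plus `state`
#'   and `stringent = FALSE`.
#' @export
classify_enhancers <- function(h3k4me1, h3k27ac, h3k27me3, tss,
                               tss_exclusion_bp = 1000L, min_bp = 1L) {
  k4 <- h3k4me1$intervals
  tssdt <- if (inherits(tss, "peak_set")) tss$intervals else as.data.table(tss)
  keep <- rep(TRUE, nrow(k4))
  if (nrow(tssdt)) {
    pts <- data.table(chrom = tssdt$chrom, pos = tss_points(tss))
    for (cc in unique(k4$chrom)) {
      p <- sort(pts[chrom == cc, pos])
      if (!length(p)) next
      sel <- which(k4$chrom == cc)
      # distance from the peak's closest end to the nearest TSS point
      near <- function(x) {
        i <- findInterval(x, p)
        lo <- ifelse(i >= 1L, x - p[pmax(i, 1L)], Inf)
        hi <- ifelse(i < length(p), p[pmin(i + 1L, length(p))] - x, Inf)
        pmin(lo, hi)
      }
      s <- k4$start[sel]; e <- k4$end[sel]
      inside <- vapply(seq_along(sel), function(k) {
        i <- findInterval(e[k] - 1L, p)
        i >= 1L && p[i] >= s[k]
      }, logical(1L))
      gap <- pmin(near(s), near(e - 1L))
      keep[sel] <- !(inside | gap < tss_exclusion_bp)
    }
  }
  k4 <- k4[keep]
  if (!nrow(k4)) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), state = character(),
                      stringent = logical()))
  }
  ov <- function(ps) {
    if (!nrow(ps$intervals)) return(rep(FALSE, nrow(k4)))
    IRanges::overlapsAny(as_granges(k4), as_granges(ps$intervals),
                         minoverlap = min_bp)
  }
  ac <- ov(h3k27ac)
  me3 <- ov(h3k27me3)
  out <- k4[, .(chrom, start, end)]
  out[, state := fifelse(me3, "poised",
                         fifelse(ac, "active", "intermediate"))]
  out[, stringent := FALSE]
  out[]
}

#' Stringent active enhancers
#'
#' Base-pair three-way intersection of DNase, H3K4me1 and H3K27ac peaks,
#' merged when separated by less than `merge_bp`, then filtered to lengths
#' in `[min_len, max_len]`. Survivors are flagged `stringent` with state
#' `active`.
#'
#' @param dnase,h3k4me1,h3k27ac [peak_set()] objects.
#' @param merge_bp merge gap (strictly less than) in bp.
#' @param min_len,max_len length bounds in bp.
#' @return enhancer `data.table` (chrom/start/end/state/stringent).
#' @export
stringent_active_enhancers <- function(dnase, h3k4me1, h3k27ac,
                                       merge_bp = 300L, min_len = 100L,
                                       max_len = 3000L) {
  grs <- lapply(list(dnase, h3k4me1, h3k27ac), function(ps) {
    GenomicRanges::reduce(as_granges(ps$intervals))
  })
  inter <- GenomicRanges::intersect(
    GenomicRanges::intersect(grs[[1L]], grs[[2L]]), grs[[3L]])
  merged <- GenomicRanges::reduce(inter, min.gapwidth = merge_bp)
  out <- granges_to_dt(merged)
  out <- out[end - start >= min_len & end - start <= max_len]
  out[, `:=`(state = "active", stringent = TRUE)]
  setorder(out, chrom, start)[]
}

#' Covariate-matched peak selection
#'
#' Greedy 1:1 nearest-neighbour matching without replacement between two
#' peak sets in z-scored covariate space (z-scores computed on the pooled
#' sets). Pairs whose Euclidean distance exceeds the caliper are dropped.
#'
#' @param set_a,set_b [peak_set()] objects carrying the covariates
#'   (`signal_density` column; length from the intervals).
#' @param covariates covariate names, subset of
#'   `c("length", "signal_density")`.
#' @param caliper maximum match distance in pooled-sd units (`Inf` keeps all
#'   matches).
#' @return `data.table(index_a, index_b, distance)` of matched peak row
#'   indices; injective in both columns.
#' @export
match_peaks <- function(set_a, set_b,
                        covariates = c("length", "signal_density"),
                        caliper = 0.25) {
  cov_of <- function(ps) {
    iv <- ps$intervals
    out <- data.table(length = as.numeric(iv$end - iv$start))
    if ("signal_density" %in% covariates) {
      stopifnot("signal_density" %in% names(iv))
      out[, signal_density := iv$signal_density]
    }
    out[, ..covariates]
  }
  a <- cov_of(set_a); b <- cov_of(set_b)
  if (!nrow(a) || !nrow(b)) {
    return(data.table(index_a = integer(), index_b = integer(),
                      distance = numeric()))
  }
  pooled <- rbind(a, b)
  mu <- vapply(pooled, mean, numeric(1))
  sdv <- vapply(pooled, sd, numeric(1))
  sdv[sdv == 0 | is.na(sdv)] <- 1
  za <- scale(as.matrix(a), center = mu, scale = sdv)
  zb <- scale(as.matrix(b), center = mu, scale = sdv)
  dmat <- outer(rowSums(za^2), rowSums(zb^2), `+`) - 2 * tcrossprod(za, zb)
  dmat <- sqrt(pmax(dmat, 0))
  n_pairs <- min(nrow(a), nrow(b))
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  res <- vector("list", n_pairs)
  ord <- order(dmat)
  k <- 0L
  for (idx in ord) {
    if (k == n_pairs) break
    ia <- (idx - 1L) %% nrow(a) + 1L
    ib <- (idx - 1L) %/% nrow(a) + 1L
    if (used_a[ia] || used_b[ib]) next
    if (dmat[ia, ib] > caliper) break   # ord is ascending; all further exceed
    used_a[ia] <- TRUE; used_b[ib] <- TRUE
    k <- k + 1L
    res[[k]] <- data.table(index_a = ia, index_b = ib,
                           distance = dmat[ia, ib])
  }
  if (k == 0L) {
    return(data.table(index_a = integer(), index_b = integer(),
                      distance = numeric()))
  }
  rbindlist(res[seq_len(k)])
}

#' Fraction of TF peaks overlapping enhancers
#'
#' @param tf_peaks a [peak_set()] of transcription-factor binding peaks.
#' @param enhancers enhancer table (e.g. from
#'   [stringent_active_enhancers()]).
#' @param min_bp minimum overlap.
#' @return list with `fraction` (`NA` when there are no TF peaks),
#'   `n_overlapping`, `n_peaks`, and `bound_factors`: per-enhancer logical
#'   vector of whether the factor binds it.
#' @export
tf_enhancer_overlap <- function(tf_peaks, enhancers, min_bp = 1L) {
  iv <- tf_peaks$intervals
  enh <- as.data.table(enhancers)
  if (!nrow(iv)) {
    return(list(fraction = NA_real_, n_overlapping = 0L, n_peaks = 0L,
                bound_factors = rep(FALSE, nrow(enh))))
  }
  if (!nrow(enh)) {
    return(list(fraction = 0, n_overlapping = 0L, n_peaks = nrow(iv),
                bound_factors = logical(0)))
  }
  hit_tf <- IRanges::overlapsAny(as_granges(iv), as_granges(enh),
                                 minoverlap = min_bp)
  hit_enh <- IRanges::overlapsAny(as_granges(enh), as_granges(iv),
                                  minoverlap = min_bp)
  list(fraction = mean(hit_tf), n_overlapping = sum(hit_tf),
       n_peaks = nrow(iv), bound_factors = hit_enh)
}

#' Join enhancers onto the promoter interactome
#'
#' Maps enhancers to fragments, then annotates every bait gene with the
#' enhancers found on the other ends of its significant interactions, and
#' builds the reverse map from each enhancer to the promoters it contacts
#' (with per-promoter mark flags when promoter mark peak sets are given).
#'
#' @param interactions calls table with `frag1`, `frag2` (one end a bait).
#' @param enhancers enhancer table with `state` (and optionally factor
#'   columns).
#' @param map the [fragment_map()].
#' @param promoter_marks optional list of [peak_set()]s used to flag
#'   contacted promoter fragments (e.g. H3K27me3).
#' @return list with `gene_enhancers` (`gene, enhancer_id, state`) and
#'   `enhancer_promoters` (`enhancer_id, state, bait_id, gene`, one logical
#'   column per promoter mark).
#' @export
interaction_enhancer_join <- function(interactions, enhancers, map,
                                      promoter_marks = NULL) {
  fr <- map$fragments
  enh <- as.data.table(enhancers)
  enh[, enhancer_id := .I]
  calls <- as.data.table(interactions)[, .(frag1, frag2)]
  bait <- fifelse(fr$bait[calls$frag1], calls$frag1, calls$frag2)
  oe <- fifelse(bait == calls$frag1, calls$frag2, calls$frag1)
  links <- data.table(bait_id = bait, oe = oe)
  # enhancer -> fragment assignment
  if (nrow(enh)) {
    hits <- GenomicRanges::findOverlaps(as_granges(enh), as_granges(fr))
    e2f <- data.table(enhancer_id = enh$enhancer_id[S4Vectors::queryHits(hits)],
                      oe = fr$fragment_id[S4Vectors::subjectHits(hits)])
  } else {
    e2f <- data.table(enhancer_id = integer(), oe = integer())
  }
  joined <- merge(links, e2f, by = "oe", allow.cartesian = TRUE)
  genes <- map$bait_genes %||%
    data.table(fragment_id = integer(), gene = character())
  joined <- merge(joined, genes, by.x = "bait_id", by.y = "fragment_id",
                  all.x = TRUE, allow.cartesian = TRUE)
  joined <- merge(joined, enh[, .(enhancer_id, state)], by = "enhancer_id")
  gene_enhancers <- unique(joined[, .(gene, bait_id, enhancer_id, state)])
  enhancer_promoters <- unique(joined[, .(enhancer_id, state, bait_id, gene)])
  if (!is.null(promoter_marks)) {
    for (ps in promoter_marks) {
      marked <- marked_fragments(map, ps)
      enhancer_promoters[, (paste0("promoter_", ps$mark)) :=
                           bait_id %in% marked]
    }
  }
  list(gene_enhancers = gene_enhancers[],
       enhancer_promoters = enhancer_promoters[])
}
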