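# Synthetic PCHi-C study generator. Produces every input the pipeline
# consumes - fragment map with baits, two-condition ditag tables with planted
# shared and cell-specific interactions, chromatin-mark peak sets with
# homotypic co-occurrence structure, TSS and bait annotation, clustered
# expression profiles - together with machine-readable truth tables. All
# randomness flows from the single seed in the configuration; every output
# is bit-reproducible given (config, seed).

#' Simulation configuration
#'
#' Returns the study configuration with the package defaults; any field can
#' be overridden by name. Key model choices: contact probability decays as
#' `(d + decay_offset)^-decay_exponent`; per-fragment visibility biases are
#' log-normal; the read universe is capture-style (every pair involves a
#' bait) with cis pairs below `min_cis_distance` removed (the proximity-
#' ligation noise regime handled upstream in real pipelines); planted
#' interactions are allocated evenly across baits at enhancer-promoter
#' distances (`spike_distance_range`) with their sampling weight multiplied
#' by `spike_fold`.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # genome / capture design
    n_chromosomes = 2L,
    chrom_length = 1e6,
    mean_fragment_length = 4000,
    n_baits = 100L,
    # contact model
    total_reads = 1e6,
    decay_exponent = 1,
    decay_offset = 1e4,
    visibility_sd = 0.2,
    trans_fraction = 0.05,
    min_cis_distance = 2e4,
    capture_only = TRUE,
    # planted interactions
    n_shared = 200L,
    n_test_specific = 100L,
    n_ref_specific = 100L,
    spike_fold = 8,
    spike_distance_range = c(2e4, 5e4),
    # peak model
    peak_marks = c("H3K27me3", "H3K4me3", "H3K9me3", "H3K27ac", "CTCF",
                   "DNase"),
    peak_density = 0.15,
    homotypic_marks = c("H3K27me3", "CTCF"),
    homotypic_coplacement = 0.8,
    n_enhancer_candidates = 80L,
    enhancer_class_props = c(active = 0.4, poised = 0.3, intermediate = 0.3),
    dnase_on_active = 0.9,
    tf_factors = c("TFAP2C", "ESRRB"),
    tf_on_active = 0.5,
    tf_background_peaks = 20L,
    # expression model
    expr_samples = c("ESC", "TSC", "TSC_d3", "TSC_d6"),
    expr_k = 7L,
    genes_per_cluster = 100L,
    expr_noise_sd = 0.25,
    expr_centroid_sep = 6,
    expr_base_log2 = 3,
    expr_bias = 0.8
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown simulation_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  stopifnot(cfg$decay_exponent > 0, cfg$spike_fold > 1,
            cfg$trans_fraction >= 0, cfg$trans_fraction < 1,
            cfg$mean_fragment_length >= 100,
            all(unlist(cfg[c("n_shared", "n_test_specific",
                             "n_ref_specific")]) >= 0))
  structure(cfg, class = "simulation_config")
}

#' Simulate a restriction fragment map with bait annotation
#'
#' Fragment lengths are geometric with the configured mean, tiled per
#' chromosome; `n_baits` fragments are drawn uniformly as promoter baits and
#' given synthetic gene names (`gene0001`, ...).
#'
#' @param config a [simulation_config()].
#' @return a [fragment_map()].
#' @export
simulate_fragment_map <- function(config) {
  set.seed(child_seed(config$seed, "map"))
  frs <- lapply(seq_len(config$n_chromosomes), function(cc) {
    ends <- integer(0)
    pos <- 0
    while (pos < config$chrom_length) {
      pos <- min(pos + rgeom(1L, 1 / config$mean_fragment_length) + 1L,
                 config$chrom_length)
      ends <- c(ends, pos)
    }
    data.table(chrom = paste0("chr", cc),
               start = c(0L, head(ends, -1L)), end = as.integer(ends))
  })
  fr <- rbindlist(frs)
  if (config$n_baits > nrow(fr)) stop("n_baits exceeds number of fragments")
  baits <- sort(sample(nrow(fr), config$n_baits))
  genes <- data.table(fragment_id = baits,
                      gene = sprintf("gene%04d", seq_along(baits)))
  fragment_map(fr, bait_ids = baits, bait_genes = genes)
}

# the capture pair universe: all pairs involving a bait (or all pairs when
# capture_only = FALSE), with proximal cis pairs removed
pair_universe <- function(map, config) {
  fr <- map$fragments
  nf <- nrow(fr)
  if (config$capture_only) {
    b <- bait_ids(map)
    i <- rep(b, each = nf)
    j <- rep(fr$fragment_id, times = length(b))
    keep <- i != j
    u <- data.table(frag1 = pmin(i, j)[keep], frag2 = pmax(i, j)[keep])
    u <- unique(u)
  } else {
    if (nf > 3000L) stop("all-pairs universe too large; use capture_only")
    idx <- which(upper.tri(matrix(0, nf, nf)), arr.ind = TRUE)
    u <- data.table(frag1 = idx[, 1L], frag2 = idx[, 2L])
  }
  mid <- (fr$start + fr$end) / 2
  u[, cis := fr$chrom[frag1] == fr$chrom[frag2]]
  u[, distance := fifelse(cis, abs(mid[frag1] - mid[frag2]), Inf)]
  u <- u[!cis | distance >= config$min_cis_distance]
  setorder(u, frag1, frag2)
  u[]
}

#' Plant ground-truth interactions
#'
#' Allocates the configured numbers of shared, test-specific and
#' ref-specific interactions by cycling over baits (every promoter receives
#' planted contacts), drawing each partner uniformly among the bait's cis
#' pairs inside `spike_distance_range` (widened outward for baits with too
#' few candidates). The three classes are disjoint. Deterministic given the
#' config.
#'
#' @param map a [fragment_map()].
#' @param config a [simulation_config()].
#' @return `data.table(frag1, frag2, class)` with class in
#'   shared/test_specific/ref_specific.
#' @export
plant_interactions <- function(map, config) {
  set.seed(child_seed(config$seed, "spikes"))
  u <- pair_universe(map, config)
  baits <- bait_ids(map)
  lo <- config$spike_distance_range[1L]
  hi <- config$spike_distance_range[2L]
  taken <- rep(FALSE, nrow(u))
  classes <- c(shared = config$n_shared,
               test_specific = config$n_test_specific,
               ref_specific = config$n_ref_specific)
  picks <- vector("list", sum(classes))
  np <- 0L
  for (cls in names(classes)) {
    remaining <- classes[[cls]]
    while (remaining > 0L) {
      planted_this_cycle <- 0L
      for (b in baits) {
        if (remaining == 0L) break
        cand <- which((u$frag1 == b | u$frag2 == b) & u$cis & !taken &
                        u$distance >= lo & u$distance <= hi)
        if (!length(cand)) {   # widen outward to the nearest distances
          cand <- which((u$frag1 == b | u$frag2 == b) & u$cis & !taken)
          if (!length(cand)) next
          cand <- cand[order(pmin(abs(u$distance[cand] - lo),
                                  abs(u$distance[cand] - hi)))]
          cand <- cand[seq_len(min(5L, length(cand)))]
        }
        pick <- cand[sample.int(length(cand), 1L)]
        taken[pick] <- TRUE
        np <- np + 1L
        picks[[np]] <- data.table(frag1 = u$frag1[pick],
                                  frag2 = u$frag2[pick], class = cls)
        remaining <- remaining - 1L
        planted_this_cycle <- planted_this_cycle + 1L
      }
      if (planted_this_cycle == 0L) {
        stop("unable to plant the requested number of interactions")
      }
    }
  }
  if (np == 0L) {
    return(data.table(frag1 = integer(), frag2 = integer(),
                      class = character()))
  }
  rbindlist(picks[seq_len(np)])
}

# shared per-fragment visibility biases (a property of the fragments, common
# to both conditions)
fragment_visibility <- function(map, config) {
  set.seed(child_seed(config$seed, "visibility"))
  exp(rnorm(nrow(map$fragments), 0, config$visibility_sd))
}

#' Simulate a ditag count table for one condition
#'
#' `total_reads` read pairs are drawn multinomially over the capture pair
#' universe with weight `vis_i * vis_j * (d + d0)^-alpha` for cis pairs and
#' a flat visibility-weighted allocation summing to `trans_fraction` for
#' trans pairs. Planted pairs active in the condition (shared plus the
#' condition's own class) have their weight multiplied by `spike_fold`.
#'
#' @param map a [fragment_map()].
#' @param config a [simulation_config()].
#' @param condition `"test"` or `"ref"`.
#' @param truth planted interactions from [plant_interactions()];
#'   recomputed from the config when `NULL`.
#' @return a [ditag_counts()]; the truth table is attached as
#'   `attr(, "truth")`.
#' @export
simulate_ditags <- function(map, config, condition = c("test", "ref"),
                            truth = NULL) {
  condition <- match.arg(condition)
  if (is.null(truth)) truth <- plant_interactions(map, config)
  vis <- fragment_visibility(map, config)
  u <- pair_universe(map, config)
  w <- vis[u$frag1] * vis[u$frag2]
  cis <- u$cis
  w[cis] <- w[cis] * (u$distance[cis] + config$decay_offset)^
    (-config$decay_exponent)
  if (any(!cis)) {
    if (config$trans_fraction > 0) {
      w[!cis] <- w[!cis] * (config$trans_fraction / (1 - config$trans_fraction) *
                              sum(w[cis]) / sum(w[!cis]))
    } else {
      w[!cis] <- 0
    }
  }
  active <- switch(condition,
                   test = c("shared", "test_specific"),
                   ref = c("shared", "ref_specific"))
  spikes <- truth[class %in% active]
  if (nrow(spikes)) {
    key <- paste(u$frag1, u$frag2)
    hit <- match(paste(spikes$frag1, spikes$frag2), key)
    if (anyNA(hit)) stop("planted pair outside the pair universe")
    w[hit] <- w[hit] * config$spike_fold
  }
  set.seed(child_seed(config$seed, condition))
  cnt <- as.vector(rmultinom(1L, as.integer(config$total_reads), w))
  keep <- cnt > 0L
  out <- ditag_counts(data.table(frag1 = u$frag1[keep], frag2 = u$frag2[keep],
                                 count = cnt[keep]),
                      condition = condition)
  setattr(out, "truth", truth)
  out
}

#' Simulate chromatin-mark peak sets and TSS annotation
#'
#' Marks are placed on fragments at the configured density (one peak inside
#' the fragment). For the configured homotypic marks, both end fragments of
#' every planted interaction additionally receive a peak with probability
#' `homotypic_coplacement`. Enhancer-candidate H3K4me1 peaks are placed on
#' reserved non-bait fragments (at least 1 kb from any TSS) and dressed with
#' H3K27ac / H3K27me3 / DNase so that the expected class proportions match
#' `enhancer_class_props`; TF peaks are placed on active enhancers with
#' probability `tf_on_active` plus random background peaks. TSSs are 1-bp
#' intervals at bait fragment starts.
#'
#' @param map a [fragment_map()].
#' @param config a [simulation_config()].
#' @param truth planted interactions (recomputed when `NULL`).
#' @return list with `peaks` (named list of [peak_set()]), `tss` (interval
#'   table), and `truth_marks` (`data.table(fragment_id, mark)` occupancy),
#'   `truth_enhancers` (`data.table` of candidate enhancers with true class),
#'   `truth_factor_genes` (factor -> genes whose planted partner carries a
#'   bound active enhancer).
#' @export
simulate_peaks <- function(map, config, truth = NULL) {
  if (is.null(truth)) truth <- plant_interactions(map, config)
  set.seed(child_seed(config$seed, "peaks"))
  fr <- map$fragments
  nf <- nrow(fr)
  baits <- bait_ids(map)
  tss <- data.table(chrom = fr$chrom[baits], start = fr$start[baits],
                    end = fr$start[baits] + 1L,
                    name = sprintf("tss_%04d", seq_along(baits)))

  # place one peak inside each fragment; region "left"/"right" confines the
  # peak to one half so that independently placed peaks (e.g. a coplaced
  # repressive mark and an enhancer candidate) never overlap each other
  peak_in_fragment <- function(fid, region = "any") {
    s <- fr$start[fid]; e <- fr$end[fid]
    half <- (e - s) %/% 2L
    if (region == "left") e <- s + half - 50L
    if (region == "right") s <- s + half + 50L
    len <- pmax(pmin(as.integer(runif(length(fid), 200, 1500)), e - s), 1L)
    off <- floor(runif(length(fid)) * (e - s - len + 1L))
    data.table(chrom = fr$chrom[fid], start = as.integer(s + off),
               end = as.integer(s + off + len))
  }
  # enhancer-candidate fragments: non-bait and long enough; planted partner
  # fragments are preferred so that enhancer-gene links exist in the truth
  planted_frags <- unique(c(truth$frag1, truth$frag2))
  tss_clear <- function(ivs) {
    clear <- rep(TRUE, nrow(ivs))
    for (cc in unique(ivs$chrom)) {
      p <- sort(tss[chrom == cc, start])
      if (!length(p)) next
      sel <- which(ivs$chrom == cc)
      near <- vapply(sel, function(k) {
        min(abs(p - ivs$start[k]), abs(p - (ivs$end[k] - 1L)))
      }, numeric(1L))
      clear[sel] <- near >= 1200
    }
    clear
  }
  long_enough <- which(!fr$bait & (fr$end - fr$start) >= 3000L)
  pref <- intersect(long_enough, planted_frags)
  rest <- setdiff(long_enough, planted_frags)
  n_cand <- config$n_enhancer_candidates
  n_pref <- min(length(pref), ceiling(n_cand / 2))
  cand_fr <- c(sample(pref, n_pref),
               sample(rest, min(n_cand - n_pref, length(rest))))
  enh_iv <- peak_in_fragment(cand_fr, region = "right")
  ok <- tss_clear(enh_iv)
  enh_iv <- enh_iv[ok]
  cand_fr <- cand_fr[ok]
  props <- config$enhancer_class_props / sum(config$enhancer_class_props)
  cls <- sample(names(props), nrow(enh_iv), replace = TRUE, prob = props)

  # background placement for each mark on fragments outside the enhancer
  # candidates (so class proportions stay as configured)
  bg_pool <- setdiff(which((fr$end - fr$start) >= 400L), cand_fr)
  peaks <- list()
  occupancy <- list()
  for (mk in config$peak_marks) {
    sel <- bg_pool[runif(length(bg_pool)) < config$peak_density]
    ivs <- if (length(sel)) peak_in_fragment(sel) else
      data.table(chrom = character(), start = integer(), end = integer())
    if (mk %in% config$homotypic_marks && nrow(truth)) {
      ends <- unique(c(truth$frag1, truth$frag2))
      co <- ends[runif(length(ends)) < config$homotypic_coplacement]
      co <- setdiff(co, sel)
      if (length(co)) {
        in_cand <- co %in% cand_fr
        if (any(!in_cand)) ivs <- rbind(ivs, peak_in_fragment(co[!in_cand]))
        if (any(in_cand)) {
          ivs <- rbind(ivs, peak_in_fragment(co[in_cand], region = "left"))
        }
      }
      sel <- c(sel, co)
    }
    peaks[[mk]] <- ivs
    occupancy[[mk]] <- sel
  }
  # dress enhancer candidates
  k4 <- enh_iv
  sub_iv <- function(iv) {   # interval nested inside the candidate peak
    w <- pmax(as.integer((iv$end - iv$start) * 0.8), 1L)
    data.table(chrom = iv$chrom, start = iv$start,
               end = pmin(iv$start + w + 50L, iv$end))
  }
  add <- function(mark, iv) peaks[[mark]] <<- rbind(peaks[[mark]], iv)
  act <- cls == "active"; poi <- cls == "poised"
  if (any(act)) add("H3K27ac", sub_iv(enh_iv[act]))
  if (any(poi)) add("H3K27me3", sub_iv(enh_iv[poi]))
  dn <- act & runif(length(cls)) < config$dnase_on_active
  if (any(dn)) add("DNase", sub_iv(enh_iv[dn]))
  peaks[["H3K4me1"]] <- if ("H3K4me1" %in% names(peaks)) {
    rbind(peaks[["H3K4me1"]], k4)
  } else k4

  # TF peaks on active enhancers + random background
  tf_sets <- list()
  factor_enh <- list()
  for (tf in config$tf_factors) {
    on <- which(act & runif(length(cls)) < config$tf_on_active)
    ivs <- if (length(on)) sub_iv(enh_iv[on]) else
      data.table(chrom = character(), start = integer(), end = integer())
    bg <- sample(bg_pool, min(config$tf_background_peaks, length(bg_pool)))
    if (length(bg)) ivs <- rbind(ivs, peak_in_fragment(bg))
    tf_sets[[tf]] <- ivs
    factor_enh[[tf]] <- on
  }
  # factor -> genes: bait genes whose planted partner fragment carries a
  # bound active enhancer
  genes <- map$bait_genes
  factor_genes <- lapply(factor_enh, function(on) {
    if (!length(on)) return(character(0))
    fids <- cand_fr[on]
    hit <- truth[frag1 %in% fids | frag2 %in% fids]
    bids <- fifelse(hit$frag1 %in% fids, hit$frag2, hit$frag1)
    sort(unique(genes$gene[match(bids, genes$fragment_id)]))
  })

  peak_sets <- c(
    lapply(setNames(nm = names(peaks)), function(mk) {
      peak_set(copy(peaks[[mk]]), mark = mk)
    }),
    lapply(setNames(nm = names(tf_sets)), function(tf) {
      peak_set(copy(tf_sets[[tf]]), mark = tf)
    })
  )
  occ <- rbindlist(lapply(names(occupancy), function(mk) {
    if (!length(occupancy[[mk]])) return(NULL)
    data.table(fragment_id = occupancy[[mk]], mark = mk)
  }))
  truth_enh <- copy(enh_iv)[, `:=`(fragment_id = cand_fr, class = cls)]
  list(peaks = peak_sets, tss = tss, truth_marks = occ,
       truth_enhancers = truth_enh, truth_factor_genes = factor_genes)
}

#' Simulate a clustered expression matrix
#'
#' Genes belong to `expr_k` clusters of `genes_per_cluster`; each cluster
#' has a centroid log2-expression profile over the samples (centroids are
#' redrawn until all pairwise distances reach `expr_centroid_sep` noise
#' standard deviations) and `FPKM = 2^(base + centroid + noise)`. Genes
#' annotated to enhancer-bound factors (from [simulate_peaks()] truth) are
#' reassigned to a factor-specific cluster with probability `expr_bias`.
#'
#' @param config a [simulation_config()].
#' @param factor_genes optional named list factor -> gene names.
#' @return FPKM matrix with attributes `truth_clusters` (named integer) and
#'   `factor_clusters` (factor -> biased cluster index).
#' @export
simulate_expression <- function(config, factor_genes = NULL) {
  set.seed(child_seed(config$seed, "expression"))
  k <- config$expr_k
  ns <- length(config$expr_samples)
  min_sep <- config$expr_centroid_sep * config$expr_noise_sd
  # centroids are drawn as z-form profiles (mean 0, sd 1 across samples) and
  # required to be separated in that space - the space the expression
  # profiles are clustered in, where additive shifts are invisible
  tries <- 0L
  repeat {
    centroids <- matrix(rnorm(k * ns, 0, 1.5), k, ns)
    centroids <- t(apply(centroids, 1L, function(x) (x - mean(x)) / sd(x)))
    if (k == 1L || min(dist(centroids)) >= min_sep) break
    tries <- tries + 1L
    if (tries > 5000L) stop("cannot satisfy the centroid separation")
  }
  n_genes <- k * config$genes_per_cluster
  genes <- sprintf("gene%04d", seq_len(n_genes))
  assign <- rep(seq_len(k), each = config$genes_per_cluster)
  names(assign) <- genes
  factor_clusters <- integer(0)
  if (!is.null(factor_genes) && length(factor_genes)) {
    factor_clusters <- setNames(
      (seq_along(factor_genes) - 1L) %% k + 1L, names(factor_genes))
    for (f in names(factor_genes)) {
      g <- intersect(factor_genes[[f]], genes)
      flip <- g[runif(length(g)) < config$expr_bias]
      assign[flip] <- factor_clusters[[f]]
    }
  }
  noise <- matrix(rnorm(n_genes * ns, 0, config$expr_noise_sd), n_genes, ns)
  lg <- config$expr_base_log2 + centroids[assign, , drop = FALSE] + noise
  fpkm <- 2^lg
  dimnames(fpkm) <- list(genes, config$expr_samples)
  attr(fpkm, "truth_clusters") <- assign
  attr(fpkm, "factor_clusters") <- factor_clusters
  fpkm
}

#' Simulate the full study bundle
#'
#' Runs every generator with a shared configuration and optionally writes
#' the inputs in their on-disk formats (fragment map and ditag TSVs, peak
#' and TSS BEDs, FPKM TSV) plus a JSON truth file.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (`NULL` keeps everything in memory).
#' @return list with `map`, `truth`, `test`, `ref` (ditag tables), `peaks`,
#'   `tss`, `fpkm`, and the peak truth tables.
#' @export
simulate_bundle <- function(config = simulation_config(), outdir = NULL) {
  map <- simulate_fragment_map(config)
  truth <- plant_interactions(map, config)
  test <- simulate_ditags(map, config, "test", truth = truth)
  ref <- simulate_ditags(map, config, "ref", truth = truth)
  pk <- simulate_peaks(map, config, truth = truth)
  fpkm <- simulate_expression(config, factor_genes = pk$truth_factor_genes)
  bundle <- list(map = map, truth = truth, test = test, ref = ref,
                 peaks = pk$peaks, tss = pk$tss,
                 truth_marks = pk$truth_marks,
                 truth_enhancers = pk$truth_enhancers,
                 truth_factor_genes = pk$truth_factor_genes,
                 fpkm = fpkm, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fragment_map(map, file.path(outdir, "fragments.tsv"))
    write_ditags(test, file.path(outdir, "ditags_test.tsv"))
    write_ditags(ref, file.path(outdir, "ditags_ref.tsv"))
    write_bed(pk$tss, file.path(outdir, "tss.bed"))
    for (mk in names(pk$peaks)) {
      write_bed(pk$peaks[[mk]]$intervals,
                file.path(outdir, sprintf("peaks_%s.bed", mk)))
    }
    fwrite(data.table(gene = rownames(fpkm), as.data.table(unclass(fpkm))),
           file.path(outdir, "fpkm.tsv"), sep = "\t")
    jsonlite::write_json(
      list(interactions = truth,
           clusters = as.list(attr(fpkm, "truth_clusters")),
           factor_genes = pk$truth_factor_genes),
      file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  bundle
}
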