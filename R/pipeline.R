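# End-to-end orchestration: configuration handling, the pipeline runner
# chaining calling -> differential -> annotation -> expression, and
# figure-style summary tables.

#' Pipeline configuration
#'
#' Defaults follow the study parameters: FDR 5%, enhancer rules with 1 kb
#' TSS exclusion, 300 bp merging and 100 bp - 3 kb size bounds.
#'
#' @param ... named overrides.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    alpha = 0.05,
    grid_points = 256L,
    smoothing_window = 5L,
    min_interactions = 10L,
    fallback_q = 0.05,
    tss_exclusion_bp = 1000L,
    merge_bp = 300L,
    min_enhancer_len = 100L,
    max_enhancer_len = 3000L,
    ihw_bins = 8L,
    ihw_folds = 5L,
    exclude_chroms = NULL,
    match_depth = TRUE,
    log2_fpkm_threshold = -1,
    expr_k = 7L,
    kmeans_restarts = 25L,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown pipeline_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$ihw_bins >= 1L,
            cfg$merge_bp >= 0L, cfg$min_enhancer_len >= 0L)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' `load_pipeline_config(save_pipeline_config(cfg, path))` round-trips the
#' configuration exactly.
#'
#' @param path YAML file path.
#' @export
load_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname load_pipeline_config
#' @param config a [pipeline_config()].
#' @export
save_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full comparison pipeline
#'
#' Chains the stages on an input bundle (as produced by [simulate_bundle()]
#' or assembled from files): significant-interaction calling per condition,
#' differential calling between the conditions, homotypic and enhancer
#' annotation, and expression analysis. Each stage failure aborts with the
#' stage name. Outputs are deterministic given identical inputs and config.
#'
#' @param bundle list with `map`, `test`, `ref`, `peaks`, `tss`, `fpkm`.
#' @param config a [pipeline_config()].
#' @param outdir optional directory for the result tables and run manifest.
#' @return list of class `pipeline_result` with `calls_test`, `calls_ref`,
#'   `differential`, `homotypic`, `specific_fractions`, `enhancers`,
#'   `stringent_enhancers`, `tf_overlap`, `gene_joins`, `clusters`,
#'   `enrichment`, `manifest`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(), outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  need <- setdiff(c("map", "test", "ref"), names(bundle))
  if (length(need)) stop("bundle is missing: ", paste(need, collapse = ", "))
  map <- bundle$map

  calls_test <- stage("interaction_calling", call_significant(
    bundle$test, map, exclude_chroms = config$exclude_chroms,
    grid_points = config$grid_points,
    smoothing_window = config$smoothing_window,
    min_interactions = config$min_interactions,
    fallback_q = config$fallback_q))
  calls_ref <- stage("interaction_calling", call_significant(
    bundle$ref, map, exclude_chroms = config$exclude_chroms,
    grid_points = config$grid_points,
    smoothing_window = config$smoothing_window,
    min_interactions = config$min_interactions,
    fallback_q = config$fallback_q))

  differential <- stage("differential_calling", call_differential(
    bundle$test, bundle$ref, map, alpha = config$alpha,
    n_bins = config$ihw_bins, n_folds = config$ihw_folds,
    seed = config$seed, match_depth = config$match_depth))

  homotypic <- specific_fractions <- enhancers <- stringent <- NULL
  tf_overlap <- gene_joins <- NULL
  if (!is.null(bundle$peaks)) {
    if (!all(c("H3K4me1", "H3K27ac", "H3K27me3") %in% names(bundle$peaks))) {
      stop("pipeline stage 'chromatin_annotation' failed: missing peak sets")
    }
    sig_union <- stage("chromatin_annotation", unique(rbind(
      calls_test$calls[passes == TRUE, .(frag1, frag2)],
      calls_ref$calls[passes == TRUE, .(frag1, frag2)])))
    homotypic <- stage("chromatin_annotation",
                       classify_homotypic(sig_union, bundle$peaks, map))
    spec_pairs <- differential$table[significant == TRUE, .(frag1, frag2)]
    specific_fractions <- stage("chromatin_annotation",
                                cell_specific_fraction(homotypic, spec_pairs))
    enhancers <- stage("chromatin_annotation", classify_enhancers(
      bundle$peaks[["H3K4me1"]], bundle$peaks[["H3K27ac"]],
      bundle$peaks[["H3K27me3"]], bundle$tss,
      tss_exclusion_bp = config$tss_exclusion_bp))
    if ("DNase" %in% names(bundle$peaks)) {
      stringent <- stage("chromatin_annotation", stringent_active_enhancers(
        bundle$peaks[["DNase"]], bundle$peaks[["H3K4me1"]],
        bundle$peaks[["H3K27ac"]], merge_bp = config$merge_bp,
        min_len = config$min_enhancer_len, max_len = config$max_enhancer_len))
      known_marks <- c("H3K27me3", "H3K4me3", "H3K9me3", "H3K4me1",
                       "H3K27ac", "CTCF", "DNase")
      tf_overlap <- stage("chromatin_annotation", rbindlist(lapply(
        setdiff(names(bundle$peaks), known_marks), function(tf) {
          ov <- tf_enhancer_overlap(bundle$peaks[[tf]], stringent)
          data.table(factor = tf, fraction = ov$fraction,
                     n_overlapping = ov$n_overlapping, n_peaks = ov$n_peaks)
        })))
    }
    gene_joins <- stage("chromatin_annotation", interaction_enhancer_join(
      calls_test$calls[passes == TRUE], enhancers, map,
      promoter_marks = bundle$peaks["H3K27me3"]))
  }

  clusters <- enrichment <- NULL
  if (!is.null(bundle$fpkm)) {
    mask <- stage("expression_analysis", filter_expressed(
      bundle$fpkm, config$log2_fpkm_threshold))
    clusters <- stage("expression_analysis", kmeans_profiles(
      bundle$fpkm, k = config$expr_k, seed = config$seed,
      n_restarts = config$kmeans_restarts, expressed_mask = mask))
    if (!is.null(gene_joins) && nrow(gene_joins$gene_enhancers)) {
      by_state <- split(gene_joins$gene_enhancers$gene,
                        gene_joins$gene_enhancers$state)
      by_state <- lapply(by_state, function(g) {
        intersect(unique(g), names(clusters$assignment))
      })
      by_state <- by_state[lengths(by_state) > 0L]
      if (length(by_state)) {
        enrichment <- stage("expression_analysis",
                            cluster_enrichment(clusters, by_state))
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("promhic")),
    seed = config$seed,
    parameters = unclass(config),
    n_pairs_test = nrow(calls_test$calls),
    n_pairs_ref = nrow(calls_ref$calls),
    n_significant_test = sum(calls_test$calls$passes),
    n_significant_ref = sum(calls_ref$calls$passes),
    n_differential = sum(differential$table$significant)
  )
  result <- structure(list(
    calls_test = calls_test, calls_ref = calls_ref,
    differential = differential, homotypic = homotypic,
    specific_fractions = specific_fractions, enhancers = enhancers,
    stringent_enhancers = stringent, tf_overlap = tf_overlap,
    gene_joins = gene_joins, clusters = clusters, enrichment = enrichment,
    manifest = manifest), class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_result(result, bundle$map, outdir)
  result
}

write_pipeline_result <- function(result, map, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_ibed(result$calls_test, map, file.path(outdir, "calls_test.ibed"))
  write_ibed(result$calls_ref, map, file.path(outdir, "calls_ref.ibed"))
  write_differential(result$differential,
                     file.path(outdir, "differential.tsv"),
                     significant_only = TRUE)
  if (!is.null(result$specific_fractions)) {
    fwrite(result$specific_fractions,
           file.path(outdir, "specific_fractions.tsv"), sep = "\t")
  }
  if (!is.null(result$enhancers)) {
    enh <- copy(result$enhancers)[, name := state]
    write_bed(enh, file.path(outdir, "enhancers.bed"))
  }
  if (!is.null(result$stringent_enhancers)) {
    enh <- copy(result$stringent_enhancers)[, name := state]
    write_bed(enh, file.path(outdir, "stringent_enhancers.bed"))
  }
  if (!is.null(result$clusters)) {
    fwrite(data.table(gene = names(result$clusters$assignment),
                      cluster = result$clusters$assignment),
           file.path(outdir, "clusters.tsv"), sep = "\t")
  }
  if (!is.null(result$enrichment)) {
    fwrite(data.table(state = rownames(result$enrichment),
                      as.data.table(result$enrichment)),
           file.path(outdir, "enrichment.tsv"), sep = "\t")
  }
  manifest <- c(result$manifest, list(written = format(Sys.time())))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Figure-style summary tables
#'
#' Condenses a pipeline result into plotting-ready tables: per-mark
#' cell-specific interaction percentages, box-plot summaries (median,
#' quartiles, 1.5 x IQR whiskers) of differential log2 ratios, and the
#' factor-by-cluster enrichment matrix.
#'
#' @param result a `pipeline_result`.
#' @return list of `data.table`s: `specific_fractions`, `ratio_summary`,
#'   `enrichment`.
#' @export
summarize_results <- function(result) {
  ratio_summary <- if (nrow(result$differential$table)) {
    sig <- result$differential$table[significant == TRUE]
    groups <- split(sig$log2_ratio, sig$direction)
    rbindlist(lapply(names(groups), function(g) {
      c(list(group = g), boxplot_stats(groups[[g]]))
    }))
  } else data.table()
  enr <- if (!is.null(result$enrichment)) {
    data.table(group = rownames(result$enrichment),
               as.data.table(result$enrichment))
  } else data.table()
  list(specific_fractions = result$specific_fractions %||% data.table(),
       ratio_summary = ratio_summary,
       enrichment = enr)
}
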