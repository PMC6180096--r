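# Ditag count tables: one row per fragment pair (canonical order i < j) with
# the number of read pairs supporting the contact.

#' Construct a ditag count table
#'
#' @param pairs `data.table`/`data.frame` with columns `frag1`, `frag2`,
#'   `count`; pairs are canonicalised to `frag1 < frag2` and duplicate rows
#'   are summed. Zero-count rows are dropped.
#' @param condition label for the condition/cell type.
#' @return object of class `ditag_counts` with elements `pairs`,
#'   `total_reads` and `condition`.
#' @export
ditag_counts <- function(pairs, condition = "unnamed") {
  dt <- as.data.table(pairs)[, .(frag1, frag2, count)]
  stopifnot(all(dt$count >= 0), all(dt$frag1 != dt$frag2))
  lo <- pmin(dt$frag1, dt$frag2)
  hi <- pmax(dt$frag1, dt$frag2)
  dt[, `:=`(frag1 = as.integer(lo), frag2 = as.integer(hi))]
  dt <- dt[count > 0, .(count = sum(count)), by = .(frag1, frag2)]
  setorder(dt, frag1, frag2)
  structure(list(pairs = dt[], total_reads = sum(dt$count),
                 condition = condition),
            class = "ditag_counts")
}

#' @export
print.ditag_counts <- function(x, ...) {
  cat(sprintf("ditag_counts '%s': %d pairs, %s reads\n", x$condition,
              nrow(x$pairs), format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' Read / write ditag tables
#'
#' Tab-delimited `frag1 frag2 count`.
#'
#' @param path file path.
#' @param condition condition label for the loaded table.
#' @export
read_ditags <- function(path, condition = basename(path)) {
  ditag_counts(fread(path, col.names = c("frag1", "frag2", "count")),
               condition = condition)
}

#' @rdname read_ditags
#' @param counts a [ditag_counts()] object.
#' @export
write_ditags <- function(counts, path) {
  fwrite(counts$pairs, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Randomly subsample a ditag table to a target depth
#'
#' Draws `target_total` reads uniformly without replacement from the multiset
#' of reads (a multivariate hypergeometric draw over pairs), matching the
#' read-depth equalisation applied before comparing two libraries.
#'
#' @param counts a [ditag_counts()].
#' @param target_total desired total read count (`<= counts$total_reads`).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a new [ditag_counts()] whose total is exactly `target_total`.
#' @export
subsample_to_depth <- function(counts, target_total, seed = 1L) {
  N <- counts$total_reads
  if (target_total > N) stop("target_total exceeds total reads")
  if (target_total == N) return(counts)
  set.seed(seed)
  n <- counts$pairs$count
  rest <- N - cumsum(n)
  x <- integer(length(n))
  rem <- as.integer(target_total)
  for (k in seq_along(n)) {
    if (rem == 0L) break
    x[k] <- rhyper(1L, n[k], rest[k], rem)
    rem <- rem - x[k]
  }
  out <- copy(counts$pairs)[, count := x][count > 0L]
  ditag_counts(out, condition = counts$condition)
}

#' Relative fragment coverage
#'
#' `c_i` = (reads touching fragment i) / (2 N); the marginal contact
#' probability of each fragment end. Sums to one over all fragments.
#'
#' @param counts a [ditag_counts()].
#' @return named numeric vector (names are fragment ids); fragments absent
#'   from the table have implicit coverage zero.
#' @export
relative_coverage <- function(counts) {
  stopifnot(counts$total_reads >= 1)
  p <- counts$pairs
  marg <- rowsum(c(p$count, p$count), c(p$frag1, p$frag2))
  setNames(as.vector(marg) / (2 * counts$total_reads), rownames(marg))
}

# sum a list of replicate tables element-wise
pool_replicates <- function(replicates, condition = NULL) {
  if (inherits(replicates, "ditag_counts")) return(replicates)
  stopifnot(length(replicates) >= 1L)
  all_pairs <- rbindlist(lapply(replicates, `[[`, "pairs"))
  ditag_counts(all_pairs,
               condition = condition %||% replicates[[1L]]$condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
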