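# Genomic intervals are plain data.tables with columns chrom, start, end and
# optionally name, score, strand. Coordinates are 0-based half-open [start, end)
# everywhere inside the package; BED input/output is therefore native.

#' Construct a genomic interval table
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param name optional labels.
#' @param score optional numeric scores.
#' @param strand optional strand (`"+"`, `"-"` or `"."`).
#' @return a `data.table` with one row per interval, sorted by chrom and start.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL,
                              strand = NULL) {
  if (any(!nzchar(chrom))) stop("chrom names must be non-empty")
  if (any(start < 0) || any(start >= end)) {
    stop("intervals require 0 <= start < end")
  }
  dt <- data.table(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end))
  if (!is.null(name))   dt[, name := as.character(..name)]
  if (!is.null(score))  dt[, score := as.numeric(..score)]
  if (!is.null(strand)) dt[, strand := as.character(..strand)]
  setorder(dt, chrom, start, end)[]
}

# convert an interval table to GRanges (1-based closed) for IRanges machinery
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

granges_to_dt <- function(gr) {
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end   = GenomicRanges::end(gr))
}

#' Test whether two intervals overlap by at least `min_bp`
#'
#' Half-open arithmetic: `[0,10)` and `[10,20)` do not overlap. Vectorised
#' over rows; the shorter argument is recycled.
#'
#' @param a,b interval tables (rows are recycled to a common length).
#' @param min_bp minimum overlap in base pairs (>= 1).
#' @return logical vector.
#' @export
interval_overlaps <- function(a, b, min_bp = 1L) {
  stopifnot(min_bp >= 1L)
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  a$chrom[ai] == b$chrom[bi] & ov >= min_bp
}

#' Read a BED file
#'
#' Accepts BED3 to BED6 (tab-delimited, 0-based half-open). `track`,
#' `browser` and `#` header lines are skipped and their count is reported via
#' a message and the `"skipped_lines"` attribute. A malformed line (fewer
#' than three fields, non-numeric or inverted coordinates) is an error that
#' names the offending line number.
#'
#' @param path file path.
#' @return interval `data.table`, sorted per chromosome.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  is_header <- grepl("^(track|browser|#)", lines)
  blank <- !nzchar(trimws(lines))
  skipped <- sum(is_header)
  body_idx <- which(!is_header & !blank)
  if (skipped > 0L) message(sprintf("read_bed: skipped %d header line(s)", skipped))
  if (!length(body_idx)) {
    out <- data.table(chrom = character(), start = integer(), end = integer())
    setattr(out, "skipped_lines", skipped)
    return(out)
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad)) {
    stop(sprintf("read_bed: line %d of %s has %d field(s); BED needs >= 3",
                 body_idx[bad[1L]], path, nf[bad[1L]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad)) {
    stop(sprintf("read_bed: line %d of %s has invalid coordinates",
                 body_idx[bad[1L]], path))
  }
  dt <- data.table(chrom = chrom, start = start, end = end)
  if (all(nf >= 4L)) dt[, name := vapply(fields, `[[`, "", 4L)]
  if (all(nf >= 5L)) dt[, score := suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))]
  if (all(nf >= 6L)) dt[, strand := vapply(fields, `[[`, "", 6L)]
  setorder(dt, chrom, start, end)
  setattr(dt, "skipped_lines", skipped)
  dt[]
}

#' Write intervals as BED
#'
#' @param x interval table with at least chrom/start/end.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED columns are positional: stop at the first absent optional column
  keep <- cols[seq_len(match(FALSE, c("chrom", "start", "end", "name",
                                      "score", "strand") %in% cols,
                             nomatch = 7L) - 1L)]
  fwrite(as.data.table(x)[, keep, with = FALSE], path,
         sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
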