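# The restriction-fragment map is the coordinate backbone: an ordered,
# gap-free tiling of each chromosome by fragments, with a subset flagged as
# promoter baits (the captured fragments of a PCHi-C design).

#' Construct a fragment map
#'
#' @param fragments interval table with columns chrom/start/end; fragments on
#'   each chromosome must tile it contiguously (each start equals the previous
#'   end) without overlap.
#' @param bait_ids integer fragment ids flagged as promoter baits.
#' @param bait_genes optional `data.table(fragment_id, gene)` mapping baits to
#'   gene symbols.
#' @return object of class `fragment_map` with elements `fragments`
#'   (chrom/start/end/fragment_id/bait) and `bait_genes`.
#' @export
fragment_map <- function(fragments, bait_ids = integer(0), bait_genes = NULL) {
  fr <- as.data.table(fragments)[, .(chrom, start, end)]
  setorder(fr, chrom, start)
  fr[, `:=`(start = as.integer(start), end = as.integer(end))]
  bad <- fr[, any(start >= end) ||
                any(start[-1L] != end[-.N]) && .N > 1L, by = chrom]
  if (any(bad$V1)) {
    stop("fragments must tile each chromosome contiguously without overlap")
  }
  fr[, fragment_id := seq_len(.N)]
  fr[, bait := fragment_id %in% bait_ids]
  if (length(bait_ids) && !all(bait_ids %in% fr$fragment_id)) {
    stop("bait_ids outside fragment id range")
  }
  if (!is.null(bait_genes)) {
    bait_genes <- as.data.table(bait_genes)[, .(fragment_id, gene)]
    if (!all(bait_genes$fragment_id %in% fr$fragment_id[fr$bait])) {
      stop("bait_genes must reference bait fragment ids")
    }
  }
  structure(list(fragments = fr[], bait_genes = bait_genes),
            class = "fragment_map")
}

#' @export
print.fragment_map <- function(x, ...) {
  fr <- x$fragments
  cat(sprintf("fragment_map: %d fragments on %d chromosome(s), %d baits\n",
              nrow(fr), uniqueN(fr$chrom), sum(fr$bait)))
  invisible(x)
}

bait_ids <- function(map) map$fragments$fragment_id[map$fragments$bait]

#' Digest genome sequences in silico
#'
#' Cuts every occurrence of a restriction-site motif at `site_start +
#' cut_offset`; the default is HindIII (`A^AGCTT`). Motif occurrences are
#' located left-to-right; `N` bases never match. An empty sequence yields no
#' fragments for that chromosome; a sequence with no cut site yields one
#' fragment covering it.
#'
#' @param sequences named character vector or list, chromosome -> DNA string
#'   (A/C/G/T/N).
#' @param site recognition motif, e.g. `"AAGCTT"`.
#' @param cut_offset cut position relative to motif start, `0 <= cut_offset <=
#'   nchar(site)`.
#' @param bait_ids,bait_genes forwarded to [fragment_map()].
#' @return a [fragment_map()].
#' @export
digest_genome <- function(sequences, site = "AAGCTT", cut_offset = 1L,
                          bait_ids = integer(0), bait_genes = NULL) {
  stopifnot(nzchar(site), cut_offset >= 0L, cut_offset <= nchar(site))
  pieces <- lapply(names(sequences), function(chrom) {
    seq <- sequences[[chrom]]
    len <- nchar(seq)
    if (len == 0L) return(NULL)
    hits <- Biostrings::matchPattern(site, Biostrings::DNAString(seq))
    cuts <- BiocGenerics::start(hits) - 1L + cut_offset   # back to 0-based
    cuts <- sort(unique(cuts[cuts > 0L & cuts < len]))
    bounds <- c(0L, cuts, len)
    data.table(chrom = chrom, start = bounds[-length(bounds)],
               end = bounds[-1L])
  })
  fragment_map(rbindlist(pieces), bait_ids = bait_ids, bait_genes = bait_genes)
}

#' Locate the fragment containing a position
#'
#' Binary search for the unique fragment with `start <= pos < end`.
#' Vectorised over `chrom`/`pos`.
#'
#' @param map a [fragment_map()].
#' @param chrom chromosome name(s).
#' @param pos 0-based position(s).
#' @return integer fragment id(s); error if any position falls outside the
#'   digested extent of its chromosome.
#' @export
locate_fragment <- function(map, chrom, pos) {
  fr <- map$fragments
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- integer(n)
  for (cc in unique(chrom)) {
    sub <- fr[chrom == cc]
    sel <- which(chrom == cc)
    if (!nrow(sub)) stop(sprintf("no fragments on chromosome %s", cc))
    idx <- findInterval(pos[sel], sub$start)
    ok <- idx >= 1L & pos[sel] < sub$end[pmax(idx, 1L)]
    if (any(!ok)) {
      stop(sprintf("position %d on %s is outside the fragment map",
                   pos[sel][!ok][1L], cc))
    }
    out[sel] <- sub$fragment_id[idx]
  }
  out
}

#' Midpoint distance between two fragments
#'
#' Midpoint-to-midpoint distance in bp for fragments on the same chromosome;
#' trans (inter-chromosomal) pairs return `Inf` so that distance-stratified
#' code must branch explicitly.
#'
#' @param map a [fragment_map()].
#' @param i,j fragment ids (vectorised).
#' @return numeric distances (`Inf` for trans pairs).
#' @export
fragment_distance <- function(map, i, j) {
  fr <- map$fragments
  stopifnot(all(c(i, j) %in% fr$fragment_id))
  mid <- (fr$start + fr$end) / 2
  d <- abs(mid[i] - mid[j])
  d[fr$chrom[i] != fr$chrom[j]] <- Inf
  d
}

#' Serialise / load a fragment map
#'
#' Tab-delimited `chrom start end fragment_id bait gene`.
#'
#' @param map a [fragment_map()].
#' @param path file path.
#' @export
write_fragment_map <- function(map, path) {
  out <- copy(map$fragments)
  out[, bait := as.integer(bait)]
  if (!is.null(map$bait_genes)) {
    out <- merge(out, map$bait_genes, by = "fragment_id", all.x = TRUE,
                 sort = FALSE)
    setorder(out, fragment_id)
    setcolorder(out, c("chrom", "start", "end", "fragment_id", "bait", "gene"))
  }
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_fragment_map
#' @export
read_fragment_map <- function(path) {
  dt <- fread(path)
  genes <- if ("gene" %in% names(dt)) {
    dt[bait == 1L & !is.na(gene) & nzchar(gene), .(fragment_id, gene)]
  }
  fragment_map(dt[, .(chrom, start, end)],
               bait_ids = dt$fragment_id[dt$bait == 1L],
               bait_genes = genes)
}
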