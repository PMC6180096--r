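# Shared fixture builders; everything is generated in code.

# A toy map: two chromosomes tiled by fixed-length fragments.
toy_map <- function(frag_len = 100L, n_frags = 10L, n_chrom = 2L,
                    bait_ids = c(1L, 4L)) {
  fr <- data.table::rbindlist(lapply(seq_len(n_chrom), function(cc) {
    data.table::data.table(
      chrom = paste0("chr", cc),
      start = seq(0L, by = frag_len, length.out = n_frags),
      end = seq(frag_len, by = frag_len, length.out = n_frags))
  }))
  genes <- data.table::data.table(
    fragment_id = bait_ids, gene = sprintf("gene%02d", seq_along(bait_ids)))
  fragment_map(fr, bait_ids = bait_ids, bait_genes = genes)
}

# Brute-force O(m^2) BH step-up oracle.
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  q <- numeric(m)
  for (k in seq_len(m)) {
    q[k] <- min(1, min(m * p[r >= r[k]] / r[r >= r[k]]))
  }
  q
}

# Direct log-space summation of the binomial upper tail P(X >= k).
binom_upper_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  if (p <= 0) return(0)
  ks <- k:min(n, k + 20000L)   # far tail is negligible at double precision
  lt <- lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)
  M <- max(lt)
  exp(M) * sum(exp(lt - M))
}

# peak_set from start/end vectors on one chromosome
quick_peaks <- function(mark, starts, ends, chrom = "chr1",
                        signal_density = NULL) {
  peak_set(data.table::data.table(chrom = chrom, start = as.integer(starts),
                                  end = as.integer(ends)),
           mark = mark, signal_density = signal_density)
}
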