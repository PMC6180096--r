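#' @import data.table
#' @importFrom stats pbinom p.adjust rgeom rnorm runif rhyper rmultinom
#'   quantile median sd kmeans chisq.test prop.test aov TukeyHSD t.test
#'   setNames dist
#' @importFrom utils head tail
NULL

# centred moving average with partial windows at the edges, so the smoothed
# signal is not artificially pulled to zero at the grid boundaries
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Benjamini-Hochberg step-up on log p-values; returns log q-values.
# Used wherever p-values underflow double precision (deep binomial tails).
bh_adjust_log <- function(logp) {
  m <- length(logp)
  if (m == 0L) return(numeric(0))
  o <- order(logp)
  lq <- logp[o] + log(m) - log(seq_len(m))
  lq <- rev(cummin(rev(lq)))
  lq <- pmin(lq, 0)
  out <- numeric(m)
  out[o] <- lq
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: `q_(k) = min_{r >= k} m p_(r) / r`,
#' capped at 1 and returned in the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues), all(pvalues >= 0 & pvalues <= 1))
  p.adjust(pvalues, method = "BH")
}

# derive a reproducible child seed from a base seed and a stream label,
# staying well inside 32-bit integer range
child_seed <- function(seed, stream) {
  offsets <- c(map = 11L, visibility = 23L, spikes = 37L, test = 53L,
               ref = 71L, peaks = 89L, expression = 107L, folds = 131L,
               pipeline = 151L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 2654435.0 + off * 97.0) %% 2147483647)
}
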