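#' Multi-level Otsu thresholding
#'
#' Selects `levels` thresholds that partition a 256-bin histogram of the
#' value range into `levels + 1` classes maximizing the between-class
#' variance (the weighted sum of squared class-mean deviations), the direct
#' generalization of Otsu's two-class criterion. The maximization is exact
#' over the histogram (dynamic programming over bin cut points); ties are
#' broken toward the smallest thresholds so the result is deterministic.
#'
#' @param values numeric vector or matrix of intensities.
#' @param levels number of thresholds (>= 1); the data must contain at least
#'   `levels + 1` distinct values.
#' @param n_bins histogram resolution (default 256).
#' @return Ascending numeric vector of `levels` thresholds, each lying on a
#'   histogram bin edge; a value v belongs to class k when
#'   `thresholds[k] <= v < thresholds[k + 1]`.
#' @examples
#' x <- c(rnorm(200, 30, 2), rnorm(200, 120, 4), rnorm(200, 220, 3))
#' multilevel_otsu(x, levels = 2)
#' @export
multilevel_otsu <- function(values, levels, n_bins = 256) {
  v <- as.vector(values)
  v <- v[is.finite(v)]
  levels <- as.integer(levels)
  if (levels < 1) stop("`levels` must be at least 1")
  nd <- length(unique(v))
  if (nd < levels + 1)
    stop("need at least ", levels + 1, " distinct values for ", levels,
         " threshold(s); got ", nd)
  lo <- min(v); hi <- max(v)
  width <- (hi - lo) / n_bins
  bin <- pmin(floor((v - lo) / width) + 1, n_bins)
  p <- tabulate(bin, n_bins) / length(v)
  mids <- lo + (seq_len(n_bins) - 0.5) * width
  P <- cumsum(p)
  S <- cumsum(p * mids)
  # between-class contribution of a class spanning bins i..j (i or j vector)
  P0 <- c(0, P); S0 <- c(0, S)
  csum <- function(i, j) {
    w <- P[j] - P0[i]
    s <- S[j] - S0[i]
    ifelse(w > 0, s^2 / w, 0)
  }
  # f[k, j]: best sum of contributions for classes 1..k covering bins 1..j
  nb <- n_bins
  f <- matrix(-Inf, levels + 1, nb)
  cut <- array(0L, c(levels + 1, nb))
  f[1, ] <- csum(1, seq_len(nb))
  for (k in 2:(levels + 1)) {
    for (j in k:nb) {
      i <- k:j  # class k spans bins i..j
      cand <- f[k - 1, i - 1] + csum(i, j)
      best <- which.max(cand)  # first maximum -> smallest cut
      f[k, j] <- cand[best]
      cut[k, j] <- i[best] - 1L
    }
  }
  cuts <- integer(levels)
  j <- nb
  for (k in (levels + 1):2) {
    cuts[k - 1] <- cut[k, j]
    j <- cut[k, j]
  }
  lo + cuts * width  # lower edge of the first bin of each upper class
}
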