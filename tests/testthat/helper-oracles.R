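# Independent reference implementations used as oracles. They are written
# for transparency, not speed, and deliberately avoid the package's compiled
# code paths.

# --- object-level similarity by exhaustive pixel counting -------------------
oracle_sm <- function(R, T_, k = 0.6) {
  rl <- setdiff(sort(unique(as.vector(R))), 0L)
  tl <- setdiff(sort(unique(as.vector(T_))), 0L)
  N <- length(rl); M <- length(tl)
  stopifnot(N >= 1)
  if (M == 0) return(list(sm = 0, term1 = 0, term2 = 0))
  inter <- matrix(0L, N, M, dimnames = list(rl, tl))
  for (i in seq_along(rl)) for (j in seq_along(tl))
    inter[i, j] <- sum(R == rl[i] & T_ == tl[j])
  rs <- vapply(rl, function(l) sum(R == l), integer(1))
  ts <- vapply(tl, function(l) sum(T_ == l), integer(1))
  best_dice <- numeric(N)
  for (i in seq_len(N)) {
    js <- which(inter[i, ] > 0)
    if (length(js))
      best_dice[i] <- max(2 * inter[i, js] / (rs[i] + ts[js]))
  }
  # mutual best overlap, ties toward the smaller partner label
  n_match <- 0L
  for (i in seq_len(N)) {
    js <- which(inter[i, ] > 0)
    if (!length(js)) next
    j <- js[which.max(inter[i, js])]
    is <- which(inter[, j] > 0)
    i2 <- is[which.max(inter[is, j])]
    if (i2 == i) n_match <- n_match + 1L
  }
  term1 <- mean(best_dice)
  term2 <- 2 * n_match / (N + M)
  list(sm = k * term1 + (1 - k) * term2, term1 = term1, term2 = term2,
       n_match = n_match)
}

# --- multi-level Otsu by brute force over histogram cut points --------------
# Histogram rule mirrors the documented contract (256 equal bins over the
# value range, value -> bin floor((v - lo)/width) + 1 capped at 256); the
# search over cut combinations is exhaustive over the occupied bins.
oracle_otsu_variance <- function(values, thresholds, n_bins = 256) {
  v <- as.vector(values)
  lo <- min(v); hi <- max(v)
  width <- (hi - lo) / n_bins
  mids <- lo + (seq_len(n_bins) - 0.5) * width
  p <- tabulate(pmin(floor((v - lo) / width) + 1, n_bins), n_bins)
  p <- p / sum(p)
  cls <- findInterval(mids, sort(thresholds))  # 0..levels
  s <- 0
  for (kk in unique(cls)) {
    w <- sum(p[cls == kk])
    if (w > 0) s <- s + sum(p[cls == kk] * mids[cls == kk])^2 / w
  }
  s
}

oracle_otsu_best <- function(values, levels, n_bins = 256) {
  v <- as.vector(values)
  lo <- min(v); hi <- max(v)
  width <- (hi - lo) / n_bins
  bins <- sort(unique(pmin(floor((v - lo) / width) + 1, n_bins)))
  # candidate thresholds: the lower edge of every occupied bin but the first
  cand <- lo + (bins[-1] - 1) * width
  best <- -Inf
  for (cmb in utils::combn(length(cand), levels, simplify = FALSE)) {
    s <- oracle_otsu_variance(values, cand[cmb], n_bins)
    if (s > best) best <- s
  }
  best
}

# --- seeded watershed by transparent frontier scanning ----------------------
# Same flood semantics as the compiled implementation (priority = surface
# value, FIFO among equal priorities, neighbors visited in fixed column-major
# (dc, dr) order, each pixel queued once), realized with plain vectors and a
# linear minimum scan.
oracle_watershed <- function(surface, markers, mask) {
  H <- nrow(surface); W <- ncol(surface)
  dr <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  dc <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  lab <- matrix(0L, H, W)
  lab[markers > 0 & mask > 0] <- markers[markers > 0 & mask > 0]
  queued <- lab > 0
  q_pix <- integer(0); q_val <- numeric(0); q_ord <- integer(0)
  q_lab <- integer(0)
  ord <- 0L
  push_neighbors <- function(r, c, from_label) {
    for (k in 1:8) {
      rr <- r + dr[k]; cc <- c + dc[k]
      if (rr < 1 || rr > H || cc < 1 || cc > W) next
      if (mask[rr, cc] > 0 && lab[rr, cc] == 0 && !queued[rr, cc]) {
        queued[rr, cc] <<- TRUE
        ord <<- ord + 1L
        q_pix <<- c(q_pix, rr + H * (cc - 1))
        q_val <<- c(q_val, surface[rr, cc])
        q_ord <<- c(q_ord, ord)
        q_lab <<- c(q_lab, from_label)
      }
    }
  }
  seedpix <- which(lab > 0)  # column-major = raster order of the C++ loops
  for (p in seedpix) {
    r <- (p - 1) %% H + 1; c <- (p - 1) %/% H + 1
    push_neighbors(r, c, lab[r, c])
  }
  while (length(q_pix)) {
    i <- order(q_val, q_ord)[1]
    p <- q_pix[i]; l <- q_lab[i]
    q_pix <- q_pix[-i]; q_val <- q_val[-i]; q_ord <- q_ord[-i]
    q_lab <- q_lab[-i]
    r <- (p - 1) %% H + 1; c <- (p - 1) %/% H + 1
    if (lab[r, c] != 0) next
    lab[r, c] <- l
    push_neighbors(r, c, l)
  }
  lab
}

# --- AUC as the Mann-Whitney pairwise ranking statistic ---------------------
oracle_auc_rank <- function(prob, truth) {
  pos <- prob[truth > 0]; neg <- prob[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# --- grayscale opening by direct sliding min-then-max -----------------------
oracle_opening <- function(img, k) {
  H <- nrow(img); W <- ncol(img)
  lo <- (k - 1) %/% 2; hi <- (k - 1) - lo
  er <- matrix(0, H, W); op <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W)
    er[r, c] <- min(img[max(1, r - lo):min(H, r + hi),
                        max(1, c - lo):min(W, c + hi)])
  for (r in 1:H) for (c in 1:W)
    op[r, c] <- max(er[max(1, r - hi):min(H, r + lo),
                       max(1, c - hi):min(W, c + lo)])
  op
}

# small helper: random label map with a few rectangular objects
random_label_map <- function(h, w, n_obj) {
  m <- matrix(0L, h, w)
  for (l in seq_len(n_obj)) {
    r0 <- sample.int(h, 1); c0 <- sample.int(w, 1)
    r1 <- min(h, r0 + sample.int(6, 1)); c1 <- min(w, c0 + sample.int(6, 1))
    m[r0:r1, c0:c1] <- l
  }
  m
}

disk_mask <- function(h, w, r0, c0, rad) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - r0)^2 + (cc - c0)^2 <= rad^2
}
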