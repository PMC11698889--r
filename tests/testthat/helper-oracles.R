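# Independent reference implementations used as oracles. These deliberately
# take the slow, direct route (per-pixel loops, dynamic programming, full
# enumeration) so they share no code with the package internals.

# per-pixel brute-force rolling-median despike (edge-truncated windows)
oracle_rolling_median <- function(x, size, k) {
  h <- size %/% 2
  nr <- nrow(x); nc <- ncol(x)
  out <- x
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      win <- x[max(1, i - h):min(nr, i + h), max(1, j - h):min(nc, j + h)]
      m <- stats::median(win)
      s <- stats::mad(win, center = m)  # 1.4826 * median |win - m|
      if (abs(x[i, j] - m) > k * s) out[i, j] <- m
    }
  }
  out
}

# exact 1-D k-partition by dynamic programming: optimal clusters are
# contiguous in sorted order, so DP over split points finds the global
# optimum of the within-cluster sum of squares
oracle_kmeans_dp <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  ssq <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in 1:n) D[1, j] <- ssq(1, j)
  if (k > 1) {
    for (q in 2:k) {
      for (j in q:n) {
        for (i in q:j) {
          v <- D[q - 1, i - 1] + ssq(i, j)
          if (v < D[q, j]) { D[q, j] <- v; B[q, j] <- i }
        }
      }
    }
  }
  starts <- integer(k)
  starts[1] <- 1L
  jj <- n
  for (q in k:2) { starts[q] <- B[q, jj]; jj <- starts[q] - 1L }
  centroids <- vapply(seq_len(k), function(q) {
    j <- if (q == k) n else starts[q + 1] - 1L
    mean(x[starts[q]:j])
  }, numeric(1))
  list(wcss = D[k, n], starts = starts, sorted = x, centroids = centroids)
}

# one-tailed Mann-Whitney p-value by enumerating every assignment of the
# pooled values to the two groups (alternative: b stochastically greater)
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); nb <- length(b)
  ustat <- function(bb, aa)
    sum(outer(bb, aa, ">")) + 0.5 * sum(outer(bb, aa, "=="))
  u_obs <- ustat(b, a)
  cmb <- utils::combn(n, nb)
  us <- apply(cmb, 2, function(idx) ustat(pooled[idx], pooled[-idx]))
  mean(us >= u_obs - 1e-12)
}

# two-tailed Wilcoxon signed-rank p-value by enumerating all 2^n sign
# patterns of the ranked absolute differences (tie-free, nonzero d)
oracle_wsr_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  vs <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  mean(abs(vs - ev) >= abs(v_obs - ev) - 1e-12)
}

# small well-separated phantom configuration: tight within-sample spread so
# glass / adipose / epithelial intensity modes do not overlap
separated_config <- function(shape = c(80L, 100L)) {
  cfg <- phantom_config(shape = shape)
  for (el in names(cfg$elements)) cfg$elements[[el]]$within_qr <- 1.6
  cfg
}
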