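# Internal numerical helpers.

# Weighted pool-adjacent-violators: least-squares non-decreasing fit of y
# with weights w. Small J (number of doses), so the simple block-merge loop
# is plenty fast.
.pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n <= 1L) return(y)
  yhat <- y
  wt <- w
  size <- rep(1L, n)
  i <- 1L
  while (i < length(yhat)) {
    if (yhat[i] > yhat[i + 1L]) {
      tw <- wt[i] + wt[i + 1L]
      yhat[i] <- (wt[i] * yhat[i] + wt[i + 1L] * yhat[i + 1L]) / tw
      wt[i] <- tw
      size[i] <- size[i] + size[i + 1L]
      yhat <- yhat[-(i + 1L)]
      wt <- wt[-(i + 1L)]
      size <- size[-(i + 1L)]
      if (i > 1L) i <- i - 1L
    } else {
      i <- i + 1L
    }
  }
  rep(yhat, size)
}

# Deterministic 31-bit seed from a master seed plus string labels, so each
# simulation cell (scenario x design) gets an independent, order-stable
# stream. Doubles stay exact: intermediate values < 2^36.
.cell_seed <- function(master_seed, ...) {
  m <- 2147483647
  h <- as.double(master_seed) %% m
  for (ch in utf8ToInt(paste(..., sep = "\r"))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

# Smallest DLT count that triggers elimination at each n in 1..n_max:
# Pr(p > phi | y, n) > cutoff under a Beta(1, 1) prior, applied from
# n >= 3. Two-pointer walk keeps this O(n_max) pbeta calls.
.elimination_boundary <- function(phi, n_max, cutoff = 0.95) {
  out <- rep(NA_integer_, n_max)
  y <- 0L
  for (n in seq_len(n_max)) {
    if (y > n) y <- n
    while (y <= n && 1 - pbeta(phi, y + 1, n - y + 1) <= cutoff) {
      y <- y + 1L
    }
    if (n >= 3L && y <= n) out[n] <- y
  }
  out
}

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}

.is_prob <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x > 0) && all(x < 1)
}
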