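# Independent oracles used across the suite. Each is implemented from the
# textbook definition, deliberately sharing no code with the package.

# Brute-force intermodes threshold: histogram smoothing written directly
# from the definition (zero-padded (1,2,1)/4 kernel; additions and exact
# binary divisions by four only).
oracle_intermodes <- function(values, bins = 256L, max_iter = 10000L) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  h <- numeric(bins)
  for (i in idx) h[i] <- h[i] + 1
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
  peaks <- function(h) {
    out <- integer()
    for (i in seq_along(h)) {
      left <- if (i == 1L) 0 else h[i - 1L]
      right <- if (i == length(h)) 0 else h[i + 1L]
      if (h[i] > left && h[i] > right) out <- c(out, i)
    }
    out
  }
  for (it in seq_len(max_iter)) {
    pk <- peaks(h)
    if (length(pk) == 2L) return(mean(centers[pk]))
    if (length(pk) < 2L) stop("oracle: not bimodal")
    hn <- numeric(length(h))
    for (i in seq_along(h)) {
      left <- if (i == 1L) 0 else h[i - 1L]
      right <- if (i == length(h)) 0 else h[i + 1L]
      hn[i] <- (left + 2 * h[i] + right) / 4
    }
    h <- hn
  }
  stop("oracle: iteration cap")
}

# Direct (non-separable) Gaussian convolution with scipy-style reflect
# padding, written as an explicit double loop.
oracle_gaussian_blur <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  n <- nrow(x); m <- ncol(x)
  refl <- function(i, n) { # mirror with edge duplicated
    while (i < 1L || i > n) {
      if (i < 1L) i <- 1L - i
      if (i > n) i <- 2L * n + 1L - i
    }
    i
  }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- 0
    for (di in -r:r) for (dj in -r:r)
      s <- s + K[di + r + 1L, dj + r + 1L] *
        x[refl(i + di, n), refl(j + dj, m)]
    out[i, j] <- s
  }
  out
}

# FAO-56 saturation vapor pressure table, frozen from an independent
# evaluation of e_s = 0.6108 exp(17.27 T / (T + 237.3)) (kPa).
ES_TABLE <- data.frame(
  temp = seq(0, 45, by = 5),
  es = c(0.6108, 0.872311, 1.227963, 1.705346, 2.338281, 3.167778,
         4.243065, 5.622681, 7.375614, 9.582483))

# Textbook Benjamini-Hochberg step-up, implemented directly from the sort
# definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (k in m:1) {
    running <- min(running, p[o[k]] * m / k)
    adj[o[k]] <- min(1, running)
  }
  adj
}

# small balanced design used by the model tests
small_design <- function(n = 2L) {
  data.frame(provenance = rep(c("F3", "PL9", "ES1", "D8", "BG10", "I4"), 2),
             treatment = rep(c("control", "drought"), each = 6), n = n)
}
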