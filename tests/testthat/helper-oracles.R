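# Independent oracles, deliberately written with different machinery than
# the package implementations they check.

# Audic-Claverie two-sided p by direct pmf recursion and tail summation
# (same canonical orientation convention as the package: condition on the
# smaller count, ties towards the larger library).
acOracle <- function(x, y, N1, N2) {
  if (y < x || (y == x && N2 > N1)) {
    tmp <- x; x <- y; y <- tmp
    tmp <- N1; N1 <- N2; N2 <- tmp
  }
  r <- N2 / N1
  pm <- numeric(y + 1)
  pj <- (1 / (1 + r))^(x + 1)
  j <- 0
  tot <- 0
  upper <- 0                  # direct summation of P(Y >= y): no cancellation
  repeat {
    if (j <= y) pm[j + 1] <- pj
    if (j >= y) upper <- upper + pj
    tot <- tot + pj
    pj <- pj * r * (x + j + 1) / ((j + 1) * (1 + r))
    j <- j + 1
    if (j > 5e5) break
    if (tot > 1 - 1e-13 && j > y + 5 && pj < upper * 1e-15 + 1e-320) break
  }
  lower <- sum(pm)
  min(1, 2 * min(lower, upper))
}

# Hypergeometric upper tail by full enumeration with choose().
hyperOracle <- function(k, K, n, N) {
  kk <- max(0, n - (N - K)):min(K, n)
  pm <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(pm[kk >= k])
}

# BH step-up by its definition.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(p[o[i:m]] * m / (i:m)))
  }
  q
}

# Hamming distance between two equal-length strings.
hammingDist <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
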