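# Independent brute-force oracles: plain double loops, no shared code with the
# package internals they check.

bruteRowP <- function(x, w, eps, i) {
  n <- nrow(x)
  k <- numeric(n)
  for (j in seq_len(n)) {
    if (j == i) next
    k[j] <- sqrt(w[i] * w[j]) * exp(-eps * sum((x[i, ] - x[j, ])^2))
  }
  k / sum(k)
}

bruteEntropy <- function(p) {
  h <- 0
  for (pj in p) if (pj > 0) h <- h - pj * log2(pj)
  h
}

# decomposed entropy for exponential weights w = exp(beta * V):
# H = log2(Z) + eps/ln2 * <d^2>_p - beta/(2 ln2) * (V_i + <V_j>_p)
bruteEntropyDecomposed <- function(x, v, eps, i, beta = 1) {
  n <- nrow(x)
  w <- exp(beta * v)
  kern <- numeric(n)
  d2 <- numeric(n)
  for (j in seq_len(n)) {
    if (j == i) next
    d2[j] <- sum((x[i, ] - x[j, ])^2)
    kern[j] <- exp(beta * (v[i] + v[j]) / 2) * exp(-eps * d2[j])
  }
  z <- sum(kern)
  p <- kern / z
  log2(z) + eps / log(2) * sum(p * d2) -
    beta / (2 * log(2)) * (v[i] + sum(p * v))
}

bruteLatentQ <- function(s) {
  n <- nrow(s)
  e <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) e[i, j] <- 1 / (1 + sum((s[i, ] - s[j, ])^2))
  }
  e / sum(e)
}

bruteKL <- function(p, q) {
  tot <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) tot <- tot + p[i, j] * log(p[i, j] / q[i, j])
  }
  tot
}

# mixture assembled by explicit loops from given per-row scales
bruteMultiscale <- function(x, w, epsList) {
  n <- nrow(x)
  mats <- lapply(epsList, function(eps) {
    m <- matrix(0, n, n)
    for (i in seq_len(n)) m[i, ] <- bruteRowP(x, w, eps[i], i)
    m
  })
  Reduce(`+`, mats) / length(mats)
}

# numeric gradient of a scalar function by central differences
numGrad <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    e <- rep(0, length(x)); e[j] <- h
    g[j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  g
}
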