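# Fixtures built in code; no data files.

# small deterministic spectra set with an arbitrary smooth signal
small_spectra <- function(n = 6, p = 20, seed = 1, labels = NULL) {
  set.seed(seed)
  w <- seq(4000, by = 8, length.out = p)
  X <- outer(rnorm(n, 1, 0.1), sin(w / 500)) + matrix(rnorm(n * p, sd = 0.01), n, p)
  if (is.null(labels)) labels <- rep(c("a", "b"), length.out = n)
  spectra_set(X, w, labels)
}

# a compact synthetic configuration on the full default grid
default_cfg <- function(seed = 1, ...) synth_config(seed = seed, ...)

# principal angles (degrees) between the column spaces of two orthonormal bases
principal_angles <- function(A, B) {
  s <- svd(crossprod(A, B))$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}

# brute-force greedy Kennard-Stone, written independently of the package
ks_oracle <- function(X, m) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(dist(X))
  best <- NULL; dmax <- -1
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > dmax) { dmax <- D[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < m) {
    cand <- setdiff(1:n, sel)
    mind <- sapply(cand, function(c) min(D[c, sel]))
    sel <- c(sel, cand[which.max(mind)])
  }
  sel
}

# direct per-window polynomial least-squares fit (Savitzky-Golay oracle);
# returns the derivative of order m at the window centre, interior points only
sg_oracle <- function(x, window, polyorder, m = 0, step = 1) {
  p <- length(x)
  half <- (window - 1) / 2
  out <- rep(NA_real_, p)
  for (i in (half + 1):(p - half)) {
    idx <- (i - half):(i + half)
    z <- (idx - i) * step
    fit <- lm(x[idx] ~ poly(z, polyorder, raw = TRUE))
    out[i] <- coef(fit)[m + 1] * factorial(m)
  }
  out
}
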