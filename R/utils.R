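# Internal helpers: deterministic seed streams and small numerics.

# Derive a sub-seed from a root seed and a salt (integer or string).
# Keeps results < 2^31 and positive. Purely arithmetic so that the same
# (root, salt) pair always maps to the same stream, independent of platform.
.deriveSeed <- function(root, salt) {
  if (is.character(salt)) salt <- .hashString(salt)
  m <- 2147483629
  s <- (as.numeric(root) %% m) * 48271 + (as.numeric(salt) %% m) * 16807 + 11
  as.integer(s %% m + 1)
}

# Polynomial rolling hash of a string, modulo a prime below 2^31.
.hashString <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  m <- 2147483629
  for (ch in v) h <- (h * 131 + ch) %% m
  h
}

# Column-center a matrix, optionally about supplied means.
.centerCols <- function(y, center = NULL) {
  if (is.null(center)) center <- colMeans(y)
  sweep(y, 2, center)
}

# Numerical rank via relative singular-value threshold.
.numRank <- function(m, rel_tol = 1e-8) {
  s <- svd(m, nu = 0, nv = 0)$d
  if (!length(s) || s[1] == 0) return(0L)
  sum(s > rel_tol * s[1])
}

# Principal angles (degrees) between the column spaces of two matrices.
.principalAngles <- function(a, b) {
  qa <- qr.Q(qr(a))
  qb <- qr.Q(qr(b))
  s <- svd(crossprod(qa, qb), nu = 0, nv = 0)$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}
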