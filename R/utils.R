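# Internal numerical helpers shared across modules.

# Pearson correlation of each column of X with vector y, computed from
# moments so that zero-variance columns can be flagged (NA) instead of
# raising. X: n x p, y: length n.
.colPearson <- function(X, y) {
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 2L)
  xm <- colMeans(X)
  ym <- mean(y)
  yc <- y - ym
  num <- as.vector(crossprod(X, yc)) - 0          # sum(x*yc) - xm*sum(yc)=0
  sxx <- colSums(X^2) - n * xm^2
  syy <- sum(yc^2)
  out <- rep(NA_real_, ncol(X))
  ok <- sxx > .Machine$double.eps * n & syy > .Machine$double.eps * n
  out[ok] <- num[ok] / sqrt(sxx[ok] * syy)
  out[ok] <- pmin(1, pmax(-1, out[ok]))
  out
}

# Scalar Pearson r between two vectors; NA when either is constant.
.pearson <- function(x, y) .colPearson(matrix(x, ncol = 1L), y)[1L]

# z-score a vector; all-constant input returns NULL (undefined).
.zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s <= .Machine$double.eps) return(NULL)
  (x - mean(x)) / s
}

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so library code never perturbs user RNG.
.withSeed <- function(seed, expr) {
  seed <- as.integer(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Derive a stream-specific 31-bit sub-seed from a base seed.
.subSeed <- function(seed, k) {
  (as.integer(seed) * 48271 + as.integer(k) * 1299721) %% 2147483647L
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
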