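# Independent brute-force oracles and small fixture builders.

# direct-summation Pearson correlation (independent of the package's
# moment-based implementation)
bruteForcePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx2 <- dx2 + (x[i] - mx)^2
    dy2 <- dy2 + (y[i] - my)^2
  }
  if (dx2 == 0 || dy2 == 0) return(NA_real_)
  num / sqrt(dx2 * dy2)
}

# direct O(n*k) causal convolution oracle
bruteForceConv <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n))
    for (j in seq_along(k))
      if (t - j + 1 >= 1) out[t] <- out[t] + x[t - j + 1] * k[j]
  out
}

# rank-based AUC of scores for separating positives from negatives
rankAuc <- function(scorePos, scoreNeg) {
  r <- rank(c(scorePos, scoreNeg))
  nP <- length(scorePos); nN <- length(scoreNeg)
  (sum(r[seq_len(nP)]) - nP * (nP + 1) / 2) / (nP * nN)
}

# greedy matching of detected onsets to planted onsets within tol (s)
matchBouts <- function(planted, detected, tol = 0.05) {
  used <- rep(FALSE, length(detected))
  hits <- 0L
  for (p in planted) {
    d <- abs(detected - p)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      used[which.min(d)] <- TRUE
      hits <- hits + 1L
    }
  }
  list(recall = if (length(planted)) hits / length(planted) else NA_real_,
       precision = if (length(detected)) hits / length(detected) else NA_real_)
}

# small synthetic experiment used across module tests (cheap geometry)
smallExperiment <- function(seed = 1L, noise = noiseParams(), ...) {
  simulateExperiment(seed = seed, frameShape = c(64L, 48L),
                     nPerArchetype = c(swim_locked = 4L, stim_on = 4L,
                                       mixed = 4L, stim_suppressed = 4L),
                     noise = noise, ...)
}

# straight tail pointing along +x with the tip deflected by `angleDeg`
tailPoints <- function(angleDeg = 0, n = 9L) {
  ax <- seq(0, 8, length.out = n)
  pts <- cbind(x = ax, y = rep(0, n))
  th <- angleDeg * pi / 180
  r <- ax[n]
  pts[n, ] <- c(r * cos(th), r * sin(th))
  pts
}
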