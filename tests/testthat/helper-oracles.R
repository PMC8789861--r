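# Independent oracles used by the tests. These are deliberately naive
# implementations kept separate from the package code paths they check.

# Exhaustive affine-gap dynamic programming, local (Smith-Waterman).
# Gap of length L costs open + L * extend; returns the optimal score.
dpLocal <- function(q, r, match = 2, mismatch = -2, open = 8, extend = 1) {
  n <- nchar(q); m <- nchar(r)
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (qs[i - 1] == rs[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1], 0) + s
    X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend,
                   Y[i - 1, j] - open - extend)
    Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend,
                   X[i, j - 1] - open - extend)
    best <- max(best, M[i, j])
  }
  best
}

# Global affine-gap DP score oracle (for the compiled amplicon aligner).
dpGlobal <- function(q, r, match = 2, mismatch = -2, open = 8, extend = 1) {
  n <- nchar(q); m <- nchar(r)
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n > 0) for (i in 2:(n + 1)) X[i, 1] <- -open - extend * (i - 1)
  if (m > 0) for (j in 2:(m + 1)) Y[1, j] <- -open - extend * (j - 1)
  for (i in seq_len(n) + 1) for (j in seq_len(m) + 1) {
    s <- if (qs[i - 1] == rs[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend,
                   Y[i - 1, j] - open - extend)
    Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend,
                   X[i, j - 1] - open - extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# all sequences of the given length over an alphabet
allSeqs <- function(len, alphabet = c("A", "C")) {
  if (len == 0) return("")
  apply(expand.grid(rep(list(alphabet), len)), 1, paste, collapse = "")
}

# golden-section minimizer of f on [lo, hi]
goldenMin <- function(f, lo, hi, tol = 1e-12) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a); d1 <- a + phi * (b - a)
  while (b - a > tol) {
    if (f(c1) < f(d1)) { b <- d1 } else { a <- c1 }
    c1 <- b - phi * (b - a); d1 <- a + phi * (b - a)
  }
  (a + b) / 2
}

# dense grid search oracle for non-negative least squares on
# || A s - c ||^2 over the scaled simplex
gridNnlsObjective <- function(A, cvec, steps = 24) {
  tot <- sum(cvec)
  gr <- seq(0, 1, length.out = steps + 1)
  best <- Inf
  for (a1 in gr) for (a2 in gr) for (a3 in gr) {
    a4 <- 1 - a1 - a2 - a3
    if (a4 < 0) next
    s <- c(a1, a2, a3, a4) * tot
    best <- min(best, sum((A %*% s - cvec)^2))
  }
  best
}

# a toy transition model used across tests
toyCleavageModel <- function() {
  cleavageModel(rbind(c(0.97, 0.01, 0.01, 0.005, 0.005),
                      c(0, 1, 0, 0, 0),
                      c(0, 0, 0.88, 0, 0.12),
                      c(0, 0, 0, 0.85, 0.15)))
}

# uniform toy MOFF parameter bundle (no GMT model)
toyMoffParams <- function(m1val = 0.5, m2val = 0.8) {
  moffParameters(mismatchMatrix(matrix(m1val, 12, 20)),
                 combinatorialMatrix(matrix(m2val, 20, 20)))
}

# state vectors for an off/on cleavage pair with independent targets:
# off cleavage probability r * pOn, on cleavage probability pOn, so the
# off-on ratio of the construct equals r exactly
statesForRatio <- function(r, pOn = 0.6) {
  pOff <- r * pOn
  c((1 - pOff) * (1 - pOn), pOff * (1 - pOn), (1 - pOff) * pOn, pOff * pOn)
}
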