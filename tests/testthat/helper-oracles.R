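# Independent oracles, deliberately implemented apart from the package code
# they check.

# closed-form OLS via the normal equations
olsOracle <- function(v, i) {
  vbar <- mean(v); ibar <- mean(i)
  slope <- sum((v - vbar) * (i - ibar)) / sum((v - vbar)^2)
  list(slope = slope, intercept = ibar - slope * vbar)
}

# quadratic-time Smith-Waterman DP with affine gaps
# (gap of length L costs open + L * ext), scores floored at 0
swOracle <- function(a, b, mat, open, ext) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - ext, H[i, j - 1] - open - ext)
      F[i, j] <- max(F[i - 1, j] - ext, H[i - 1, j] - open - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[a[i - 1], b[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# brute-force enumeration of every motif window (C, n wildcards, C, H)
motifOracle <- function(seq, nInternal = 2L) {
  chars <- strsplit(seq, "")[[1]]
  L <- nInternal + 3L
  starts <- integer()
  if (length(chars) >= L) {
    for (s in seq_len(length(chars) - L + 1L)) {
      if (chars[s] == "C" && chars[s + nInternal + 1L] == "C" &&
          chars[s + nInternal + 2L] == "H")
        starts <- c(starts, s - 1L) # 0-based
    }
  }
  starts
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomPeptide <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
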