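# Independent oracles, written against textbook definitions and kept free of
# the package's implementation paths.

# BLOSUM62 with X scoring 0, as the scoring convention under test.
oracle_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      m <<- env$BLOSUM62
      m["X", ] <<- 0L
      m[, "X"] <<- 0L
    }
    m
  }
})

# Gotoh affine-gap dynamic programming, local (Smith-Waterman). The first
# residue of a gap costs open + extend.
oracle_sw_score <- function(a, b, open = 11, extend = 1) {
  sub <- oracle_submat()
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)   # gap in a (consumes b)
  F <- matrix(NEG, n + 1L, m + 1L)   # gap in b (consumes a)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - extend, E[i, j - 1L] - extend)
      F[i, j] <- max(H[i - 1L, j] - open - extend, F[i - 1L, j] - extend)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + sub[A[i - 1L], B[j - 1L]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Gotoh affine-gap dynamic programming, global (Needleman-Wunsch) with end
# gaps penalized.
oracle_nw_score <- function(a, b, open = 11, extend = 1) {
  sub <- oracle_submat()
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  H <- matrix(NEG, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)
  F <- matrix(NEG, n + 1L, m + 1L)
  H[1L, 1L] <- 0
  for (j in 2L:(m + 1L)) {
    E[1L, j] <- -open - extend * (j - 1L)
    H[1L, j] <- E[1L, j]
  }
  for (i in 2L:(n + 1L)) {
    F[i, 1L] <- -open - extend * (i - 1L)
    H[i, 1L] <- F[i, 1L]
  }
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - extend, E[i, j - 1L] - extend)
      F[i, j] <- max(H[i - 1L, j] - open - extend, F[i - 1L, j] - extend)
      H[i, j] <- max(H[i - 1L, j - 1L] + sub[A[i - 1L], B[j - 1L]],
                     E[i, j], F[i, j])
    }
  }
  H[n + 1L, m + 1L]
}

# Direct term-by-term summation of the binomial upper tail P(X >= k).
oracle_binom_tail <- function(k, n, p0) {
  if (k <= 0) return(1)
  if (p0 <= 0) return(0)
  if (p0 >= 1) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)))
}

# Textbook pooled two-sample t-test p-value (two-sided).
oracle_pooled_t_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tstat), df = n1 + n2 - 2)
}

random_aa_string <- function(len, alphabet = c("A", "C", "D", "E", "F", "G",
                                               "H", "I", "K", "L", "M", "N",
                                               "P", "Q", "R", "S", "T", "V",
                                               "W", "Y")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
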