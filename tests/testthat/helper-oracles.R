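## Independent brute-force oracles. These deliberately avoid the
## package's own code paths: plain loops and textbook formulas only.

## directional quantile by cumulative enumeration, upstream -> downstream
oracle_quantile_pos <- function(counts, rel, q) {
  tot <- sum(counts)
  acc <- 0
  for (i in seq_along(counts)) {
    acc <- acc + counts[i]
    if (acc >= q * tot) return(rel[i])
  }
  NA_integer_
}

## per-position efficiency by explicit suffix summation
oracle_suffix_efficiency <- function(counts) {
  n <- length(counts)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    denom <- 0
    for (j in i:n) denom <- denom + counts[j]
    if (denom > 0) out[i] <- counts[i] / denom
  }
  out
}

## first-success product chain by stepwise survival enumeration
oracle_chain_usage <- function(p) {
  u <- numeric(length(p))
  surv <- 1
  for (i in seq_along(p)) {
    u[i] <- surv * p[i]
    surv <- surv * (1 - p[i])
  }
  u
}

## per-position quadratic least squares via lm(), truncated windows
oracle_quadratic_smooth <- function(y, half = 10L) {
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    x <- (lo:hi) - i
    fit <- stats::lm(y[lo:hi] ~ x + I(x^2))
    out[i] <- unname(stats::coef(fit)[1])
  }
  out
}

## zero-padded kernel convolution by nested loops
oracle_convolve <- function(x, w) {
  half <- (length(w) - 1) %/% 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (d in -half:half) {
      j <- i + d
      if (j >= 1 && j <= n) out[i] <- out[i] + w[d + half + 1] * x[j]
    }
  }
  out
}

## element mismatch by per-position set membership
oracle_pattern_mm <- function(s, pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               W = c("A", "T"), R = c("A", "G"))
  sb <- strsplit(s, "")[[1]]; pb <- strsplit(pattern, "")[[1]]
  mm <- 0
  for (i in seq_along(pb)) if (!sb[i] %in% sets[[pb[i]]]) mm <- mm + 1
  mm
}
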