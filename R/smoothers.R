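#' Local quadratic (Savitzky-Golay-style) smoother
#'
#' At each position a second-order polynomial is least-squares fit over
#' a symmetric window of `half` neighbors each side (21 points by
#' default) and evaluated at the center. Edges use truncated windows
#' (no padding — mirror padding would fabricate signal). The smoother
#' is linear and reproduces quadratics exactly.
#'
#' @param y Numeric vector.
#' @param half Neighbors each side (default 10).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_quadratic <- function(y, half = 10L) {
  n <- length(y)
  if (n < 3) return(y)
  if (n < 2 * half + 1) {
    half <- max(1L, (n - 1L) %/% 2L)
    warning("profile shorter than smoothing span; span reduced to ", half,
            " neighbors each side")
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    x <- (lo:hi) - i
    if (length(x) < 3) { out[i] <- y[i]; next }
    X <- cbind(1, x, x^2)
    beta <- tryCatch(solve(crossprod(X), crossprod(X, y[lo:hi])),
                     error = function(e) NULL)
    out[i] <- if (is.null(beta)) y[i] else beta[1]
  }
  out
}

## kernels are weight vectors over offsets -half..half, summing to 1
kernel_uniform <- function(half = 5L) {
  rep(1 / (2 * half + 1), 2 * half + 1)
}

## triweight w(d) proportional to (1 - (d / (half + 1))^2)^3 for
## |d| <= half; the denominator half + 1 keeps endpoint weights nonzero
kernel_triweight <- function(half = 75L) {
  d <- -half:half
  w <- (1 - (d / (half + 1))^2)^3
  w / sum(w)
}

#' Convolve a profile with a symmetric kernel
#'
#' @param x Numeric vector.
#' @param w Kernel weights over offsets `-half..half` (odd length,
#'   summing to 1).
#' @param edge `"zero"` treats out-of-range signal as zero (mass is
#'   conserved in the interior); `"renorm"` renormalizes the truncated
#'   kernel at the edges (used for autocorrelation smoothing, where
#'   zero padding would fabricate a dip).
#' @return Smoothed vector of the same length.
#' @export
convolve_kernel <- function(x, w, edge = c("zero", "renorm")) {
  edge <- match.arg(edge)
  half <- (length(w) - 1L) %/% 2L
  n <- length(x)
  padded <- c(numeric(half), x, numeric(half))
  ## stats::filter computes sum_j w[j] * padded[i + half + 1 - (j - half - 1)]
  out <- stats::filter(padded, rev(w), sides = 2)
  out <- as.numeric(out[(half + 1L):(half + n)])
  if (edge == "renorm" && half > 0 && n > 1) {
    for (i in c(seq_len(min(half, n)), seq.int(max(1L, n - half + 1L), n))) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      ww <- w[(lo - i + half + 1L):(hi - i + half + 1L)]
      out[i] <- sum(ww * x[lo:hi]) / sum(ww)
    }
  }
  out
}
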