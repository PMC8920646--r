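# Internal numeric helpers shared across modules.

#' Analytic signal of a real vector via the frequency-domain construction
#'
#' Doubles positive frequencies, zeroes negative ones, keeps DC (and Nyquist
#' for even lengths), then inverse-transforms. Used for envelope detection.
#' @param x real numeric vector
#' @return complex vector of the same length
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 1L) return(complex(real = x, imaginary = 0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Population (n-denominator) central-moment statistics; the homodyned-K
# estimator and its lookup table must use identical definitions.
moment_stats <- function(x) {
  mu <- mean(x)
  d <- x - mu
  v <- mean(d^2)
  s <- sqrt(v)
  list(
    mean = mu,
    sd = s,
    snr = if (s > 0) mu / s else Inf,
    skewness = if (s > 0) mean(d^3) / s^3 else NaN,
    kurtosis = if (s > 0) mean(d^4) / v^2 else NaN
  )
}

#' Stratified fold assignment
#' @param y factor of class labels
#' @param k number of folds
#' @param seed integer seed controlling the shuffle
#' @return integer vector of fold ids in 1..k
#' @keywords internal
#' @noRd
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    idx <- sample(idx)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
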