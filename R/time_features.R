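#' Statistical time-domain features F1-F9
#'
#' Computes the nine statistical descriptors of a single-channel signal:
#' \describe{
#'   \item{F1 rms}{`sqrt(mean(x^2))`}
#'   \item{F2 square_mean_root}{`(mean(sqrt(abs(x))))^2`}
#'   \item{F3 peak_to_peak}{`max(abs(x)) - min(abs(x))`}
#'   \item{F4 kurtosis}{`mean(((x - mean(x)) / sd)^4)` (non-excess)}
#'   \item{F5 skewness}{`mean(((x - mean(x)) / sd)^3)`}
#'   \item{F6 kurtosis_factor}{`F4 / F1^4`}
#'   \item{F7 shape_factor}{`F1 / mean(abs(x))`}
#'   \item{F8 crest_factor}{`max(abs(x)) / F1`}
#'   \item{F9 impulse_factor}{`max(abs(x)) / mean(abs(x))`}
#' }
#' All moments use the population (1/N) convention. F6-F9 follow the
#' canonical vibration-analysis definitions built from F1 and F4.
#'
#' @param x Numeric signal of length >= 4 with positive variance.
#' @return Named numeric vector `F1`..`F9`.
#' @export
statistical_features <- function(x) {
  if (length(x) < 4) stop("signal too short: need at least 4 samples")
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  n <- length(x)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) stop("degenerate signal: zero variance")
  ax <- abs(x)
  rms <- sqrt(mean(x^2))
  mean_abs <- mean(ax)
  z <- (x - mu) / sigma
  c(F1 = rms,
    F2 = mean(sqrt(ax))^2,
    F3 = max(ax) - min(ax),
    F4 = mean(z^4),
    F5 = mean(z^3),
    F6 = mean(z^4) / rms^4,
    F7 = rms / mean_abs,
    F8 = max(ax) / rms,
    F9 = max(ax) / mean_abs)
}

#' Hjorth mobility (F10) and complexity (F11)
#'
#' Mobility is `sqrt(var(x') / var(x))` with `x'` the first difference
#' (no sampling-rate scaling, so mobility is in radians per sample);
#' complexity is the mobility of `x'` divided by the mobility of `x`.
#' Population variances throughout. Both are invariant to amplitude
#' scaling; for a pure sinusoid of angular frequency w per sample,
#' mobility approaches `2 * sin(w / 2)`.
#'
#' @param x Numeric signal; `x` and its first difference must both be
#'   non-constant.
#' @return Named numeric vector `c(F10, F11)`.
#' @export
hjorth_parameters <- function(x) {
  if (length(x) < 4) stop("signal too short: need at least 4 samples")
  pvar <- function(v) mean((v - mean(v))^2)
  d1 <- diff(x)
  d2 <- diff(d1)
  v0 <- pvar(x); v1 <- pvar(d1); v2 <- pvar(d2)
  if (v0 == 0 || v1 == 0) stop("degenerate signal: constant signal or constant first difference")
  mob <- sqrt(v1 / v0)
  c(F10 = mob, F11 = sqrt(v2 / v1) / mob)
}

#' All eleven time-domain features of a signal
#'
#' @param x Numeric signal.
#' @return Named numeric vector `F1`..`F11`.
#' @export
time_features <- function(x) {
  c(statistical_features(x), hjorth_parameters(x))
}
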