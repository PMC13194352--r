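#' @keywords internal
"_PACKAGE"

# Deterministic child seed derivation: one user-facing integer seed fans out to
# independent sub-generator streams, all kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(stream) * 16807
  as.integer(s %% 2147483587 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian smoothing of a sampled signal
#'
#' Zero-phase FIR smoothing with a Gaussian kernel, edge-padded by replication.
#' Used for energy-envelope extraction at several time scales.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param sigma_ms kernel standard deviation in milliseconds.
#' @return smoothed signal, same length as `x`.
#' @keywords internal
gaussian_smooth <- function(x, fs, sigma_ms) {
  sigma <- sigma_ms * fs / 1000
  if (sigma <= 0) return(x)
  half <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

# Indices of strict local maxima (plateaus resolved to their first sample).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Sub-sample peak refinement by parabolic interpolation around sample i.
# Returns fractional index.
refine_peak <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(as.numeric(i))
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (!is.finite(den) || den >= 0) return(as.numeric(i))
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / den
  if (abs(delta) > 1) delta <- sign(delta)
  i + delta
}

# Convert 1-based sample index (possibly fractional) to ms on the shared clock
# (sample 1 sits at t = 0).
idx_to_ms <- function(i, fs) (i - 1) / fs * 1000

ms_to_idx <- function(t_ms, fs) t_ms * fs / 1000 + 1

rms <- function(x) sqrt(mean(x^2))
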