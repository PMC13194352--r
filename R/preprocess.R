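# Filtering, artifact rejection, and respiratory gating.

check_filter_length <- function(x, fs, min_ms = 50) {
  if (length(x) < fs * min_ms / 1000)
    stop("recording shorter than filter warm-up (", min_ms, " ms)")
}

#' Band-pass filter a phonocardiogram (20--1,000 Hz band)
#'
#' Zero-phase Butterworth filtering: a 4th-order 20 Hz high-pass cascaded with
#' a 4th-order 950 Hz low-pass guard (the nominal 1,000 Hz upper edge equals
#' Nyquist at the 2 kHz sampling rate and is unrealizable exactly). Zero-phase
#' application keeps fiducial timings free of group delay.
#'
#' @param x PCG samples.
#' @param fs sampling rate in Hz (2000 expected).
#' @param low_hz,high_hz band edges.
#' @return filtered signal, same length.
#' @export
bandpass_pcg <- function(x, fs = 2000, low_hz = 20, high_hz = 950) {
  check_filter_length(x, fs)
  hp <- signal::butter(4, low_hz / (fs / 2), type = "high")
  y <- signal::filtfilt(hp, x)
  if (high_hz < fs / 2) {
    lp <- signal::butter(4, high_hz / (fs / 2), type = "low")
    y <- signal::filtfilt(lp, y)
  }
  y
}

#' Band-pass filter a single-lead ECG (0.5--40 Hz band)
#'
#' Zero-phase Butterworth filtering: 2nd-order 0.5 Hz high-pass plus 6th-order
#' 40 Hz low-pass, removing baseline drift and attenuating 50/60 Hz mains
#' interference by more than 20 dB.
#'
#' @param x ECG samples.
#' @param fs sampling rate in Hz (500 expected).
#' @param low_hz,high_hz band edges.
#' @return filtered signal, same length.
#' @export
bandpass_ecg <- function(x, fs = 500, low_hz = 0.5, high_hz = 40) {
  check_filter_length(x, fs)
  hp <- signal::butter(2, low_hz / (fs / 2), type = "high")
  lp <- signal::butter(6, high_hz / (fs / 2), type = "low")
  signal::filtfilt(lp, signal::filtfilt(hp, x))
}

#' Detect artifact-contaminated windows
#'
#' Scans the (filtered) PCG in contiguous 1-s windows and marks a window
#' invalid when either metric trips: (a) the window's peak envelope deviates
#' from the recording-median per-window envelope peak by more than
#' `amp_threshold` (fraction), or (b) the in-window burst-to-gap power ratio
#' falls below `snr_threshold_db`. Both metrics are reported for every window.
#' The trailing partial window is merged into the previous one so the mask
#' tiles the recording exactly.
#'
#' @param pcg filtered PCG samples.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 1).
#' @param amp_threshold relative amplitude-variation threshold (default 0.30).
#' @param snr_threshold_db SNR threshold in dB (default 10).
#' @return data.frame with one row per window: `start_ms`, `end_ms`,
#'   `amp_variation`, `snr_db`, `valid`.
#' @export
detect_artifacts <- function(pcg, fs = 2000, window_s = 1,
                             amp_threshold = 0.30, snr_threshold_db = 10) {
  n <- length(pcg)
  wlen <- as.integer(round(window_s * fs))
  n_win <- max(1L, n %/% wlen)
  starts <- (seq_len(n_win) - 1L) * wlen + 1L
  ends <- c(starts[-1L] - 1L, n)   # last window absorbs the partial tail

  env <- sqrt(gaussian_smooth(pcg^2, fs, 8))
  peak_w <- vapply(seq_len(n_win),
                   function(i) max(env[starts[i]:ends[i]]), numeric(1))
  med_peak <- stats::median(peak_w)

  burst <- env > 0.30 * med_peak
  snr_db <- vapply(seq_len(n_win), function(i) {
    idx <- starts[i]:ends[i]
    b <- burst[idx]
    if (!any(b) || all(b)) return(0)  # indistinguishable burst/background
    10 * log10(mean(pcg[idx][b]^2) / max(mean(pcg[idx][!b]^2), 1e-300))
  }, numeric(1))

  amp_var <- if (med_peak > 0) abs(peak_w - med_peak) / med_peak else
    rep(Inf, n_win)
  data.frame(start_ms = idx_to_ms(starts, fs),
             end_ms = ends / fs * 1000,
             amp_variation = amp_var, snr_db = snr_db,
             valid = amp_var <= amp_threshold & snr_db >= snr_threshold_db)
}

#' Estimate the respiratory lung-volume proxy from PCG amplitude modulation
#'
#' Extracts the slow (sub-cardiac-rate) modulation of the PCG energy envelope
#' and rescales it robustly to \[0, 1\]. Under the synthesizer's model the
#' heart-sound amplitude scales with lung volume, so the minimum of this
#' series marks end-expiration.
#'
#' @param pcg filtered PCG samples.
#' @param fs sampling rate in Hz.
#' @return numeric vector, one value per sample, in \[0, 1\].
#' @export
estimate_resp_volume <- function(pcg, fs = 2000) {
  env <- pcg_envelope(pcg, fs)
  # dominant burst (S1) heights, one per cardiac cycle: local envelope maxima
  # with a 350 ms exclusion zone, strongest kept
  m <- local_maxima(env)
  m <- m[env[m] > 0.4 * stats::median(env[m][env[m] >
          stats::quantile(env[m], 0.75)])]
  if (length(m) < 4) return(rep(NA_real_, length(pcg)))
  m <- m[order(env[m], decreasing = TRUE)]
  sep <- 0.35 * fs
  keep <- integer(0)
  for (i in m) if (!length(keep) || all(abs(keep - i) >= sep))
    keep <- c(keep, i)
  keep <- sort(keep)
  if (length(keep) < 4) return(rep(NA_real_, length(pcg)))
  h <- stats::approx(keep, env[keep], xout = seq_along(pcg),
                     rule = 2)$y
  lo <- stats::quantile(h, 0.05)
  hi <- stats::quantile(h, 0.95)
  if (hi - lo <= 0) return(rep(NA_real_, length(pcg)))
  pmin(1, pmax(0, (h - lo) / (hi - lo)))
}

#' Flag beats at end-expiration
#'
#' A beat is flagged when its respiratory phase lies within `tolerance` of the
#' end-expiration phase (pi by convention). The phase source is, in order of
#' preference: an explicit per-beat phase vector or phase function, or a
#' lung-volume estimate from the PCG amplitude modulation (phase within
#' tolerance of pi is equivalent to volume below (1 - cos(tolerance))/2). If
#' no source is available all beats are flagged and a warning is logged
#' (gating disabled).
#'
#' @param beat_times_ms beat reference times (R peaks), ms.
#' @param phase per-beat phase vector (radians) or function `t_ms -> radians`;
#'   optional.
#' @param pcg,fs filtered PCG and its sampling rate, used to estimate the
#'   phase when `phase` is missing.
#' @param tolerance half-width of the accepted phase window (default pi/4).
#' @param target_phase end-expiration phase convention (default pi).
#' @return logical vector, one flag per beat.
#' @export
respiratory_gate <- function(beat_times_ms, phase = NULL, pcg = NULL,
                             fs = 2000, tolerance = pi / 4,
                             target_phase = pi) {
  nb <- length(beat_times_ms)
  if (is.function(phase)) phase <- phase(beat_times_ms)
  if (!is.null(phase)) {
    d <- abs(((phase - target_phase) + pi) %% (2 * pi) - pi)
    return(d <= tolerance)
  }
  if (!is.null(pcg)) {
    vol <- estimate_resp_volume(pcg, fs)
    if (!anyNA(vol)) {
      vb <- vol[pmin(length(vol), pmax(1L, round(ms_to_idx(beat_times_ms, fs))))]
      return(vb <= (1 - cos(tolerance)) / 2)
    }
  }
  warning("no respiratory phase obtainable; gating disabled (all beats flagged)")
  rep(TRUE, nb)
}
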