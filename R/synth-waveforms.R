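#' Synthesize a single-lead paediatric ECG with known fiducials
#'
#' Builds a template-based sinus-rhythm ECG (P wave, raised-cosine Q dip,
#' Gaussian R/S/T deflections) sampled at `fs`. The returned ground truth
#' carries the template anchors (Q onset, R peak) for every beat, so detector
#' accuracy can be scored exactly.
#'
#' @param heart_rate_bpm mean heart rate, beats per minute (40--200).
#' @param n_beats number of beats to generate (>= 1).
#' @param rr_jitter fractional beat-to-beat RR variability (SD of the
#'   multiplicative Gaussian jitter); 0 gives a metronomic rhythm.
#' @param noise_snr_db additive white-noise level relative to the signal RMS,
#'   in dB; `Inf` (default) adds no noise.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param fs sampling rate in Hz (default 500, the device's ECG rate).
#' @return list with `signal`, `fs`, `duration_ms`, and `truth`, a data.frame
#'   with one row per beat (`beat`, `q_onset_ms`, `r_peak_ms`, `rr_ms`).
#' @export
#' @examples
#' e <- generate_ecg(86, 30, seed = 1)
#' diff(e$truth$r_peak_ms)[1]  # 60000/86 = 697.7 ms
generate_ecg <- function(heart_rate_bpm, n_beats, rr_jitter = 0,
                         noise_snr_db = Inf, seed = 1L, fs = 500) {
  if (!is.finite(heart_rate_bpm) || heart_rate_bpm < 40 || heart_rate_bpm > 200)
    stop("heart_rate_bpm must lie in [40, 200]")
  if (!is.finite(n_beats) || n_beats < 1)
    stop("n_beats must be a positive integer")
  if (rr_jitter < 0) stop("rr_jitter must be non-negative")
  n_beats <- as.integer(n_beats)
  set.seed(child_seed(seed, 11L))

  rr0 <- 60000 / heart_rate_bpm
  rr <- rr0 * (1 + rr_jitter * stats::rnorm(n_beats))
  rr <- pmax(rr, 300)
  r_times <- 400 + cumsum(c(0, rr[-n_beats]))
  rr_ms <- c(diff(r_times), rr[n_beats])
  q_onset <- r_times - 40

  duration_ms <- r_times[n_beats] + 600
  n <- as.integer(ceiling(duration_ms * fs / 1000))
  t <- idx_to_ms(seq_len(n), fs)
  x <- numeric(n)
  gauss <- function(c0, sd, amp) amp * exp(-((t - c0)^2) / (2 * sd^2))
  for (k in seq_len(n_beats)) {
    r <- r_times[k]
    x <- x + gauss(r - 160, 18, 0.12)            # P wave
    qi <- which(t >= r - 40 & t <= r - 10)       # Q: 30 ms raised-cosine dip
    x[qi] <- x[qi] - 0.15 * 0.5 * (1 - cos(2 * pi * (t[qi] - (r - 40)) / 30))
    x <- x + gauss(r, 8, 1.0)                    # R
    x <- x + gauss(r + 28, 9, -0.25)             # S
    x <- x + gauss(r + 220, 45, 0.35)            # T
  }
  if (is.finite(noise_snr_db))
    x <- x + stats::rnorm(n, sd = rms(x) * 10^(-noise_snr_db / 20))

  list(signal = x, fs = fs, duration_ms = n / fs * 1000,
       truth = data.frame(beat = seq_len(n_beats), q_onset_ms = q_onset,
                          r_peak_ms = r_times, rr_ms = rr_ms))
}

# Heart-sound burst envelopes ------------------------------------------------

# S1 is a Gaussian-windowed low-frequency burst: envelope peak sits exactly at
# the window centre. A2/P2 are short attack-decay clicks so that narrow S2
# splits remain resolvable; their envelope (1 - exp(-u/rise)) * exp(-u/decay)
# peaks at u* = rise * log(1 + decay/rise), which the generator subtracts so
# the requested peak time is exact.
s1_burst <- function(t, peak_ms, amp = 1, sigma_ms = 10, freq_hz = 55) {
  amp * exp(-((t - peak_ms)^2) / (2 * sigma_ms^2)) *
    cos(2 * pi * freq_hz * (t - peak_ms) / 1000)
}

s2_click <- function(t, peak_ms, amp, rise_ms = 0.6, decay_ms = 2.2,
                     freq_hz = 180) {
  t_star <- rise_ms * log(1 + decay_ms / rise_ms)
  u <- t - (peak_ms - t_star)
  env <- ifelse(u > 0, (1 - exp(-u / rise_ms)) * exp(-u / decay_ms), 0)
  amp * env * sin(2 * pi * freq_hz * pmax(u, 0) / 1000)
}

#' Synthesize a phonocardiogram matched to an ECG ground truth
#'
#' Places S1 bursts and A2/P2 clicks per beat so that the generated timing
#' indices are exactly the requested values: the S1 envelope peak falls at
#' `q_onset + emat_ms`, the A2 peak at `s1_peak + s1s2_ms`, and the P2 peak at
#' `a2_peak + split`, where the instantaneous split is
#' `s2_split_ms + resp_mod_ms * sin(respiratory phase)`. Optional per-beat
#' jitter (mean-centred within the recording) adds physiological beat-to-beat
#' variability without moving the subject-level mean.
#'
#' @param truth ECG ground-truth data.frame from [generate_ecg()].
#' @param s2_split_ms nominal (end-expiration) A2--P2 interval, ms (>= 0).
#' @param emat_ms electromechanical activation time, Q onset to first S1 peak,
#'   ms (> 0).
#' @param s1s2_ms S1-peak to A2-peak interval, ms.
#' @param resp_mod_ms amplitude of the sinusoidal respiratory modulation of the
#'   split, ms (0 emulates the fixed splitting of ASD).
#' @param resp_period_s respiratory period in seconds.
#' @param resp_phase optional function `t_ms -> radians` overriding the default
#'   free-running sinusoidal phase (used to emulate an end-expiratory hold).
#' @param resp_amp_depth depth of the respiratory amplitude modulation of the
#'   whole PCG (lung-volume proxy used by the respiratory-phase estimator).
#' @param beat_jitter_sd_ms SD of centred per-beat Gaussian jitter applied to
#'   EMAT, S1--S2 and the split (default 0; subjects use 2 ms).
#' @param noise_snr_db white-noise level relative to signal RMS, dB.
#' @param duration_ms recording length; defaults to the ECG duration so both
#'   channels share one clock.
#' @param seed integer seed.
#' @param fs sampling rate in Hz (default 2000).
#' @return list with `signal`, `fs`, `duration_ms`, and `truth`: the input
#'   truth extended with `s1_peak_ms`, `a2_peak_ms`, `p2_peak_ms`,
#'   `resp_phase`, and the true per-beat indices.
#' @export
generate_pcg <- function(truth, s2_split_ms, emat_ms, s1s2_ms,
                         resp_mod_ms = 0, resp_period_s = 4,
                         resp_phase = NULL, resp_amp_depth = 0.15,
                         beat_jitter_sd_ms = 0, noise_snr_db = Inf,
                         duration_ms = NULL, seed = 1L, fs = 2000) {
  if (s2_split_ms < 0) stop("s2_split_ms must be non-negative")
  if (emat_ms <= 0) stop("emat_ms must be positive")
  if (resp_mod_ms < 0) stop("resp_mod_ms must be non-negative")
  if (s2_split_ms > 0 && s2_split_ms < 0.5)
    warning("requested S2 split is below the timing resolution at 2 kHz")
  set.seed(child_seed(seed, 22L))

  nb <- nrow(truth)
  phase_fun <- resp_phase %||%
    function(t_ms) (2 * pi * t_ms / (resp_period_s * 1000)) %% (2 * pi)
  phi <- phase_fun(truth$r_peak_ms)

  jitter <- function() {
    if (beat_jitter_sd_ms <= 0 || nb < 2) return(numeric(nb))
    z <- stats::rnorm(nb, 0, beat_jitter_sd_ms)
    z - mean(z)                      # centred: subject-true mean == target
  }
  emat_b <- emat_ms + jitter()
  s1s2_b <- s1s2_ms + jitter()
  split_b <- pmax(0, s2_split_ms + resp_mod_ms * sin(phi) + jitter())

  s1_peak <- truth$q_onset_ms + emat_b
  a2_peak <- s1_peak + s1s2_b
  p2_peak <- a2_peak + split_b

  duration_ms <- duration_ms %||% (max(truth$r_peak_ms) + 600)
  n <- as.integer(ceiling(duration_ms * fs / 1000))
  t <- idx_to_ms(seq_len(n), fs)
  x <- numeric(n)
  for (k in seq_len(nb)) {
    win <- which(t >= s1_peak[k] - 60 & t <= p2_peak[k] + 40)
    x[win] <- x[win] +
      s1_burst(t[win], s1_peak[k]) +
      s2_click(t[win], a2_peak[k], amp = 1.1) +
      s2_click(t[win], p2_peak[k], amp = 0.85)
  }
  # Respiratory amplitude modulation: sounds scale with lung volume
  # v = (1 + cos(phase)) / 2, which is 0 at end-expiration (phase = pi).
  if (resp_amp_depth > 0)
    x <- x * (1 + resp_amp_depth * (1 + cos(phase_fun(t))) / 2)
  if (is.finite(noise_snr_db))
    x <- x + stats::rnorm(n, sd = rms(x) * 10^(-noise_snr_db / 20))

  out_truth <- truth
  out_truth$s1_peak_ms <- s1_peak
  out_truth$a2_peak_ms <- a2_peak
  out_truth$p2_peak_ms <- p2_peak
  out_truth$resp_phase <- phi
  out_truth$s2_split_true_ms <- split_b
  out_truth$emat_true_ms <- emat_b
  out_truth$s1s2_true_ms <- s1s2_b
  out_truth$s1s2_rr_true_pct <- s1s2_b / truth$rr_ms * 100
  out_truth$emat_rr_true_pct <- emat_b / truth$rr_ms * 100

  list(signal = x, fs = fs, duration_ms = n / fs * 1000, truth = out_truth)
}
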