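# ECG and PCG fiducial detection: R peaks, Q onsets, S1/S2 bursts, A2/P2
# sub-components, and analysis-beat selection.

#' Detect R peaks on a filtered ECG
#'
#' Derivative-energy detection (squared, smoothed first difference) with an
#' adaptive threshold and a 200 ms refractory period; the R time is refined to
#' the signal maximum near each energy peak with parabolic sub-sample
#' interpolation.
#'
#' @param ecg filtered ECG samples.
#' @param fs sampling rate in Hz.
#' @param refractory_ms minimum peak-to-peak distance (default 200).
#' @return numeric vector of R-peak times in ms (empty for flat input).
#' @export
detect_r_peaks <- function(ecg, fs = 500, refractory_ms = 200) {
  n <- length(ecg)
  if (n < 5 || all(abs(ecg) < 1e-12)) return(numeric(0))
  d <- c(0, diff(ecg)) * fs / 1000
  e <- gaussian_smooth(d^2, fs, 10)
  thr <- 0.2 * stats::quantile(e, 0.99)
  if (thr <= 0) return(numeric(0))
  cand <- local_maxima(e)
  cand <- cand[e[cand] > thr]
  if (!length(cand)) return(numeric(0))
  # greedy refractory enforcement, strongest first
  cand <- cand[order(e[cand], decreasing = TRUE)]
  keep <- integer(0)
  ref <- refractory_ms * fs / 1000
  for (i in cand) if (!length(keep) || all(abs(keep - i) >= ref))
    keep <- c(keep, i)
  keep <- sort(keep)
  # refine to the ECG maximum within +/- 50 ms
  half <- as.integer(round(0.05 * fs))
  r_idx <- vapply(keep, function(i) {
    a <- max(1L, i - half); b <- min(n, i + half)
    j <- a - 1L + which.max(ecg[a:b])
    refine_peak(ecg, j)
  }, numeric(1))
  r_idx <- sort(r_idx)
  # dedupe refinements that collapsed onto the same R
  if (length(r_idx) > 1) r_idx <- r_idx[c(TRUE, diff(r_idx) >= ref / 2)]
  idx_to_ms(r_idx, fs)
}

#' Locate Q-wave onsets before detected R peaks
#'
#' Scans a 120 ms window before each R peak on the smoothed ECG derivative and
#' places the onset where the absolute slope first exceeds `slope_frac` of the
#' window's maximum absolute slope (linearly interpolated between samples) --
#' i.e. the last sub-threshold-slope point before the QRS deflection. Beats
#' whose window is truncated by the recording start are returned as `NA`.
#'
#' @param ecg filtered ECG samples.
#' @param fs sampling rate in Hz.
#' @param r_peaks_ms R-peak times from [detect_r_peaks()].
#' @param search_ms pre-R window length (default 120).
#' @param slope_frac onset threshold as a fraction of the peak slope.
#' @return numeric vector of Q-onset times in ms (NA where undetectable).
#' @export
detect_q_onset <- function(ecg, fs = 500, r_peaks_ms, search_ms = 120,
                           slope_frac = 0.06) {
  if (!length(r_peaks_ms)) return(numeric(0))
  d <- gaussian_smooth(c(0, diff(ecg)) * fs / 1000, fs, 4)
  sus <- as.integer(round(0.008 * fs))   # slope must persist ~8 ms
  vapply(r_peaks_ms, function(r) {
    a <- ms_to_idx(r - search_ms, fs)
    b <- ms_to_idx(r - 10, fs)
    if (a < 1) return(NA_real_)
    ia <- as.integer(ceiling(a)); ib <- as.integer(floor(b))
    if (ib - ia < 4) return(NA_real_)
    w <- abs(d[ia:ib])
    # threshold: fraction of the QRS slope, floored above the baseline noise
    # slope (estimated from the first 40 ms of the window)
    base <- w[seq_len(min(length(w), as.integer(0.04 * fs)))]
    thr <- max(slope_frac * max(w),
               stats::median(base) + 3 * stats::mad(base))
    nw <- length(w)
    sustained <- vapply(seq_len(nw), function(j) {
      jj <- j:min(nw, j + sus)
      w[j] >= thr && mean(w[jj] >= thr) >= 0.7
    }, logical(1))
    j <- which(sustained)[1]
    if (is.na(j)) return(NA_real_)
    if (j == 1) return(idx_to_ms(ia, fs))
    frac <- (thr - w[j - 1]) / max(w[j] - w[j - 1], 1e-12)
    frac <- min(1, max(0, frac))
    idx_to_ms(ia + (j - 2) + frac, fs)
  }, numeric(1))
}

#' Smoothed energy envelope of a filtered PCG
#'
#' Shannon-energy-style envelope: the square of the signal smoothed with a
#' Gaussian kernel, square-rooted back to amplitude units. Local maxima align
#' with burst centres.
#'
#' @param pcg filtered PCG samples.
#' @param fs sampling rate in Hz.
#' @param smooth_ms kernel SD in ms (default 8, the coarse S1/S2 scale).
#' @return non-negative envelope, same length as `pcg`.
#' @export
pcg_envelope <- function(pcg, fs = 2000, smooth_ms = 8) {
  sqrt(pmax(0, gaussian_smooth(pcg^2, fs, smooth_ms)))
}

# onset = last crossing of 10% of the peak height, scanning back from the
# peak; the threshold rides on the local envelope baseline so a broadband
# noise floor cannot drag the onset to the window edge
envelope_onset <- function(env, fs, peak_idx, height, floor_idx,
                           frac = 0.10) {
  baseline <- stats::median(env[floor_idx:as.integer(round(peak_idx))])
  thr <- baseline + frac * (height - baseline)
  i <- as.integer(round(peak_idx))
  while (i > floor_idx && env[i] > thr) i <- i - 1L
  if (env[i] > thr) return(idx_to_ms(i, fs))
  frac_i <- (thr - env[i]) / max(env[i + 1] - env[i], 1e-12)
  idx_to_ms(i + frac_i, fs)
}

#' Segment S1 and S2 bursts beat by beat
#'
#' Within each cardiac cycle the S1 peak is the dominant envelope maximum in
#' \[R, R+200 ms\] and the S2 peak the dominant maximum in
#' \[R+200 ms, R+0.6 RR\]; onsets are placed at the 10%-of-peak-height
#' crossing. Beats lacking either sound (peak below 25% of the recording
#' median for that sound) are flagged invalid rather than raising an error.
#'
#' @param env coarse PCG envelope from [pcg_envelope()].
#' @param fs PCG sampling rate in Hz.
#' @param r_peaks_ms R-peak times in ms.
#' @param rr_ms per-beat RR in ms; defaults to `diff(r_peaks_ms)` with the
#'   median recycled for the last beat.
#' @return data.frame per beat: `r_peak_ms`, `s1_onset_ms`, `s1_peak_ms`,
#'   `s2_onset_ms`, `s2_peak_ms`, `s1_height`, `s2_height`, `valid`.
#' @export
segment_s1_s2 <- function(env, fs = 2000, r_peaks_ms, rr_ms = NULL) {
  nb <- length(r_peaks_ms)
  stopifnot(nb >= 1)
  if (is.null(rr_ms)) {
    rr_ms <- if (nb > 1) c(diff(r_peaks_ms), stats::median(diff(r_peaks_ms)))
             else 750
  }
  n <- length(env)
  out <- data.frame(r_peak_ms = r_peaks_ms, s1_onset_ms = NA_real_,
                    s1_peak_ms = NA_real_, s2_onset_ms = NA_real_,
                    s2_peak_ms = NA_real_, s1_height = NA_real_,
                    s2_height = NA_real_, valid = FALSE)
  window_peak <- function(lo_ms, hi_ms) {
    a <- max(1L, as.integer(ceiling(ms_to_idx(lo_ms, fs))))
    b <- min(n, as.integer(floor(ms_to_idx(hi_ms, fs))))
    if (b - a < 10) return(NULL)
    j <- a - 1L + which.max(env[a:b])
    list(idx = refine_peak(env, j), height = env[j], floor = a)
  }
  for (k in seq_len(nb)) {
    r <- r_peaks_ms[k]
    p1 <- window_peak(r, r + 200)
    p2 <- window_peak(r + 200, r + 0.6 * rr_ms[k])
    if (is.null(p1) || is.null(p2)) next
    out$s1_peak_ms[k] <- idx_to_ms(p1$idx, fs)
    out$s2_peak_ms[k] <- idx_to_ms(p2$idx, fs)
    out$s1_height[k] <- p1$height
    out$s2_height[k] <- p2$height
    out$s1_onset_ms[k] <- envelope_onset(env, fs, p1$idx, p1$height, p1$floor)
    out$s2_onset_ms[k] <- envelope_onset(env, fs, p2$idx, p2$height, p2$floor)
  }
  med1 <- stats::median(out$s1_height, na.rm = TRUE)
  med2 <- stats::median(out$s2_height, na.rm = TRUE)
  out$valid <- !is.na(out$s1_peak_ms) & !is.na(out$s2_peak_ms) &
    out$s1_height > 0.25 * med1 & out$s2_height > 0.25 * med2
  out
}

#' Split the second heart sound into its A2 and P2 components
#'
#' Computes a fine-scale sub-envelope over the S2 window (onset - 20 ms to
#' onset + 120 ms), finds its resolvable local maxima (above `rel_height` of
#' the window maximum, maxima closer than 2 ms merged), and returns the first
#' of the two dominant peaks as A2 and the second as P2. A single resolvable
#' peak yields a zero split with coincident fiducials. Peak times use
#' parabolic sub-sample refinement.
#'
#' @param pcg filtered PCG samples.
#' @param fs sampling rate in Hz.
#' @param s2_onset_ms S2 onset time anchoring the window, ms.
#' @param window_ms window relative to the onset (default c(-20, 120)).
#' @param smooth_ms fine sub-envelope kernel SD (default 1.2 ms).
#' @param rel_height minimum relative height of a resolvable component.
#' @return list with `a2_peak_ms`, `p2_peak_ms`, `split_ms`.
#' @export
split_s2 <- function(pcg, fs = 2000, s2_onset_ms,
                     window_ms = c(-20, 120), smooth_ms = 1.2,
                     rel_height = 0.35) {
  a <- max(1L, as.integer(ceiling(ms_to_idx(s2_onset_ms + window_ms[1], fs))))
  b <- min(length(pcg),
           as.integer(floor(ms_to_idx(s2_onset_ms + window_ms[2], fs))))
  if (b <= a) stop("empty S2 window")
  seg <- pcg[a:b]
  # restrict to the S2 click band before envelope extraction so broadband
  # noise outside it cannot mask the two components
  if (length(seg) > 30) {
    bp <- signal::butter(3, c(60, 400) / (fs / 2), type = "pass")
    seg <- signal::filtfilt(bp, seg)
  }
  fenv <- sqrt(pmax(0, gaussian_smooth(seg^2, fs, smooth_ms)))
  m <- local_maxima(fenv)
  if (!length(m)) m <- which.max(fenv)
  m <- m[fenv[m] >= rel_height * max(fenv)]
  if (length(m) > 1) {                       # merge maxima closer than 2 ms
    m <- m[order(m)]
    min_sep <- 2 * fs / 1000
    kept <- m[1]
    for (i in m[-1]) {
      if (i - kept[length(kept)] < min_sep) {
        if (fenv[i] > fenv[kept[length(kept)]]) kept[length(kept)] <- i
      } else kept <- c(kept, i)
    }
    m <- kept
  }
  if (length(m) >= 2) {
    top2 <- m[order(fenv[m], decreasing = TRUE)][1:2]
    top2 <- sort(top2)
    a2 <- idx_to_ms(a - 1 + refine_peak(fenv, top2[1]), fs)
    p2 <- idx_to_ms(a - 1 + refine_peak(fenv, top2[2]), fs)
  } else {
    a2 <- p2 <- idx_to_ms(a - 1 + refine_peak(fenv, m[1]), fs)
  }
  list(a2_peak_ms = a2, p2_peak_ms = p2, split_ms = p2 - a2)
}

#' Select the analysis run of beats
#'
#' Returns the earliest run of `n_required` consecutive beats that are valid,
#' artifact-free and end-expiration-flagged. If no such run exists the longest
#' qualifying run is returned with a warning; zero qualifying beats is an
#' error (subject excluded).
#'
#' @param qualifying logical vector, one entry per beat (valid AND
#'   artifact-free AND gated).
#' @param n_required run length sought (default 30).
#' @return integer vector of selected beat indices.
#' @export
select_beats <- function(qualifying, n_required = 30) {
  if (!any(qualifying)) stop("no qualifying beats; subject excluded")
  r <- rle(qualifying)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  full <- ok[r$lengths[ok] >= n_required]
  if (length(full)) {
    s <- starts[full[1]]
    return(seq.int(s, s + n_required - 1L))
  }
  best <- ok[which.max(r$lengths[ok])]
  warning("no run of ", n_required, " consecutive qualifying beats; ",
          "returning the longest run (", r$lengths[best], " beats)")
  seq.int(starts[best], ends[best])
}
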