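# Fiducial detection against generator ground truth.

test_that("R peaks are recovered within 4 ms on clean recordings", {
  rec <- make_clean_recording(seed = 1)
  r <- detect_r_peaks(bandpass_ecg(rec$ecg$signal), 500)
  expect_length(r, 30)
  expect_lt(max(abs(r - rec$ecg$truth$r_peak_ms)), 4)
})

test_that("flat input yields no R peaks", {
  expect_length(detect_r_peaks(numeric(5000), 500), 0)
  expect_length(detect_r_peaks(rep(0.3, 5000), 500), 0)
})

test_that("R detection keeps sensitivity and precision >= 0.95 at 10 dB", {
  sens <- prec <- numeric(20)
  for (s in 1:20) {
    e <- generate_ecg(86, 30, rr_jitter = 0.03, noise_snr_db = 10, seed = s)
    r <- detect_r_peaks(bandpass_ecg(e$signal), 500)
    tp <- sum(vapply(e$truth$r_peak_ms,
                     function(x) any(abs(r - x) < 50), logical(1)))
    sens[s] <- tp / nrow(e$truth)
    prec[s] <- if (length(r)) tp / length(r) else 0
  }
  expect_gte(mean(sens), 0.95)
  expect_gte(mean(prec), 0.95)
})

test_that("Q onsets are found within 4 ms on clean recordings", {
  rec <- make_clean_recording(seed = 2)
  ef <- bandpass_ecg(rec$ecg$signal)
  r <- detect_r_peaks(ef, 500)
  q <- detect_q_onset(ef, 500, r)
  expect_lt(max(abs(q - rec$ecg$truth$q_onset_ms)), 4)
  expect_length(detect_q_onset(ef, 500, numeric(0)), 0)
})

test_that("Q onset median error stays within 8 ms at 10 dB", {
  errs <- c()
  for (s in 1:20) {
    e <- generate_ecg(86, 30, rr_jitter = 0.03, noise_snr_db = 10, seed = s)
    ef <- bandpass_ecg(e$signal)
    r <- detect_r_peaks(ef, 500)
    q <- detect_q_onset(ef, 500, r)
    m <- vapply(r, function(x) which.min(abs(e$truth$r_peak_ms - x)),
                integer(1))
    errs <- c(errs, abs(q - e$truth$q_onset_ms[m]))
  }
  expect_lte(stats::median(errs, na.rm = TRUE), 8)
})

test_that("the envelope peaks align with burst centres", {
  fs <- 2000
  t <- idx_to_ms(seq_len(2 * fs), fs)
  x1 <- exp(-((t - 500)^2) / (2 * 8^2)) * cos(2 * pi * 0.08 * (t - 500))
  env <- pcg_envelope(x1, fs)
  expect_lt(abs(idx_to_ms(which.max(env), fs) - 500), 2)

  x2 <- x1 + exp(-((t - 540)^2) / (2 * 8^2)) * cos(2 * pi * 0.08 * (t - 540))
  env2 <- pcg_envelope(x2, fs)
  m <- local_maxima(env2)
  m <- m[env2[m] > 0.5 * max(env2)]
  expect_length(m, 2)
  expect_lt(abs(diff(idx_to_ms(m, fs)) - 40), 2)

  expect_true(all(pcg_envelope(numeric(1000), fs) == 0))
})

test_that("S1/S2 segmentation recovers burst peaks within 2 ms", {
  rec <- make_clean_recording(seed = 3)
  pf <- bandpass_pcg(rec$pcg$signal)
  seg <- segment_s1_s2(pcg_envelope(pf), 2000, rec$ecg$truth$r_peak_ms,
                       rec$ecg$truth$rr_ms)
  expect_true(all(seg$valid))
  expect_lt(max(abs(seg$s1_peak_ms - rec$pcg$truth$s1_peak_ms)), 2)
  # the coarse S2 peak merges A2+P2; it must land between them
  expect_true(all(seg$s2_peak_ms > rec$pcg$truth$a2_peak_ms - 2 &
                  seg$s2_peak_ms < rec$pcg$truth$p2_peak_ms + 2))
  # onsets precede peaks
  expect_true(all(seg$s1_onset_ms < seg$s1_peak_ms))
  expect_true(all(seg$s2_onset_ms < seg$s2_peak_ms))
})

test_that("a beat with a suppressed S2 is flagged invalid, others kept", {
  rec <- make_clean_recording(seed = 4)
  pcg <- rec$pcg$signal
  tr <- rec$pcg$truth
  k <- 10
  idx <- seq(ms_to_idx(tr$a2_peak_ms[k] - 25, 2000),
             ms_to_idx(tr$p2_peak_ms[k] + 25, 2000))
  pcg[idx] <- 0
  seg <- segment_s1_s2(pcg_envelope(bandpass_pcg(pcg)), 2000,
                       rec$ecg$truth$r_peak_ms, rec$ecg$truth$rr_ms)
  expect_false(seg$valid[k])
  expect_true(all(seg$valid[-k]))
})

test_that("segmentation stays reliable at 15 dB SNR", {
  n_valid <- 0; n_total <- 0; errs <- c()
  for (s in 1:10) {
    rec <- make_clean_recording(seed = s, snr = 15, n_beats = 50)
    pf <- bandpass_pcg(rec$pcg$signal)
    seg <- segment_s1_s2(pcg_envelope(pf), 2000, rec$ecg$truth$r_peak_ms,
                         rec$ecg$truth$rr_ms)
    n_valid <- n_valid + sum(seg$valid); n_total <- n_total + nrow(seg)
    ok <- which(seg$valid)
    errs <- c(errs, abs(seg$s1_peak_ms[ok] - rec$pcg$truth$s1_peak_ms[ok]))
  }
  expect_gte(n_valid / n_total, 0.95)
  expect_lte(stats::quantile(errs, 0.95), 4)
})

test_that("S2 splitting is recovered within 2 ms, including the zero split", {
  rec <- make_clean_recording(seed = 5, split = 39.65)
  pf <- bandpass_pcg(rec$pcg$signal)
  seg <- segment_s1_s2(pcg_envelope(pf), 2000, rec$ecg$truth$r_peak_ms,
                       rec$ecg$truth$rr_ms)
  est <- vapply(seq_len(nrow(seg)), function(k)
    split_s2(pf, 2000, seg$s2_onset_ms[k])$split_ms, numeric(1))
  expect_lt(max(abs(est - rec$pcg$truth$s2_split_true_ms)), 2)

  rec0 <- make_clean_recording(seed = 6, split = 0)
  pf0 <- bandpass_pcg(rec0$pcg$signal)
  seg0 <- segment_s1_s2(pcg_envelope(pf0), 2000, rec0$ecg$truth$r_peak_ms,
                        rec0$ecg$truth$rr_ms)
  sp0 <- split_s2(pf0, 2000, seg0$s2_onset_ms[1])
  expect_lt(abs(sp0$split_ms), 2)
  expect_equal(sp0$a2_peak_ms, sp0$p2_peak_ms)
  expect_error(split_s2(pf0, 2000, -500), "empty")
})

test_that("the split estimator is linear over 5-60 ms", {
  rec <- make_clean_recording(seed = 7)
  true_s <- seq(5, 60, by = 5)
  est <- vapply(true_s, function(s) {
    p <- generate_pcg(rec$ecg$truth, s2_split_ms = s, emat_ms = 96.2,
                      s1s2_ms = 238.5, noise_snr_db = 30, seed = 7,
                      duration_ms = rec$ecg$duration_ms)
    pf <- bandpass_pcg(p$signal)
    seg <- segment_s1_s2(pcg_envelope(pf), 2000, rec$ecg$truth$r_peak_ms,
                         rec$ecg$truth$rr_ms)
    mean(vapply(seq_len(nrow(seg)), function(k)
      split_s2(pf, 2000, seg$s2_onset_ms[k])$split_ms, numeric(1)))
  }, numeric(1))
  fit <- stats::lm(est ~ true_s)
  expect_gt(stats::coef(fit)[2], 0.9)
  expect_lt(stats::coef(fit)[2], 1.1)
  expect_lt(abs(stats::coef(fit)[1]), 2)
})

test_that("the split is invariant to translating the recording", {
  rec <- make_clean_recording(seed = 8)
  pf <- bandpass_pcg(rec$pcg$signal)
  seg <- segment_s1_s2(pcg_envelope(pf), 2000, rec$ecg$truth$r_peak_ms,
                       rec$ecg$truth$rr_ms)
  s0 <- split_s2(pf, 2000, seg$s2_onset_ms[3])
  shift_ms <- 250                       # exact multiple of the sample period
  pf_shift <- c(numeric(shift_ms * 2), pf)
  s1 <- split_s2(pf_shift, 2000, seg$s2_onset_ms[3] + shift_ms)
  expect_equal(s1$split_ms, s0$split_ms, tolerance = 1e-9)
})

test_that("split error degrades monotonically as SNR falls", {
  snrs <- c(30, 20, 15, 10)
  mean_err <- vapply(snrs, function(snr) {
    errs <- c()
    for (s in 1:20) {
      rec <- make_clean_recording(seed = s, snr = snr)
      pf <- bandpass_pcg(rec$pcg$signal)
      seg <- segment_s1_s2(pcg_envelope(pf), 2000, rec$ecg$truth$r_peak_ms,
                           rec$ecg$truth$rr_ms)
      ok <- which(seg$valid)
      est <- vapply(ok, function(k)
        split_s2(pf, 2000, seg$s2_onset_ms[k])$split_ms, numeric(1))
      errs <- c(errs, abs(est - rec$pcg$truth$s2_split_true_ms[ok]))
    }
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) > -0.1))
})

test_that("select_beats applies the earliest-run rule with fallback", {
  expect_equal(select_beats(rep(TRUE, 60), 30), 1:30)
  q <- rep(TRUE, 60); q[5:8] <- FALSE
  expect_equal(select_beats(q, 30), 9:38)
  q2 <- c(rep(TRUE, 12), rep(FALSE, 48))
  expect_warning(sel <- select_beats(q2, 30), "longest run")
  expect_equal(sel, 1:12)
  expect_error(select_beats(rep(FALSE, 10), 30), "excluded")
})
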