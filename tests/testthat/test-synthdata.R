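# Waveform and cohort generators: timing contracts, determinism, and
# convergence of the index-level cohort to its specification.

test_that("ECG generator honours the RR contract", {
  e <- generate_ecg(86, 30, rr_jitter = 0, seed = 1)
  expect_equal(nrow(e$truth), 30)
  expect_true(all(abs(diff(e$truth$r_peak_ms) - 60000 / 86) < 1e-9))

  e1 <- generate_ecg(60, 1, rr_jitter = 0, seed = 0)
  expect_equal(e1$truth$rr_ms, 1000)

  e2 <- generate_ecg(86, 200, rr_jitter = 0.05, seed = 7)
  cv <- stats::sd(e2$truth$rr_ms) / mean(e2$truth$rr_ms)
  expect_gt(cv, 0.03)
  expect_lt(cv, 0.07)
  expect_lt(abs(mean(e2$truth$rr_ms) - 60000 / 86) / (60000 / 86), 0.01)

  expect_error(generate_ecg(-5, 30), "heart_rate_bpm")
  expect_error(generate_ecg(86, 0), "n_beats")
})

test_that("ECG truth fiducials are ordered and increasing", {
  e <- generate_ecg(120, 50, rr_jitter = 0.05, seed = 3)
  expect_true(all(e$truth$q_onset_ms < e$truth$r_peak_ms))
  expect_true(all(diff(e$truth$r_peak_ms) > 0))
})

test_that("PCG generator inverts the index definitions exactly", {
  e <- generate_ecg(86, 20, seed = 2)
  p <- generate_pcg(e$truth, s2_split_ms = 39.65, emat_ms = 96.2,
                    s1s2_ms = 238.5, resp_mod_ms = 0, seed = 2)
  tr <- p$truth
  expect_equal(tr$p2_peak_ms - tr$a2_peak_ms, rep(39.65, 20))
  expect_equal(tr$s1_peak_ms - tr$q_onset_ms, rep(96.2, 20))
  expect_equal(tr$a2_peak_ms - tr$s1_peak_ms, rep(238.5, 20))
  expect_true(all(tr$q_onset_ms < tr$r_peak_ms &
                  tr$r_peak_ms < tr$s1_peak_ms &
                  tr$s1_peak_ms < tr$a2_peak_ms &
                  tr$a2_peak_ms <= tr$p2_peak_ms))
})

test_that("zero split collapses A2 and P2; tiny split warns", {
  e <- generate_ecg(86, 5, seed = 2)
  p0 <- generate_pcg(e$truth, s2_split_ms = 0, emat_ms = 96.2, s1s2_ms = 238.5)
  expect_equal(p0$truth$a2_peak_ms, p0$truth$p2_peak_ms)
  expect_warning(
    generate_pcg(e$truth, s2_split_ms = 0.2, emat_ms = 96.2, s1s2_ms = 238.5),
    "resolution")
  expect_error(generate_pcg(e$truth, s2_split_ms = -1, emat_ms = 96.2,
                            s1s2_ms = 238.5), "non-negative")
  expect_error(generate_pcg(e$truth, s2_split_ms = 10, emat_ms = 0,
                            s1s2_ms = 238.5), "positive")
})

test_that("respiratory modulation spans the stated sinusoidal range", {
  e <- generate_ecg(86, 120, rr_jitter = 0.02, seed = 4)
  p <- generate_pcg(e$truth, s2_split_ms = 28.20, emat_ms = 96.2,
                    s1s2_ms = 238.5, resp_mod_ms = 10, resp_period_s = 4,
                    seed = 4)
  sp <- p$truth$s2_split_true_ms
  expect_gte(min(sp), 18.20)
  expect_lte(max(sp), 38.20)
  # beats sample the 4-s cycle densely over ~85 s, so the extremes are reached
  expect_lt(min(sp), 18.7)
  expect_gt(max(sp), 37.7)
})

test_that("subject generator is deterministic and honours its targets", {
  r1 <- generate_subject("ASD", targets = list(s2_split_ms = 39.65),
                         artifact_rate = 0, seed = 3)
  r2 <- generate_subject("ASD", targets = list(s2_split_ms = 39.65),
                         artifact_rate = 0, seed = 3)
  expect_identical(r1$pcg$signal, r2$pcg$signal)
  expect_identical(r1$ecg$signal, r2$ecg$signal)
  expect_identical(r1$truth, r2$truth)
  # centred jitter: mean true end-expiration split equals the target
  hold <- abs(r1$truth$resp_phase - pi) < 1e-9
  expect_lt(abs(mean(r1$truth$s2_split_true_ms) - 39.65), 0.2)
  expect_gte(sum(hold), 30)
  expect_gte(r1$duration_ms, 60000)
})

test_that("injected artifacts are logged and contained in the recording", {
  r <- generate_subject("control", artifact_rate = 0.5, seed = 4)
  expect_true(all(r$artifacts$start_ms >= 0))
  expect_true(all(r$artifacts$end_ms <= r$duration_ms))
  if (nrow(r$artifacts) > 1)
    expect_true(all(diff(r$artifacts$start_ms) > 1000))
})

test_that("cohort tables have the published two-group structure", {
  tab <- generate_cohort_indices(asd_cohort_spec(n_per_group = 50), seed = 11)
  expect_equal(nrow(tab), 100)
  expect_setequal(unique(tab$group), c("control", "ASD"))
  expect_true(all(c("s2_split_ms", "s1s2_ms", "s1s2_rr_pct", "emat_ms",
                    "emat_rr_pct") %in% names(tab)))
  expect_true(all(is.na(tab$asd_size_mm[tab$group == "control"])))
  expect_true(all(!is.na(tab$asd_size_mm[tab$group == "ASD"])))
})

test_that("degenerate zero-SD spec yields constant indices", {
  spec <- asd_cohort_spec(n_per_group = 10)
  spec$groups$control$indices$sd[] <- 0
  tab <- generate_cohort_indices(spec, seed = 5)
  ctrl <- tab[tab$group == "control", ]
  expect_equal(unname(stats::sd(ctrl$s2_split_ms)), 0)
  expect_equal(ctrl$s2_split_ms[1], 28.20)
})

test_that("cohort sample moments converge to the specification", {
  spec <- asd_cohort_spec(n_per_group = 100000)
  tab <- generate_cohort_indices(spec, seed = 21)
  for (g in c("control", "ASD")) {
    sub <- tab[tab$group == g, ]
    ref <- spec$groups[[g]]$indices
    for (i in seq_len(nrow(ref))) {
      v <- sub[[ref$variable[i]]]
      expect_lt(abs(mean(v) - ref$mean[i]) / ref$mean[i], 0.01)
      expect_lt(abs(stats::sd(v) - ref$sd[i]) / ref$sd[i], 0.02)
    }
  }
})

test_that("requested covariate correlation is recovered at large n", {
  spec <- asd_cohort_spec(n_per_group = 5000)
  tab <- generate_cohort_indices(spec, seed = 9)
  asd <- tab[tab$group == "ASD", ]
  r <- stats::cor(asd$s2_split_ms, asd$asd_size_mm)
  expect_gt(r, 0.69)
  expect_lt(r, 0.75)
  r2 <- stats::cor(asd$rvedvi_ml_m2, asd$s2_split_ms)
  expect_gt(r2, 0.73)
  expect_lt(r2, 0.79)
})

test_that("infeasible correlation requests are rejected", {
  spec <- asd_cohort_spec(n_per_group = 10)
  spec$covariates$asd_size_mm$r <- c(s2_split_ms = 0.99)
  expect_error(generate_cohort_indices(spec, seed = 1), NA) # |r|<1 feasible
  spec$covariates$asd_size_mm$r <- c(s2_split_ms = 1.0)
  expect_error(generate_cohort_indices(spec, seed = 1), "correlation")
  spec$covariates$asd_size_mm$r <- c(s2_split_ms = 0.9, s1s2_rr_pct = 0.9)
  expect_error(generate_cohort_indices(spec, seed = 1), "infeasible")
})
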