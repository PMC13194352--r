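# Subject- and cohort-level synthesis: index tables with the published group
# structure, and full two-channel recordings composed from the waveform
# generators.

#' Cohort specification with the published group structure
#'
#' Returns the default cohort specification: 50 subjects per group, per-group
#' means and SDs for the five acoustic-electrocardiographic indices and the
#' demographic variables, plus index--covariate correlations (ASD size and
#' RVEDVI) for the ASD group.
#'
#' The two discriminative indices (S2 splitting and S1--S2/RR) share a latent
#' right-ventricular-overload component (`index_rho`, default 0.5): without it
#' the four stated covariate correlations are jointly infeasible, and both
#' indices are physiologically driven by the same shunt volume.
#'
#' @param n_per_group subjects per group (>= 1; group statistics need >= 2).
#' @param index_rho correlation between standardized S2 splitting and
#'   S1--S2/RR within each group.
#' @return a list of class `cohort_spec`.
#' @export
asd_cohort_spec <- function(n_per_group = 50, index_rho = 0.5) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (abs(index_rho) >= 1) stop("|index_rho| must be < 1")
  idx <- function(split, s1s2, s1s2_rr, emat, emat_rr)
    data.frame(variable = c("s2_split_ms", "s1s2_ms", "s1s2_rr_pct",
                            "emat_ms", "emat_rr_pct"),
               mean = c(split[1], s1s2[1], s1s2_rr[1], emat[1], emat_rr[1]),
               sd = c(split[2], s1s2[2], s1s2_rr[2], emat[2], emat_rr[2]))
  demo <- function(age, height, weight, bmi, hr, sbp, dbp, male_n)
    list(age_yr = age, height_cm = height, weight_kg = weight, bmi = bmi,
         hr_bpm = hr, sbp_mmhg = sbp, dbp_mmhg = dbp, male_frac = male_n / 50)
  spec <- list(
    n_per_group = as.integer(n_per_group),
    index_rho = index_rho,
    groups = list(
      control = list(
        indices = idx(c(28.20, 8.91), c(243.54, 26.25), c(34.47, 2.99),
                      c(95.16, 3.58), c(15.44, 3.38)),
        demographics = demo(c(8.1, 2.5), c(135.6, 8.3), c(31.3, 4.1),
                            c(17.00, 0.20), c(86, 6.0), c(103.1, 6.3),
                            c(64.3, 6.0), 28)),
      ASD = list(
        indices = idx(c(39.65, 8.37), c(238.50, 29.72), c(37.53, 2.39),
                      c(96.20, 4.34), c(15.33, 2.81)),
        demographics = demo(c(8.0, 2.5), c(135.4, 8.2), c(31.1, 4.0),
                            c(16.89, 0.17), c(87, 6.0), c(102.8, 7.8),
                            c(64.4, 5.3), 27))),
    # covariates exist only where the defect exists; r targets are exact
    covariates = list(
      asd_size_mm = list(mean = 12, sd = 4, group = "ASD",
                         r = c(s2_split_ms = 0.72, s1s2_rr_pct = 0.65)),
      rvedvi_ml_m2 = list(mean = 85, sd = 15, group = "ASD",
                          r = c(s2_split_ms = 0.76, s1s2_rr_pct = 0.69))))
  class(spec) <- "cohort_spec"
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_per_group < 1) stop("n_per_group must be >= 1")
  for (g in spec$groups)
    if (any(g$indices$sd < 0)) stop("index SDs must be non-negative")
  for (cv in spec$covariates)
    if (any(abs(cv$r) >= 1)) stop("covariate correlations must satisfy |r| < 1")
  invisible(spec)
}

#' Draw a subject-level index cohort from a specification
#'
#' Indices are drawn as per-group normals with the specified means and SDs;
#' S2 splitting and S1--S2/RR share the spec's latent correlation, the rest
#' are independent. Covariates are built from the standardized indices so the
#' requested Pearson correlations hold exactly in expectation; a request whose
#' implied residual variance is negative is rejected as infeasible.
#'
#' @param spec a `cohort_spec`, e.g. [asd_cohort_spec()].
#' @param seed integer seed.
#' @return data.frame: one row per subject with `subject_id`, `group`,
#'   demographics, the five indices, and covariate columns (NA outside their
#'   group).
#' @export
generate_cohort_indices <- function(spec = asd_cohort_spec(), seed = 1L) {
  validate_cohort_spec(spec)
  set.seed(child_seed(seed, 33L))
  n <- spec$n_per_group
  rho <- spec$index_rho
  rows <- lapply(names(spec$groups), function(gname) {
    g <- spec$groups[[gname]]
    z <- matrix(stats::rnorm(n * 5), n, 5)
    colnames(z) <- g$indices$variable
    z[, "s1s2_rr_pct"] <- rho * z[, "s2_split_ms"] +
      sqrt(1 - rho^2) * z[, "s1s2_rr_pct"]
    vals <- sweep(sweep(z, 2, g$indices$sd, "*"), 2, g$indices$mean, "+")
    d <- g$demographics
    out <- data.frame(
      subject_id = paste0(gname, "_", seq_len(n)), group = gname,
      age_yr = stats::rnorm(n, d$age_yr[1], d$age_yr[2]),
      sex = ifelse(stats::rbinom(n, 1, d$male_frac) == 1, "M", "F"),
      height_cm = stats::rnorm(n, d$height_cm[1], d$height_cm[2]),
      weight_kg = stats::rnorm(n, d$weight_kg[1], d$weight_kg[2]),
      bmi = stats::rnorm(n, d$bmi[1], d$bmi[2]),
      hr_bpm = stats::rnorm(n, d$hr_bpm[1], d$hr_bpm[2]),
      sbp_mmhg = stats::rnorm(n, d$sbp_mmhg[1], d$sbp_mmhg[2]),
      dbp_mmhg = stats::rnorm(n, d$dbp_mmhg[1], d$dbp_mmhg[2]))
    out <- cbind(out, as.data.frame(vals))
    for (cvn in names(spec$covariates)) {
      cv <- spec$covariates[[cvn]]
      if (!identical(cv$group, gname)) { out[[cvn]] <- NA_real_; next }
      r <- cv$r
      zz <- z[, names(r), drop = FALSE]
      # correlation matrix of the referenced standardized indices
      R <- diag(length(r))
      nm <- names(r)
      if (all(c("s2_split_ms", "s1s2_rr_pct") %in% nm)) {
        i <- match("s2_split_ms", nm); j <- match("s1s2_rr_pct", nm)
        R[i, j] <- R[j, i] <- rho
      }
      a <- solve(R, r)
      resid <- 1 - sum(a * r)
      if (resid < 0)
        stop("infeasible covariate correlation request for ", cvn)
      zc <- as.numeric(zz %*% a) + sqrt(resid) * stats::rnorm(n)
      out[[cvn]] <- cv$mean + cv$sd * zc
    }
    out
  })
  do.call(rbind, rows)
}

#' Generate one synthetic subject: synchronized ECG + PCG with ground truth
#'
#' Composes [generate_ecg()] and [generate_pcg()] into a >= 60 s two-channel
#' recording. The acquisition protocol is emulated with an end-expiratory
#' breath-hold segment (respiratory phase held at pi) long enough to contain
#' 30 consecutive gated beats; outside the hold the respiratory phase runs
#' freely. ASD subjects get near-zero respiratory split modulation (fixed
#' splitting), controls a nonzero one. Transient artifacts (1-s broadband
#' bursts at 5x the signal amplitude scale) are injected at `artifact_rate`
#' per minute and logged in the ground truth. If fewer than 30 clean gated
#' consecutive beats remain, generation is retried once with a longer
#' recording, then fails.
#'
#' @param group "ASD" or "control".
#' @param targets named list of index targets; any of `s2_split_ms`,
#'   `emat_ms`, `s1s2_ms`, `heart_rate_bpm`, `resp_mod_ms` (defaults are the
#'   published group means).
#' @param artifact_rate expected artifacts per minute (default 0).
#' @param seed integer seed.
#' @param duration_s nominal recording length in seconds (>= 60).
#' @param pcg_snr_db,ecg_snr_db channel noise levels in dB.
#' @param beat_jitter_sd_ms within-subject beat-to-beat index variability
#'   (default 2 ms; the study reports none, so this is a free parameter).
#' @param demographics optional named list stored with the subject.
#' @return list of class `sync_recording`: `ecg`, `pcg` (each
#'   `list(signal, fs)`), `truth` (per-beat fiducials, true indices,
#'   respiratory phase), `artifacts` (data.frame of start/end ms), `group`,
#'   `resp_phase_fun`, `demographics`, `duration_ms`.
#' @export
generate_subject <- function(group = c("ASD", "control"), targets = list(),
                             artifact_rate = 0, seed = 1L, duration_s = 70,
                             pcg_snr_db = 30, ecg_snr_db = 25,
                             beat_jitter_sd_ms = 2, demographics = NULL) {
  group <- match.arg(group)
  if (duration_s < 60) stop("duration_s must be >= 60")
  def <- if (group == "ASD")
    list(s2_split_ms = 39.65, emat_ms = 96.20, s1s2_ms = 238.50,
         heart_rate_bpm = 87, resp_mod_ms = 0.5)
  else
    list(s2_split_ms = 28.20, emat_ms = 95.16, s1s2_ms = 243.54,
         heart_rate_bpm = 86, resp_mod_ms = 10)
  tg <- utils::modifyList(def, targets)

  build <- function(dur_s, attempt) {
    hold <- c(20, min(48 + (attempt - 1) * 30, dur_s - 10)) * 1000
    resp_period_s <- 4
    phase_fun <- function(t_ms) {
      ph <- (2 * pi * t_ms / (resp_period_s * 1000)) %% (2 * pi)
      ph[t_ms >= hold[1] & t_ms <= hold[2]] <- pi
      ph
    }
    nb <- as.integer(ceiling(dur_s * tg$heart_rate_bpm / 60)) + 2L
    ecg <- generate_ecg(tg$heart_rate_bpm, nb, rr_jitter = 0.03,
                        noise_snr_db = ecg_snr_db,
                        seed = child_seed(seed, 100 + attempt))
    pcg <- generate_pcg(ecg$truth, s2_split_ms = tg$s2_split_ms,
                        emat_ms = tg$emat_ms, s1s2_ms = tg$s1s2_ms,
                        resp_mod_ms = tg$resp_mod_ms,
                        resp_period_s = resp_period_s,
                        resp_phase = phase_fun,
                        beat_jitter_sd_ms = beat_jitter_sd_ms,
                        noise_snr_db = pcg_snr_db,
                        duration_ms = ecg$duration_ms,
                        seed = child_seed(seed, 200 + attempt))
    # inject artifacts
    set.seed(child_seed(seed, 300 + attempt))
    dur_min <- pcg$duration_ms / 60000
    n_art <- stats::rpois(1, artifact_rate * dur_min)
    arts <- data.frame(start_ms = numeric(0), end_ms = numeric(0))
    if (n_art > 0) {
      starts <- sort(stats::runif(n_art, 0, pcg$duration_ms - 1000))
      keep <- c(TRUE, diff(starts) > 1200)   # non-overlapping
      starts <- starts[keep]
      arts <- data.frame(start_ms = starts, end_ms = starts + 1000)
      a_ref <- stats::quantile(abs(pcg$signal), 0.999)
      for (i in seq_len(nrow(arts))) {
        idx <- which(idx_to_ms(seq_along(pcg$signal), pcg$fs) >= arts$start_ms[i] &
                     idx_to_ms(seq_along(pcg$signal), pcg$fs) <= arts$end_ms[i])
        pcg$signal[idx] <- pcg$signal[idx] +
          stats::rnorm(length(idx), sd = 2.5 * a_ref)
      }
    }
    # qualifying beats on ground truth: gated, clean, away from recording edges
    tr <- pcg$truth
    gated <- abs(((tr$resp_phase - pi) + pi) %% (2 * pi) - pi) <= pi / 4
    clean <- !vapply(tr$r_peak_ms, function(r)
      any(r > arts$start_ms - 400 & r < arts$end_ms + 400), logical(1))
    runs <- rle(gated & clean)
    max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    list(ecg = ecg, pcg = pcg, arts = arts, phase_fun = phase_fun,
         max_run = max_run)
  }

  b <- build(duration_s, 1L)
  if (b$max_run < 30) b <- build(duration_s + 40, 2L)
  if (b$max_run < 30)
    stop("artifact rate too high: fewer than 30 clean end-expiration beats")

  structure(list(
    ecg = list(signal = b$ecg$signal, fs = b$ecg$fs),
    pcg = list(signal = b$pcg$signal, fs = b$pcg$fs),
    truth = b$pcg$truth, artifacts = b$arts, group = group,
    targets = tg, resp_phase_fun = b$phase_fun,
    demographics = demographics, duration_ms = b$pcg$duration_ms,
    seed = seed), class = "sync_recording")
}
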