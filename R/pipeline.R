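# End-to-end pipeline: per-subject extraction, cohort-level analysis, and the
# simulate / extract / analyze commands behind the command-line interface.

#' Default run configuration
#'
#' All defaults reproduce the published acquisition and analysis settings:
#' 30 analysis beats, 1-s artifact windows with the 30% amplitude-variation
#' and 10 dB SNR thresholds, end-expiration gate of pi +/- pi/4, 10-fold
#' cross-validation and 1,000 bootstrap resamples.
#'
#' @param ... named overrides of any default.
#' @return named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(seed = 1L, n_per_group = 50L, n_beats_required = 30L,
              window_s = 1, amp_threshold = 0.30, snr_threshold_db = 10,
              resp_tolerance = pi / 4, cv_k = 10L, bootstrap_B = 1000L,
              artifact_rate = 0, duration_s = 70,
              score_variables = c("s2_split_ms", "s1s2_rr_pct"),
              out_dir = "s2screen_output")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  structure(utils::modifyList(cfg, over), class = c("run_config", "list"))
}

#' Delineate every beat of a synchronized recording
#'
#' Runs the full fiducial chain: band-pass both channels, detect R peaks and
#' Q onsets, build the coarse PCG envelope, segment S1/S2, split S2 into
#' A2/P2, and assemble one `BeatAnnotation` row per beat. A beat is valid when
#' all its fiducials were found in physiological order and its RR is known.
#'
#' @param rec a `sync_recording`.
#' @return list with `annotations` (data.frame), `artifact_mask` (from
#'   [detect_artifacts()]), and the filtered channels.
#' @export
delineate_recording <- function(rec) {
  ecg_f <- bandpass_ecg(rec$ecg$signal, rec$ecg$fs)
  pcg_f <- bandpass_pcg(rec$pcg$signal, rec$pcg$fs)
  r <- detect_r_peaks(ecg_f, rec$ecg$fs)
  if (length(r) < 2) stop("fewer than two R peaks detected")
  q <- detect_q_onset(ecg_f, rec$ecg$fs, r)
  env <- pcg_envelope(pcg_f, rec$pcg$fs)
  rr <- c(diff(r), NA_real_)
  seg <- segment_s1_s2(env, rec$pcg$fs, r,
                       rr_ms = ifelse(is.na(rr), stats::median(diff(r)), rr))
  nb <- length(r)
  a2 <- p2 <- rep(NA_real_, nb)
  for (k in seq_len(nb)) {
    if (!seg$valid[k] || is.na(seg$s2_onset_ms[k])) next
    sp <- try(split_s2(pcg_f, rec$pcg$fs, seg$s2_onset_ms[k]), silent = TRUE)
    if (!inherits(sp, "try-error")) {
      a2[k] <- sp$a2_peak_ms
      p2[k] <- sp$p2_peak_ms
    }
  }
  ann <- data.frame(beat = seq_len(nb), q_onset_ms = q, r_peak_ms = r,
                    s1_onset_ms = seg$s1_onset_ms, s1_peak_ms = seg$s1_peak_ms,
                    s2_onset_ms = seg$s2_onset_ms, a2_peak_ms = a2,
                    p2_peak_ms = p2, rr_ms = rr)
  ann$valid <- seg$valid & !is.na(q) & !is.na(a2) & !is.na(rr) &
    q < ann$r_peak_ms & ann$r_peak_ms < ann$s1_peak_ms &
    ann$s1_peak_ms < a2 & a2 <= p2 & rr > 200
  ann$valid[is.na(ann$valid)] <- FALSE
  list(annotations = ann, artifact_mask = detect_artifacts(
         pcg_f, rec$pcg$fs), ecg_filtered = ecg_f, pcg_filtered = pcg_f)
}

beat_artifact_free <- function(ann, mask) {
  invalid <- mask[!mask$valid, , drop = FALSE]
  vapply(seq_len(nrow(ann)), function(k) {
    lo <- ann$q_onset_ms[k] - 20
    hi <- (if (is.na(ann$p2_peak_ms[k])) ann$r_peak_ms[k] + 400
           else ann$p2_peak_ms[k] + 40)
    if (is.na(lo)) lo <- ann$r_peak_ms[k] - 120
    !any(lo < invalid$end_ms & hi > invalid$start_ms)
  }, logical(1))
}

#' Extract the subject-level index record from a recording
#'
#' Delineates the recording, rejects artifact windows, gates beats to
#' end-expiration, selects the analysis run of consecutive qualifying beats,
#' and averages the per-beat indices.
#'
#' @param rec a `sync_recording`.
#' @param config a `run_config`; see [default_config()].
#' @param subject_id identifier carried into the record.
#' @param use_truth_phase use the ground-truth respiratory phase for gating
#'   when available (default TRUE; set FALSE to force estimation from the PCG
#'   amplitude modulation).
#' @return list with `record` (one-row subject summary), `annotations`,
#'   `selected` (beat indices used), `artifact_mask`.
#' @export
extract_subject <- function(rec, config = default_config(),
                            subject_id = "subject", use_truth_phase = TRUE) {
  del <- delineate_recording(rec)
  ann <- del$annotations
  phase <- if (use_truth_phase && !is.null(rec$truth$resp_phase) &&
               nrow(rec$truth) == nrow(ann)) rec$truth$resp_phase else NULL
  gate <- if (!is.null(phase))
    respiratory_gate(ann$r_peak_ms, phase = phase,
                     tolerance = config$resp_tolerance)
  else if (is.function(rec$resp_phase_fun))
    respiratory_gate(ann$r_peak_ms, phase = rec$resp_phase_fun,
                     tolerance = config$resp_tolerance)
  else respiratory_gate(ann$r_peak_ms, pcg = del$pcg_filtered,
                        fs = rec$pcg$fs, tolerance = config$resp_tolerance)
  clean <- beat_artifact_free(ann, del$artifact_mask)
  sel <- select_beats(ann$valid & clean & gate, config$n_beats_required)
  idx <- beat_indices(ann[sel, ])
  rec_row <- subject_summary(idx, subject_id = subject_id,
                             group = rec$group %||% NA_character_,
                             demographics = rec$demographics)
  list(record = rec_row, annotations = ann, selected = sel,
       artifact_mask = del$artifact_mask)
}

#' Diagnostic performance report for a subject-level cohort
#'
#' For each score variable: nonparametric AUC with Hanley-McNeil SE and Wald
#' CI, Youden-optimal cut-off with sensitivity/specificity, stratified k-fold
#' cross-validated AUC, and bootstrap bias-corrected AUC. A multivariable
#' logistic model over all score variables supplies coefficients, Wald
#' chi-squares and odds ratios.
#'
#' @param cohort data.frame with `group` and the score columns.
#' @param config a `run_config`.
#' @return list of class `diagnostic_report`: `roc` (one row per variable),
#'   `logistic` (a `logit_result`), `n_cases`, `n_controls`.
#' @export
diagnostic_report <- function(cohort, config = default_config()) {
  l <- check_labels(cohort$group)
  vars <- intersect(config$score_variables, names(cohort))
  if (!length(vars)) stop("no score variables present in cohort")
  # stratified folds need both classes in every fold
  k <- max(2L, min(config$cv_k, sum(l), sum(!l)))
  if (k < config$cv_k)
    message("cross-validation folds reduced to ", k,
            " to keep both classes in every fold")
  rows <- lapply(vars, function(v) {
    sc <- cohort[[v]]
    auc <- roc_auc(sc, l)
    ci <- auc_se_ci(auc, sum(l), sum(!l))
    yc <- youden_cutoff(sc, l)
    cv <- crossval_auc(sc, l, k = k, seed = config$seed)
    bt <- bootstrap_auc(sc, l, B = config$bootstrap_B, seed = config$seed)
    data.frame(variable = v, auc = auc, se = ci$se, ci_lower = ci$ci_lower,
               ci_upper = ci$ci_upper, cutoff = yc$cutoff,
               sensitivity = yc$sensitivity, specificity = yc$specificity,
               youden = yc$youden, cv_auc = cv$auc,
               cv_ci_lower = cv$ci_lower, cv_ci_upper = cv$ci_upper,
               boot_auc_bc = bt$auc_bc, boot_ci_lower = bt$ci_lower,
               boot_ci_upper = bt$ci_upper)
  })
  logit <- tryCatch(logistic_fit(cohort[vars], l), error = function(e) {
    message("logistic model not fitted: ", conditionMessage(e))
    NULL
  })
  structure(list(roc = do.call(rbind, rows), logistic = logit,
                 n_cases = sum(l), n_controls = sum(!l)),
            class = "diagnostic_report")
}

# ---- commands ---------------------------------------------------------------

#' Simulate a cohort to disk
#'
#' Writes one recording directory per subject (WAV + CSV + JSON sidecars), a
#' subject-level index table drawn from the published group structure, and a
#' manifest with every derived seed.
#'
#' @param config a `run_config`.
#' @param waveforms generate waveform recordings (TRUE) or only the index
#'   table (FALSE).
#' @return output directory, invisibly.
#' @export
cmd_simulate <- function(config = default_config(), waveforms = TRUE) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  spec <- asd_cohort_spec(n_per_group = config$n_per_group)
  cohort <- generate_cohort_indices(spec, seed = config$seed)
  utils::write.csv(cohort, file.path(out, "cohort_indices.csv"),
                   row.names = FALSE)
  manifest <- list(seed = config$seed, n_per_group = config$n_per_group,
                   subjects = list())
  if (waveforms) {
    for (i in seq_len(nrow(cohort))) {
      sid <- cohort$subject_id[i]
      sseed <- child_seed(config$seed, 1000 + i)
      rec <- generate_subject(
        group = cohort$group[i],
        targets = list(s2_split_ms = cohort$s2_split_ms[i],
                       emat_ms = cohort$emat_ms[i],
                       s1s2_ms = cohort$s1s2_ms[i],
                       heart_rate_bpm = min(200, max(40, cohort$hr_bpm[i]))),
        artifact_rate = config$artifact_rate, seed = sseed,
        duration_s = config$duration_s,
        demographics = as.list(cohort[i, c("age_yr", "sex", "height_cm",
                                           "weight_kg", "bmi", "hr_bpm",
                                           "sbp_mmhg", "dbp_mmhg")]))
      write_recording(rec, file.path(out, "recordings", sid))
      manifest$subjects[[sid]] <- list(seed = sseed, group = cohort$group[i])
    }
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Extract subject indices from simulated recordings
#'
#' Runs preprocessing, delineation and index extraction over every recording
#' directory; failing subjects are excluded and listed with reasons in
#' `rejects.csv`.
#'
#' @param config a `run_config`.
#' @return the extracted table, invisibly (also written to
#'   `extracted_indices.csv`).
#' @export
cmd_extract <- function(config = default_config()) {
  out <- config$out_dir
  rec_dir <- file.path(out, "recordings")
  dirs <- list.dirs(rec_dir, recursive = FALSE)
  if (!length(dirs)) stop("no readable subjects under ", rec_dir)
  rows <- list(); rejects <- list()
  for (d in dirs) {
    sid <- basename(d)
    res <- try({
      rec <- read_recording(d)
      extract_subject(rec, config, subject_id = sid)$record
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      rejects[[sid]] <- conditionMessage(attr(res, "condition"))
      warning("subject ", sid, " excluded: ", rejects[[sid]])
    } else rows[[sid]] <- res
  }
  if (!length(rows)) stop("no subjects could be extracted")
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(out, "extracted_indices.csv"),
                   row.names = FALSE)
  if (length(rejects))
    utils::write.csv(data.frame(subject_id = names(rejects),
                                reason = unlist(rejects)),
                     file.path(out, "rejects.csv"), row.names = FALSE)
  invisible(tab)
}

#' Analyze a subject-level index table
#'
#' Emits the group-comparison table (demographics + indices), the
#' age-stratified subgroup analysis, index--covariate correlations where
#' covariates are present, and the full diagnostic report (ROC, cut-offs,
#' cross-validation, bootstrap, logistic model) as CSV/JSON files.
#'
#' @param config a `run_config`.
#' @param cohort optional in-memory table; defaults to
#'   `cohort_indices.csv` under the output directory (or the extracted table
#'   if present).
#' @return list with `comparisons`, `report`, `subgroups`, `correlations`,
#'   invisibly.
#' @export
cmd_analyze <- function(config = default_config(), cohort = NULL) {
  out <- config$out_dir
  if (is.null(cohort)) {
    f <- file.path(out, "extracted_indices.csv")
    if (!file.exists(f)) f <- file.path(out, "cohort_indices.csv")
    if (!file.exists(f)) stop("no index table found under ", out)
    cohort <- utils::read.csv(f)
  }
  for (v in config$score_variables)
    if (!v %in% names(cohort)) stop("missing column in index table: ", v)
  if (length(unique(cohort$group)) < 2) {
    message("single-group input: group tests skipped")
    return(invisible(NULL))
  }
  comparisons <- compare_groups(cohort)
  report <- diagnostic_report(cohort, config)
  subgroups <- if ("age_yr" %in% names(cohort) &&
                   all(table(cohort$age_yr < 8, cohort$group) > 0))
    lapply(stats::setNames(nm = config$score_variables), function(v)
      subgroup_analysis(cohort, v))
  else NULL
  correlations <- NULL
  covs <- intersect(c("asd_size_mm", "rvedvi_ml_m2"), names(cohort))
  asd <- cohort[cohort$group == "ASD", ]
  if (length(covs) && nrow(asd) >= 3) {
    correlations <- do.call(rbind, lapply(covs, function(cv) {
      if (all(is.na(asd[[cv]]))) return(NULL)
      do.call(rbind, lapply(config$score_variables, function(v) {
        pr <- pearson_r(asd[[v]], asd[[cv]])
        data.frame(index = v, covariate = cv, r = pr$r, p = pr$p, n = pr$n)
      }))
    }))
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(comparisons, file.path(out, "group_comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(report$roc, file.path(out, "roc_analysis.csv"),
                   row.names = FALSE)
  if (!is.null(report$logistic))
    utils::write.csv(report$logistic$coefficients,
                     file.path(out, "logistic_model.csv"), row.names = FALSE)
  if (!is.null(correlations))
    utils::write.csv(correlations, file.path(out, "correlations.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(roc = report$roc, logistic = report$logistic$coefficients,
         n_cases = report$n_cases, n_controls = report$n_controls,
         interaction_p = lapply(subgroups, `[[`, "interaction_p"),
         settings = unclass(config)[c("seed", "cv_k", "bootstrap_B",
                                      "n_beats_required")]),
    file.path(out, "diagnostic_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(comparisons = comparisons, report = report,
                 subgroups = subgroups, correlations = correlations))
}
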