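# The five acoustic-electrocardiographic indices, per beat and per subject.

#' Compute the five timing indices for annotated beats
#'
#' From per-beat fiducials: S2 splitting = P2 - A2; S1--S2 = A2 peak - S1
#' peak; EMAT = S1 peak - Q onset; and the RR-normalized percentages
#' S1--S2/RR and EMAT/RR. The RR used for the ratio indices is the beat's own
#' interval (current R to next R).
#'
#' @param annotation data.frame with columns `q_onset_ms`, `s1_peak_ms`,
#'   `a2_peak_ms`, `p2_peak_ms`, `rr_ms` (one row per beat). An `s2_peak_ms`
#'   column, if present, is ignored in favour of the A2 peak: the S1--S2
#'   interval ends at the aortic component.
#' @return data.frame with columns `s2_split_ms`, `s1s2_ms`, `s1s2_rr_pct`,
#'   `emat_ms`, `emat_rr_pct`.
#' @export
#' @examples
#' beat_indices(data.frame(q_onset_ms = 0, s1_peak_ms = 96.2,
#'                         a2_peak_ms = 334.7, p2_peak_ms = 374.35,
#'                         rr_ms = 635.49))
beat_indices <- function(annotation) {
  need <- c("q_onset_ms", "s1_peak_ms", "a2_peak_ms", "p2_peak_ms", "rr_ms")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) stop("missing fiducial column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(annotation[need]))))
    stop("missing fiducial value(s) in annotation")
  if (any(annotation$rr_ms <= 0)) stop("rr_ms must be positive")
  with(annotation, {
    s1s2 <- a2_peak_ms - s1_peak_ms
    emat <- s1_peak_ms - q_onset_ms
    data.frame(s2_split_ms = p2_peak_ms - a2_peak_ms,
               s1s2_ms = s1s2,
               s1s2_rr_pct = s1s2 / rr_ms * 100,
               emat_ms = emat,
               emat_rr_pct = emat / rr_ms * 100)
  })
}

#' Summarize a subject: mean of all valid beats
#'
#' Arithmetic mean of each per-beat index (mean of the per-beat ratios, not
#' the ratio of means), with the number of contributing beats recorded.
#'
#' @param indices data.frame from [beat_indices()], valid beats only.
#' @param subject_id identifier string.
#' @param group group label, "ASD" or "control".
#' @param demographics optional named list merged into the record.
#' @return one-row data.frame: `subject_id`, `group`, demographics, the five
#'   mean indices, and `n_beats`.
#' @export
subject_summary <- function(indices, subject_id = NA_character_,
                            group = NA_character_, demographics = NULL) {
  if (!nrow(indices)) stop("no valid beats to summarize")
  out <- data.frame(subject_id = subject_id, group = group)
  for (d in names(demographics)) out[[d]] <- demographics[[d]]
  for (v in names(indices)) out[[v]] <- mean(indices[[v]])
  out$n_beats <- nrow(indices)
  out
}
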