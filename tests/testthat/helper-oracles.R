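# Independent brute-force oracles and small synthesis shortcuts shared by the
# test files.

# AUC as the literal probability over all case-control pairs, ties half.
pairwise_auc <- function(scores, labels) {
  l <- as.logical(labels)
  s1 <- scores[l]; s0 <- scores[!l]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Youden optimum by exhaustive search over every midpoint threshold.
exhaustive_youden <- function(scores, labels) {
  l <- as.logical(labels)
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) c(u[1] - 1, (u[-length(u)] + u[-1]) / 2,
                               u[length(u)] + 1) else c(u - 1, u + 1)
  best <- NULL
  for (th in cand) {
    sens <- mean(scores[l] >= th)
    spec <- mean(scores[!l] < th)
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden + 1e-12 ||
        (abs(j - best$youden) <= 1e-12 && sens > best$sensitivity))
      best <- list(cutoff = th, sensitivity = sens, specificity = spec,
                   youden = j)
  }
  best
}

# Short clean recording (single generator pass, no subject-level protocol):
# 30 beats at 86 bpm with the requested targets, high SNR.
make_clean_recording <- function(seed = 1, split = 39.65, emat = 96.2,
                                 s1s2 = 238.5, snr = 30, n_beats = 30,
                                 jitter = 0.03, resp_mod = 0) {
  e <- generate_ecg(86, n_beats, rr_jitter = jitter, seed = seed)
  p <- generate_pcg(e$truth, s2_split_ms = split, emat_ms = emat,
                    s1s2_ms = s1s2, resp_mod_ms = resp_mod,
                    noise_snr_db = snr, seed = seed,
                    duration_ms = e$duration_ms)
  list(ecg = e, pcg = p)
}

# Match delineated beats to ground-truth rows by nearest R peak.
match_beats <- function(ann, truth, max_ms = 100) {
  vapply(ann$r_peak_ms, function(r) {
    d <- abs(truth$r_peak_ms - r)
    if (min(d) > max_ms) NA_integer_ else which.min(d)
  }, integer(1))
}
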