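# File interfaces: 16-bit PCM WAV for the PCG channel, CSV for the ECG and
# tables, JSON sidecars for ground truth and reports. The WAV reader/writer is
# a minimal mono RIFF implementation (no audio package ships with the
# analysis stack this targets).

#' Write a mono 16-bit PCM WAV file
#'
#' The signal is scaled by `scale` (default: its own absolute maximum) into
#' \[-1, 1\] before quantization; the scale is returned so the amplitude can
#' be restored on read.
#'
#' @param x numeric samples.
#' @param fs sampling rate in Hz.
#' @param path output file.
#' @param scale full-scale amplitude; defaults to `max(abs(x))`.
#' @return the scale used, invisibly.
#' @export
write_wav_pcm16 <- function(x, fs, path, scale = NULL) {
  scale <- scale %||% max(abs(x), 1e-12)
  s <- as.integer(round(pmax(-1, pmin(1, x / scale)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(s)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(s, con, size = 2, endian = "little")
  invisible(scale)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file written by [write_wav_pcm16()] (or any mono PCM16
#'   RIFF file with a standard fmt chunk).
#' @param scale amplitude scale to restore (default 1: samples in \[-1, 1\]).
#' @return list with `signal` and `fs`.
#' @export
read_wav_pcm16 <- function(path, scale = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, "integer", 1, 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!nzchar(id)) stop("no data chunk found")
    len <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      if (fmt[1] != 1 || fmt[2] != 1) stop("only mono PCM supported")
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "raw", len - 8)
    } else if (id == "data") {
      s <- readBin(con, "integer", len / 2, 2, signed = TRUE,
                   endian = "little")
      return(list(signal = s / 32767 * scale, fs = fs))
    } else readBin(con, "raw", len)
  }
}

#' Write a synchronized recording to a directory
#'
#' Layout: `pcg.wav` (16-bit PCM at the PCG rate), `ecg.csv`
#' (`time_ms, amplitude`), `truth.json` (per-beat ground truth and artifact
#' intervals), `meta.json` (group, seed, amplitude scales, demographics).
#'
#' @param rec a `sync_recording` from [generate_subject()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- write_wav_pcm16(rec$pcg$signal, rec$pcg$fs,
                           file.path(dir, "pcg.wav"))
  t_ms <- idx_to_ms(seq_along(rec$ecg$signal), rec$ecg$fs)
  utils::write.csv(data.frame(time_ms = t_ms, amplitude = rec$ecg$signal),
                   file.path(dir, "ecg.csv"), row.names = FALSE)
  jsonlite::write_json(list(truth = rec$truth, artifacts = rec$artifacts),
                       file.path(dir, "truth.json"), digits = NA)
  jsonlite::write_json(list(group = rec$group, seed = rec$seed,
                            pcg_scale = scale, fs_ecg = rec$ecg$fs,
                            fs_pcg = rec$pcg$fs,
                            duration_ms = rec$duration_ms,
                            targets = rec$targets,
                            demographics = rec$demographics),
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synchronized recording written by [write_recording()]
#'
#' @param dir directory containing `pcg.wav`, `ecg.csv`, `truth.json`,
#'   `meta.json`.
#' @return a `sync_recording` list (without the respiratory phase function,
#'   which is not serialized; gating falls back to the stored per-beat phase
#'   or the amplitude-modulation estimate).
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  wav <- read_wav_pcm16(file.path(dir, "pcg.wav"), scale = meta$pcg_scale)
  ecg <- utils::read.csv(file.path(dir, "ecg.csv"))
  tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  arts <- as.data.frame(tj$artifacts)
  if (!nrow(arts)) arts <- data.frame(start_ms = numeric(0),
                                      end_ms = numeric(0))
  structure(list(
    ecg = list(signal = ecg$amplitude, fs = meta$fs_ecg),
    pcg = list(signal = wav$signal, fs = wav$fs),
    truth = as.data.frame(tj$truth), artifacts = arts,
    group = meta$group, targets = meta$targets,
    resp_phase_fun = NULL, demographics = meta$demographics,
    duration_ms = meta$duration_ms, seed = meta$seed),
    class = "sync_recording")
}
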