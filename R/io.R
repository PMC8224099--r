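#' Write a recording as multi-channel float32 WAV
#'
#' Minimal RIFF/WAVE writer (IEEE float, format tag 3), channels
#' interleaved.
#'
#' @param rec A [pcg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_wav <- function(rec, path) {
  ch <- nrow(rec$samples); n <- ncol(rec$samples)
  fs <- as.integer(round(rec$fs_hz))
  data_bytes <- 4L * ch * n
  con <- file(path, "wb")
  on.exit(close(con))
  wc <- function(x) writeChar(x, con, eos = NULL)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wc("RIFF"); wi(36L + data_bytes, 4); wc("WAVE")
  wc("fmt "); wi(16L, 4); wi(3L, 2); wi(ch, 2); wi(fs, 4)
  wi(fs * ch * 4L, 4); wi(ch * 4L, 2); wi(32L, 2)
  wc("data"); wi(data_bytes, 4)
  writeBin(as.numeric(as.vector(rec$samples)), con, size = 4,
           endian = "little")
  invisible(path)
}

#' Read a multi-channel float32 WAV written by [write_recording_wav()]
#'
#' @param path WAV file path.
#' @param subject_id,label Metadata to attach (not stored in WAV).
#' @return A [pcg_recording()].
#' @export
read_recording_wav <- function(path, subject_id = "unknown",
                               label = "non-CAD") {
  con <- file(path, "rb")
  on.exit(close(con))
  rc <- function(n) readChar(con, n, useBytes = TRUE)
  ri <- function(size, n = 1L) readBin(con, "integer", n = n, size = size,
                                       endian = "little")
  if (rc(4) != "RIFF") stop("not a RIFF file")
  ri(4); if (rc(4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL
  repeat {
    id <- rc(4)
    if (nchar(id) < 4) stop("no data chunk found")
    sz <- ri(4)
    if (id == "fmt ") {
      tag <- ri(2); ch <- ri(2); fs <- ri(4); ri(4); ri(2); bits <- ri(2)
      if (tag != 3L || bits != 32L) stop("only float32 WAV is supported")
      if (sz > 16) readBin(con, "raw", sz - 16L)
      fmt <- list(ch = ch, fs = fs)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      v <- readBin(con, "numeric", n = sz %/% 4L, size = 4, endian = "little")
      smp <- matrix(v, nrow = fmt$ch)
      return(pcg_recording(smp, fmt$fs, subject_id, label))
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
  }
}

#' Write a ground-truth / annotation CSV
#'
#' Columns `cycle, s1_start, s1_end, sys_end, s2_end, dia_end`; 0-based,
#' half-open sample indices. Round-trips with [read_states_csv()].
#'
#' @param ann A [cycle_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_states_csv <- function(ann, path) {
  df <- cbind(cycle = seq_len(nrow(ann$cycles)) - 1L, ann$cycles)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_states_csv
#' @param source Annotation source tag for the reconstructed object.
#' @return `read_states_csv` returns a [cycle_annotation()].
#' @export
read_states_csv <- function(path, source = "ground_truth") {
  df <- utils::read.csv(path)
  cycle_annotation(df[, c("s1_start", "s1_end", "sys_end", "s2_end",
                          "dia_end")], source = source)
}

#' Write a cohort manifest CSV
#'
#' One row per subject: id, label and the generator parameters that
#' produced the recording (including the per-subject seed).
#'
#' @param cohort A list from [generate_cohort()].
#' @param path Output path.
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  rows <- lapply(cohort, function(s) {
    pf <- s$profile
    data.frame(subject_id = pf$subject_id, label = pf$label,
               heart_rate_bpm = pf$heart_rate_bpm, hr_jitter = pf$hr_jitter,
               murmur_snr_db = pf$murmur_snr_db,
               desync_level = pf$desync_level,
               hf_noise_db = pf$hf_noise_db,
               gains = paste(signif(pf$channel_gains, 6), collapse = ";"),
               seed = pf$seed)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write per-segment quality report CSV
#'
#' @param segments List of [pcg_segment()]s.
#' @param path Output path.
#' @param thresholds See [quality_thresholds()].
#' @return The report data.frame, invisibly.
#' @export
write_quality_report <- function(segments, path,
                                 thresholds = quality_thresholds()) {
  rows <- lapply(segments, function(seg) {
    q <- assess_quality(seg, thresholds)
    cbind(subject_id = seg$subject_id, segment_index = seg$segment_index,
          q$metrics, pass = q$pass)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
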