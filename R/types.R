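#' Multi-channel PCG recording
#'
#' Container for synchronized multi-channel heart sound samples.
#'
#' @param samples Numeric matrix, channels x samples (5 x N).
#' @param fs_hz Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param label `"CAD"` or `"non-CAD"`.
#' @return An object of class `pcg_recording`.
#' @export
pcg_recording <- function(samples, fs_hz, subject_id, label) {
  if (!is.matrix(samples)) stop("samples must be a channels x samples matrix")
  if (any(!is.finite(samples))) stop("samples must be finite (no NaN/Inf)")
  label <- match.arg(label, c("CAD", "non-CAD"))
  structure(list(samples = samples, fs_hz = fs_hz,
                 subject_id = subject_id, label = label),
            class = "pcg_recording")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("pcg_recording: %d channels x %d samples (%.1f s @ %g Hz), subject %s [%s]\n",
              nrow(x$samples), ncol(x$samples), ncol(x$samples) / x$fs_hz,
              x$fs_hz, x$subject_id, x$label))
  invisible(x)
}

#' One 10-s multi-channel segment of a recording
#'
#' @param samples Channels x samples matrix.
#' @param fs_hz Sampling rate in Hz.
#' @param subject_id,label Propagated recording metadata.
#' @param segment_index 0-based index of the segment within its recording.
#' @param offset 0-based sample offset of the segment start in the recording.
#' @param quality_pass Logical quality-gate verdict (`NA` until assessed).
#' @return An object of class `pcg_segment`.
#' @export
pcg_segment <- function(samples, fs_hz, subject_id, label,
                        segment_index, offset = 0L, quality_pass = NA) {
  structure(list(samples = samples, fs_hz = fs_hz, subject_id = subject_id,
                 label = label, segment_index = as.integer(segment_index),
                 offset = as.integer(offset), quality_pass = quality_pass),
            class = "pcg_segment")
}

#' Per-cycle cardiac state annotation
#'
#' Boundaries of the four states of each cardiac cycle, as 0-based
#' half-open sample indices: S1 occupies `[s1_start, s1_end)`, systole
#' `[s1_end, sys_end)`, S2 `[sys_end, s2_end)` and diastole
#' `[s2_end, dia_end)`.
#'
#' @param cycles Data frame with integer columns `s1_start`, `s1_end`,
#'   `sys_end`, `s2_end`, `dia_end`, one row per complete cycle, ordered.
#' @param source `"ground_truth"` or `"envelope"`.
#' @return An object of class `cycle_annotation`.
#' @export
cycle_annotation <- function(cycles, source = c("ground_truth", "envelope")) {
  source <- match.arg(source)
  need <- c("s1_start", "s1_end", "sys_end", "s2_end", "dia_end")
  if (!all(need %in% names(cycles))) stop("missing annotation columns")
  cycles <- cycles[, need, drop = FALSE]
  if (nrow(cycles) > 0) {
    flat <- as.vector(t(as.matrix(cycles)))
    if (any(diff(flat) <= 0) &&
        !all(diff(flat) >= 0)) stop("state indices must be increasing")
    if (any(apply(cycles, 1, function(r) any(diff(r) <= 0))))
      stop("state indices must be strictly increasing within a cycle")
    if (nrow(cycles) > 1 &&
        any(cycles$s1_start[-1] < cycles$dia_end[-nrow(cycles)]))
      stop("cycles must not overlap")
  }
  structure(list(cycles = cycles, source = source), class = "cycle_annotation")
}

#' @export
print.cycle_annotation <- function(x, ...) {
  cat(sprintf("cycle_annotation: %d cycles (source: %s)\n",
              nrow(x$cycles), x$source))
  invisible(x)
}

#' Number of annotated cycles
#' @param ann A [cycle_annotation()].
#' @return Integer cycle count.
#' @export
n_cycles <- function(ann) nrow(ann$cycles)

# slice of x on the 0-based half-open window [a, b)
slice0 <- function(x, a, b) x[(a + 1):b]

#' Extract per-cycle state windows from one channel
#'
#' @param seg_channel Numeric vector (one channel of a segment).
#' @param ann A [cycle_annotation()] whose indices refer to `seg_channel`.
#' @return A list with one element per cycle, each holding numeric vectors
#'   `s1`, `systole`, `s2`, `diastole`.
#' @export
state_slices <- function(seg_channel, ann) {
  cy <- ann$cycles
  if (nrow(cy) == 0) return(list())
  if (max(cy$dia_end) > length(seg_channel))
    stop("annotation extends beyond the signal")
  lapply(seq_len(nrow(cy)), function(k) {
    r <- cy[k, ]
    list(s1 = slice0(seg_channel, r$s1_start, r$s1_end),
         systole = slice0(seg_channel, r$s1_end, r$sys_end),
         s2 = slice0(seg_channel, r$sys_end, r$s2_end),
         diastole = slice0(seg_channel, r$s2_end, r$dia_end))
  })
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
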