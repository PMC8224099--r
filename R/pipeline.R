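entropy_feature_basenames <- function() {
  c("SampEn_Sys", "SampEn_Dia", "FuzzyEn_Sys", "FuzzyEn_Dia",
    "DistEn_Sys", "DistEn_Dia")
}

# the 48 canonical single-channel feature names (no channel suffix)
channel_feature_basenames <- function() {
  c(as.vector(rbind(paste0("m_", time_feature_basenames()),
                    paste0("sd_", time_feature_basenames()))),
    as.vector(rbind(paste0("m_", freq_feature_basenames()),
                    paste0("sd_", freq_feature_basenames()))),
    as.vector(rbind(paste0("m_", entropy_feature_basenames()),
                    paste0("sd_", entropy_feature_basenames()))))
}

#' Canonical names of the 270 features
#'
#' The 48 single-channel features (20 time, 16 frequency, 12 entropy) of
#' channels 1-5 in channel-block order, followed by the 30 cross-entropy
#' features over the 10 channel pairs.
#'
#' @return Character vector of length 270.
#' @export
feature_names <- function() {
  single <- unlist(lapply(1:5, function(ch)
    paste0(channel_feature_basenames(), "_", ch)))
  c(single, cross_feature_names())
}

#' Pipeline configuration
#'
#' @param entropy An [entropy_params()] object.
#' @param cross A [cross_entropy_params()] object.
#' @param cross_decimate Decimation factor before cross-entropy
#'   computation (default 4).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(entropy = entropy_params(),
                            cross = cross_entropy_params(),
                            cross_decimate = 4L) {
  structure(list(entropy = entropy, cross = cross,
                 cross_decimate = as.integer(cross_decimate)),
            class = "pipeline_config")
}

#' Extract the 270-feature row of one segment
#'
#' Concatenates the time (20), frequency (16) and entropy (12) blocks of
#' each of the 5 channels and the 30 cross-entropy features. A failing
#' block is reported as `NA` values with a warning, never silently
#' dropped.
#'
#' @param seg A [pcg_segment()].
#' @param ann A [cycle_annotation()] in segment coordinates (shared by all
#'   channels), or a list of 5 per-channel annotations.
#' @param cfg A [pipeline_config()].
#' @return A one-row data.frame: `subject_id`, `label`, `segment_index`
#'   and the 270 named feature columns.
#' @export
extract_features <- function(seg, ann, cfg = pipeline_config()) {
  anns <- if (inherits(ann, "cycle_annotation")) rep(list(ann), 5) else ann
  stopifnot(length(anns) == 5)
  base <- channel_feature_basenames()
  block_names <- list(time = base[1:20], freq = base[21:36], ent = base[37:48])
  vals <- numeric(0)
  for (ch in 1:5) {
    x <- seg$samples[ch, ]
    a <- anns[[ch]]
    blocks <- list(
      time = function() time_domain_features(x, a, seg$fs_hz),
      freq = function() frequency_domain_features(x, a, seg$fs_hz),
      ent = function() entropy_block(x, a, cfg$entropy))
    for (b in names(blocks)) {
      v <- tryCatch(suppressWarnings(blocks[[b]]()), error = function(e) {
        warning(sprintf("channel %d %s block failed: %s", ch, b,
                        conditionMessage(e)))
        stats::setNames(rep(NA_real_, length(block_names[[b]])),
                        block_names[[b]])
      })
      names(v) <- paste0(names(v), "_", ch)
      vals <- c(vals, v)
    }
  }
  cross <- tryCatch(suppressWarnings(
    cross_block(seg, cfg$cross, cfg$cross_decimate)),
    error = function(e) {
      warning(sprintf("cross block failed: %s", conditionMessage(e)))
      stats::setNames(rep(NA_real_, 30), cross_feature_names())
    })
  vals <- c(vals, cross)
  stopifnot(identical(names(vals), feature_names()))
  cbind(data.frame(subject_id = seg$subject_id, label = seg$label,
                   segment_index = seg$segment_index,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(vals), check.names = FALSE))
}

#' Run the full pipeline over a cohort
#'
#' For each subject: filter the full recording (high-pass + notch), crop
#' it to 10-s segments, apply the quality gate, annotate cardiac states
#' (ground-truth pass-through by default, envelope segmentation
#' otherwise) and extract the 270-feature row of every usable segment.
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param cfg A [pipeline_config()].
#' @param seg_len_s Segment length in seconds (default 10).
#' @param use_truth Use the generator's ground-truth annotations
#'   (default `TRUE`); otherwise envelope segmentation on `channel`.
#' @param channel Envelope segmentation channel (default 2).
#' @param thresholds Quality thresholds, see [quality_thresholds()].
#' @return A data.frame with one row per usable segment; attribute
#'   `n_excluded` counts segments dropped by the quality gate or for
#'   having fewer than 3 annotated cycles.
#' @export
extract_feature_table <- function(cohort, cfg = pipeline_config(),
                                  seg_len_s = 10, use_truth = TRUE,
                                  channel = 2L,
                                  thresholds = quality_thresholds()) {
  rows <- list()
  n_excluded <- 0L
  for (subj in cohort) {
    rec <- preprocess_recording(subj$recording)
    for (seg in crop_segments(rec, seg_len_s)) {
      q <- assess_quality(seg, thresholds)
      if (!q$pass) { n_excluded <- n_excluded + 1L; next }
      ann <- if (use_truth) segment_states(seg, truth = subj$states)
             else segment_states(seg, channel = channel)
      if (n_cycles(ann) < 3) { n_excluded <- n_excluded + 1L; next }
      rows[[length(rows) + 1L]] <- extract_features(seg, ann, cfg)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Feature-set definition
#'
#' The five feature sets compared by the analysis: `Sin1` (one channel,
#' no entropy; 36 columns), `Sin2` (one channel with entropy; 48), `Mul1`
#' (five channels, no entropy; 180), `Mul2` (five channels with entropy;
#' 240) and `Mul3` (five channels with entropy and cross entropy; 270).
#'
#' @param id One of `"Sin1"`, `"Sin2"`, `"Mul1"`, `"Mul2"`, `"Mul3"`.
#' @param channel Channel (1-5); required for the `Sin` sets.
#' @return A list of class `feature_set_spec`.
#' @export
feature_set_spec <- function(id = c("Sin1", "Sin2", "Mul1", "Mul2", "Mul3"),
                             channel = NULL) {
  id <- match.arg(id)
  if (id %in% c("Sin1", "Sin2")) {
    if (is.null(channel)) stop("single-channel sets require a channel")
    channel <- as.integer(channel)
    stopifnot(channel %in% 1:5)
  }
  structure(list(id = id, channel = channel), class = "feature_set_spec")
}

#' Column names selected by a feature-set definition
#'
#' @param spec A [feature_set_spec()].
#' @return Character vector of feature column names.
#' @export
feature_set_columns <- function(spec) {
  base <- channel_feature_basenames()
  tf <- base[1:36]    # time + frequency
  ent <- base[37:48]  # entropy
  perch <- function(nms, chs) unlist(lapply(chs, function(c) paste0(nms, "_", c)))
  switch(spec$id,
         Sin1 = perch(tf, spec$channel),
         Sin2 = perch(c(tf, ent), spec$channel),
         Mul1 = perch(tf, 1:5),
         Mul2 = perch(c(tf, ent), 1:5),
         Mul3 = c(perch(c(tf, ent), 1:5), cross_feature_names()))
}

#' Restrict a feature table to one feature set
#'
#' @param table A feature table from [extract_feature_table()].
#' @param spec A [feature_set_spec()].
#' @return The table with metadata columns plus only the selected
#'   feature columns.
#' @export
build_feature_set <- function(table, spec) {
  cols <- feature_set_columns(spec)
  missing <- setdiff(cols, names(table))
  if (length(missing)) stop("table lacks columns: ", paste(head(missing), collapse = ", "))
  table[, c("subject_id", "label", "segment_index", cols)]
}
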