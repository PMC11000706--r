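# Zero-phase Butterworth band-pass filtering and non-overlapping segmentation.
#
# Filtering applies an order-2 band-pass Butterworth design forward and then
# backward, so the net phase response is zero and the effective magnitude
# response is the squared one-pass response (the -3 dB cutoffs become -6 dB).
# Edge transients are controlled by odd-reflection padding before the
# forward-backward pass.

#' Band-pass filter specification
#'
#' @param low_cut Low cutoff in Hz (default 0.5).
#' @param high_cut High cutoff in Hz (default 50).
#' @param order Butterworth order of the one-pass design (default 2).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 0.5, high_cut = 50, order = 2L) {
  stopifnot(low_cut > 0, high_cut > low_cut, order >= 1)
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order)),
            class = "filter_spec")
}

# padding length used before the forward-backward pass (per side);
# mirrors the common 3 * (number of filter taps - 1) rule
.filtfilt_padlen <- function(order) 3L * (2L * order)

# zero-phase IIR filtering with odd-reflection edge padding
.zero_phase_filter <- function(b, a, x, padlen) {
  n <- length(x)
  if (n <= padlen) {
    stop(sprintf("signal too short for zero-phase filtering: %d samples, need > %d",
                 n, padlen), call. = FALSE)
  }
  # odd reflection about the end points
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(pre, x, post)
  y <- signal::filter(b, a, ext)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase band-pass filter an EEG record
#'
#' Order-`order` Butterworth band-pass coefficients (from [signal::butter()])
#' applied forward then backward. Passband tones come through with no time
#' delay; the effective attenuation is the squared one-pass magnitude
#' response.
#'
#' @param record An [eeg_record()].
#' @param spec A [filter_spec()]; default is the 0.5-50 Hz order-2 design.
#' @return Filtered [eeg_record()] of identical length.
#' @export
bandpass_filter <- function(record, spec = filter_spec()) {
  stopifnot(inherits(record, "eeg_record"), inherits(spec, "filter_spec"))
  nyq <- record$fs / 2
  if (spec$high_cut >= nyq) {
    stop(sprintf("bandpass_filter: high_cut %.3g Hz >= Nyquist %.3g Hz",
                 spec$high_cut, nyq), call. = FALSE)
  }
  bt <- signal::butter(spec$order, c(spec$low_cut, spec$high_cut) / nyq,
                       type = "pass")
  y <- .zero_phase_filter(bt$b, bt$a, record$samples,
                          .filtfilt_padlen(spec$order))
  out <- record
  out$samples <- as.numeric(y)
  out
}

#' Squared magnitude response of the zero-phase band-pass design
#'
#' Utility giving the effective gain of [bandpass_filter()] at given
#' frequencies (the one-pass Butterworth magnitude, squared).
#'
#' @param freq_hz Frequencies in Hz.
#' @param fs Sampling frequency in Hz.
#' @param spec A [filter_spec()].
#' @return Numeric vector of effective amplitude gains.
#' @export
bandpass_gain <- function(freq_hz, fs = BONN_FS, spec = filter_spec()) {
  nyq <- fs / 2
  bt <- signal::butter(spec$order, c(spec$low_cut, spec$high_cut) / nyq,
                       type = "pass")
  vapply(pi * freq_hz / nyq, function(w) {
    z <- exp(-1i * w * (seq_along(bt$b) - 1))
    Mod(sum(bt$b * z) / sum(bt$a * z))^2
  }, numeric(1))
}

#' Split a record into non-overlapping segments
#'
#' Windows are anchored at the first sample; the trailing remainder
#' (`length %% seg_len` samples) is discarded.
#'
#' @param record An [eeg_record()].
#' @param seg_len Samples per segment (>= 1).
#' @return Matrix with one row per segment, `seg_len` columns. Zero rows
#'   (with a warning) if the record is shorter than `seg_len`.
#' @export
segment_signal <- function(record, seg_len) {
  stopifnot(inherits(record, "eeg_record"), seg_len >= 1)
  seg_len <- as.integer(seg_len)
  n <- length(record$samples)
  k <- n %/% seg_len
  if (k == 0L) {
    warning(sprintf("segment_signal: record '%s' shorter (%d) than seg_len %d",
                    record$source_id, n, seg_len))
    return(matrix(numeric(0), nrow = 0L, ncol = seg_len))
  }
  matrix(record$samples[seq_len(k * seg_len)], nrow = k, ncol = seg_len,
         byrow = TRUE)
}

# study table: filtering and segment length per input regime
.STUDY_TABLE <- data.frame(
  study = 1:6,
  filtered = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
  # NA = full-length signals (identity segmentation)
  seg_len = c(NA, NA, 2048L, 2048L, 178L, 178L)
)

#' Study definitions (input regime per study)
#'
#' Studies 1/2 use full-length 23.6 s signals, 3/4 use 11.8 s halves
#' (2,048 samples), 5/6 use 1 s segments (178 samples); even-numbered
#' studies band-pass filter first.
#' @return Data frame with columns `study`, `filtered`, `seg_len`.
#' @export
study_table <- function() .STUDY_TABLE

#' Assemble the task-ready segment dataset for one study
#'
#' Applies the zero-phase band-pass for even-numbered studies, segments each
#' record at the study's segment length (full length for studies 1-2), and
#' propagates each source record's class label and group id to its segments.
#'
#' @param labelled Output of [make_task()] (fields `task`, `records`,
#'   `labels`).
#' @param study Study number 1-6.
#' @param spec Band-pass [filter_spec()] used for even-numbered studies.
#' @return Object of class `segmented_dataset`: list with `segments`
#'   (n_segments x seg_len matrix), `labels`, `group_ids`, `seg_len`,
#'   `task`, `study`.
#' @export
build_study_dataset <- function(labelled, study, spec = filter_spec()) {
  stopifnot(is.list(labelled),
            all(c("task", "records", "labels") %in% names(labelled)))
  if (!study %in% 1:6) {
    stop("build_study_dataset: study must be in 1..6", call. = FALSE)
  }
  row <- .STUDY_TABLE[.STUDY_TABLE$study == study, ]
  recs <- labelled$records
  if (row$filtered) recs <- lapply(recs, bandpass_filter, spec = spec)

  seg_list <- vector("list", length(recs))
  lab_list <- vector("list", length(recs))
  gid_list <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    sl <- if (is.na(row$seg_len)) length(recs[[i]]$samples) else row$seg_len
    m <- segment_signal(recs[[i]], sl)
    seg_list[[i]] <- m
    lab_list[[i]] <- rep(labelled$labels[i], nrow(m))
    gid_list[[i]] <- rep(recs[[i]]$source_id, nrow(m))
  }
  seg_len_all <- unique(vapply(seg_list, ncol, integer(1)))
  if (length(seg_len_all) != 1L) {
    stop("build_study_dataset: records have unequal lengths under full-length segmentation",
         call. = FALSE)
  }
  structure(
    list(segments = do.call(rbind, seg_list),
         labels = unlist(lab_list),
         group_ids = unlist(gid_list),
         seg_len = seg_len_all,
         task = labelled$task,
         study = as.integer(study)),
    class = "segmented_dataset"
  )
}

#' @export
print.segmented_dataset <- function(x, ...) {
  cat(sprintf(
    "<segmented_dataset> study %d, task %s: %d segments x %d samples, %d classes\n",
    x$study, x$task$name, nrow(x$segments), x$seg_len, x$task$n_classes))
  invisible(x)
}

#' Per-segment z-score standardization (off by default in the pipeline)
#'
#' The published pipeline applies no amplitude normalization; this helper is
#' provided for experimentation only.
#'
#' @param dataset A `segmented_dataset`.
#' @return The dataset with each row standardized to mean 0, sd 1.
#' @export
zscore_segments <- function(dataset) {
  stopifnot(inherits(dataset, "segmented_dataset"))
  m <- dataset$segments
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  sdv[sdv == 0] <- 1
  dataset$segments <- (m - mu) / sdv
  dataset
}
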