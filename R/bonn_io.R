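# Reading and labelling Bonn-layout plain-text EEG records.
#
# The Bonn corpus ships five sets (A-E) of 100 single-channel records each,
# one integer sample per line, 4,097 samples per record at 173.61 Hz. On disk
# the sets are conventionally named Z, O, N, F, S; the mapping is configurable.

#' Default sampling frequency of the Bonn recordings (Hz)
#' @export
BONN_FS <- 173.61

#' Default number of samples per Bonn record
#' @export
BONN_N_POINTS <- 4097L

#' Default on-disk folder names for sets A-E
#'
#' The public distribution uses folders Z, O, N, F, S for sets A, B, C, D, E.
#' @export
BONN_FOLDER_MAP <- c(A = "Z", B = "O", C = "N", D = "F", E = "S")

#' Construct a single-channel EEG record
#'
#' @param samples Numeric vector of amplitudes (arbitrary ADC units).
#' @param fs Sampling frequency in Hz.
#' @param set_id One of `"A"`..`"E"`.
#' @param source_id String identifying the source file or synthetic seed.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs = BONN_FS, set_id, source_id = "") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("eeg_record: 'samples' must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("eeg_record: 'samples' must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("eeg_record: 'fs' must be a positive number", call. = FALSE)
  }
  set_id <- as.character(set_id)
  if (length(set_id) != 1L || !(set_id %in% c("A", "B", "C", "D", "E"))) {
    stop("eeg_record: 'set_id' must be one of A, B, C, D, E", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = fs, set_id = set_id,
         source_id = as.character(source_id)),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> set %s, %d samples @ %.2f Hz (%.1f s), source '%s'\n",
              x$set_id, length(x$samples), x$fs, length(x$samples) / x$fs,
              x$source_id))
  invisible(x)
}

#' @export
length.eeg_record <- function(x) length(x$samples)

#' Read one Bonn-dialect EEG record from a text file
#'
#' One sample per line; blank lines and surrounding whitespace are tolerated.
#'
#' @param path Path to the record file.
#' @param fs Sampling frequency in Hz.
#' @param set_id Set label to attach (`"A"`..`"E"`).
#' @param expected_length Optional expected sample count; a mismatch is an error.
#' @return An [eeg_record()].
#' @export
read_record <- function(path, fs = BONN_FS, set_id, expected_length = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("read_record: file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed)
  vals <- suppressWarnings(as.numeric(trimmed[keep]))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1L]]
    stop(sprintf("read_record: cannot parse line %d of '%s': '%s'",
                 bad, path, lines[bad]), call. = FALSE)
  }
  if (!is.null(expected_length) && length(vals) != expected_length) {
    stop(sprintf(
      "read_record: '%s' has %d samples, expected %d",
      path, length(vals), as.integer(expected_length)), call. = FALSE)
  }
  eeg_record(vals, fs = fs, set_id = set_id,
             source_id = basename(path))
}

#' Write an EEG record as a Bonn-dialect text file
#'
#' One sample per line. Integer-valued amplitudes are written without a
#' decimal point so integer records round-trip exactly.
#'
#' @param record An [eeg_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  x <- record$samples
  if (all(x == round(x))) {
    out <- format(as.integer(round(x)), scientific = FALSE, trim = TRUE)
  } else {
    out <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }
  writeLines(out, path)
  invisible(path)
}

#' Load every record of one Bonn set
#'
#' @param root Directory containing the set folders.
#' @param set_id Set label (`"A"`..`"E"`).
#' @param folder_map Named character vector mapping set labels to folder
#'   names; the default is the public distribution's Z/O/N/F/S layout. If the
#'   mapped folder is absent but a folder literally named `set_id` exists,
#'   that folder is used.
#' @param fs Sampling frequency attached to each record.
#' @param expected_length Optional per-record length check.
#' @return List of [eeg_record()]s, sorted by filename.
#' @export
load_set <- function(root, set_id, folder_map = BONN_FOLDER_MAP,
                     fs = BONN_FS, expected_length = NULL) {
  if (!dir.exists(root)) {
    stop(sprintf("load_set: directory not found: '%s'", root), call. = FALSE)
  }
  stopifnot(set_id %in% c("A", "B", "C", "D", "E"))
  dir_candidates <- unique(c(file.path(root, folder_map[[set_id]]),
                             file.path(root, set_id)))
  dir_use <- dir_candidates[dir.exists(dir_candidates)][1]
  if (is.na(dir_use)) {
    stop(sprintf("load_set: no folder for set %s under '%s' (tried %s)",
                 set_id, root, paste(basename(dir_candidates), collapse = ", ")),
         call. = FALSE)
  }
  files <- sort(list.files(dir_use, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) {
    stop(sprintf("load_set: no record files in '%s'", dir_use), call. = FALSE)
  }
  message(sprintf("load_set: set %s: %d records from '%s'",
                  set_id, length(files), dir_use))
  lapply(files, read_record, fs = fs, set_id = set_id,
         expected_length = expected_length)
}

# ---- classification tasks ---------------------------------------------------

.TASK_CLASS_MAPS <- list(
  "A-E"       = c(A = 0L, E = 1L),
  "B-E"       = c(B = 0L, E = 1L),
  "AB-CD-E"   = c(A = 0L, B = 0L, C = 1L, D = 1L, E = 2L),
  "AB-C-D-E"  = c(A = 0L, B = 0L, C = 1L, D = 2L, E = 3L),
  "A-B-C-D-E" = c(A = 0L, B = 1L, C = 2L, D = 3L, E = 4L)
)

#' Normalize a task name
#'
#' Accepts hyphen or en-dash separators (`"A-E"` and `"A–E"`).
#' @param task_name Task name string.
#' @return Canonical hyphenated name.
#' @export
normalize_task_name <- function(task_name) {
  nm <- gsub("–|—|_", "-", toupper(trimws(task_name)))
  if (!nm %in% names(.TASK_CLASS_MAPS)) {
    stop(sprintf("unknown task '%s'; expected one of %s", task_name,
                 paste(names(.TASK_CLASS_MAPS), collapse = ", ")),
         call. = FALSE)
  }
  nm
}

#' All task names
#' @return Character vector of the five task names.
#' @export
task_names <- function() names(.TASK_CLASS_MAPS)

#' Build a task specification
#'
#' A task maps Bonn sets to contiguous class indices. Class order follows the
#' task name left to right: healthy sets lowest, the seizure set E highest,
#' which fixes the confusion-matrix orientation downstream.
#'
#' @param task_name One of `"A-E"`, `"B-E"`, `"AB-CD-E"`, `"AB-C-D-E"`,
#'   `"A-B-C-D-E"` (en-dash spellings accepted).
#' @return An object of class `task_spec` with fields `name`, `class_map`
#'   (named integer vector `set_id -> class`), `n_classes`.
#' @export
task_spec <- function(task_name) {
  nm <- normalize_task_name(task_name)
  cm <- .TASK_CLASS_MAPS[[nm]]
  structure(
    list(name = nm, class_map = cm, n_classes = max(cm) + 1L),
    class = "task_spec"
  )
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec> %s (%d classes): %s\n", x$name, x$n_classes,
              paste(sprintf("%s->%d", names(x$class_map), x$class_map),
                    collapse = " ")))
  invisible(x)
}

#' Label records for a classification task
#'
#' Records from sets the task does not use are dropped (e.g. C and D for
#' task A-E). Labelling is deterministic: input order is preserved.
#'
#' @param records List of [eeg_record()]s.
#' @param task_name Task name, see [task_spec()].
#' @return List with `task` (the [task_spec()]), `records` (the retained
#'   records) and `labels` (integer class per retained record).
#' @export
make_task <- function(records, task_name) {
  task <- task_spec(task_name)
  stopifnot(all(vapply(records, inherits, logical(1), "eeg_record")))
  sets <- vapply(records, function(r) r$set_id, character(1))
  keep <- sets %in% names(task$class_map)
  records <- records[keep]
  if (length(records) == 0L) {
    stop("make_task: no records from the task's sets", call. = FALSE)
  }
  labels <- unname(task$class_map[sets[keep]])
  list(task = task, records = records, labels = labels)
}
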