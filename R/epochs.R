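#' Epoched multichannel data set
#'
#' Container for one subject/condition block of epoched signals. Data are
#' stored as a numeric array of dimension `epochs x channels x samples`;
#' labels use `+1` for left-hand and `-1` for right-hand trials throughout
#' the package (the sign convention every classifier in the pipeline relies
#' on).
#'
#' @param data numeric array, `epochs x channels x samples`.
#' @param labels integer vector of per-epoch class labels in `{+1, -1}`.
#' @param condition one of `"MI"` (motor imagery), `"PM"` (passive
#'   movement) or `"rest"`.
#' @param modality `"MEG"` or `"EEG"` (EEG gets a common-average reference
#'   downstream; MEG does not).
#' @param subject_id integer subject identifier.
#' @param sfreq sampling frequency in Hz.
#' @param t0 time of the first sample in seconds relative to cue onset
#'   (negative = pre-cue baseline).
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, condition, modality, subject_id, sfreq, t0) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  condition <- match.arg(condition, c("MI", "PM", "rest"))
  modality <- match.arg(modality, c("MEG", "EEG"))
  if (length(labels) != dim(data)[1L])
    stop("labels length must equal the number of epochs")
  if (!all(labels %in% c(1, -1)))
    stop("labels must be +1 (left) or -1 (right)")
  if (condition != "rest" && length(unique(labels)) < 2L)
    stop("MI/PM epoch sets must contain both classes")
  if (!all(is.finite(data)))
    stop("epoch data contain non-finite values")
  structure(
    list(data = data, labels = as.integer(labels), condition = condition,
         modality = modality, subject_id = as.integer(subject_id),
         sfreq = as.numeric(sfreq), t0 = as.numeric(t0)),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> subject %d, %s/%s: %d epochs x %d channels x %d samples @ %g Hz, t0 = %g s\n",
              x$subject_id, x$modality, x$condition, d[1L], d[2L], d[3L],
              x$sfreq, x$t0))
  cat(sprintf("  labels: %d left (+1), %d right (-1)\n",
              sum(x$labels == 1L), sum(x$labels == -1L)))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

# time axis of an epoch_set, seconds relative to cue
epoch_times <- function(epochs) {
  n <- dim(epochs$data)[3L]
  epochs$t0 + (seq_len(n) - 1L) / epochs$sfreq
}

# replace the data array, keeping metadata (used by the preprocessing ops)
replace_data <- function(epochs, data, sfreq = epochs$sfreq, t0 = epochs$t0) {
  epochs$data <- data
  epochs$sfreq <- sfreq
  epochs$t0 <- t0
  epochs
}
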