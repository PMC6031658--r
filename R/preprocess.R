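#' Preprocessing configuration
#'
#' Defaults follow the offline analysis chain the pipeline models: band-pass
#' 6-45 Hz, epochs cropped to -1..2 s around the cue, baseline -1..0 s,
#' decimation by 10 for the sparse-regression features, and a common-average
#' reference for EEG only.
#'
#' @param band `c(low, high)` pass band, Hz.
#' @param epoch_window crop window, seconds relative to cue.
#' @param baseline_window baseline window, seconds relative to cue; must lie
#'   within `epoch_window`.
#' @param decimation_factor keep every k-th sample for the flattened
#'   time-course features.
#' @param reference `"common_average"` (EEG) or `"none"`.
#' @return A list of class `preproc_config`.
#' @export
preproc_config <- function(band = c(6, 45),
                           epoch_window = c(-1, 2),
                           baseline_window = c(-1, 0),
                           decimation_factor = 10L,
                           reference = c("common_average", "none")) {
  reference <- match.arg(reference)
  if (band[1L] >= band[2L]) stop("preproc_config: band low must be < high")
  if (baseline_window[1L] < epoch_window[1L] ||
      baseline_window[2L] > epoch_window[2L])
    stop("preproc_config: baseline_window must lie within epoch_window")
  if (decimation_factor < 1L) stop("preproc_config: decimation_factor >= 1")
  structure(list(band = band, epoch_window = epoch_window,
                 baseline_window = baseline_window,
                 decimation_factor = as.integer(decimation_factor),
                 reference = reference),
            class = "preproc_config")
}

# apply an FFT-domain gain curve per channel to one epoch (samples x channels)
fft_filter_matrix <- function(x, gain) {
  n <- nrow(x)
  X <- stats::mvfft(x) * gain
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

# two-sided brick-wall gain for a pass band, length n at sampling rate sfreq
bandpass_gain <- function(n, sfreq, band) {
  f <- (seq_len(n) - 1L) * sfreq / n
  f <- pmin(f, sfreq - f)
  as.numeric(f >= band[1L] & f <= band[2L])
}

#' Zero-phase FFT band-pass filter
#'
#' Filters every epoch and channel with an FFT-domain FIR whose length
#' equals the epoch length: the epoch spectrum is multiplied by a real
#' (zero-phase) pass-band response, so ERD timing is not shifted. Shape and
#' metadata are unchanged.
#'
#' @param epochs an [epoch_set()].
#' @param band `c(low, high)` in Hz; `high` must be below Nyquist.
#' @return The filtered [epoch_set()].
#' @export
bandpass <- function(epochs, band = c(6, 45)) {
  if (band[2L] >= epochs$sfreq / 2)
    stop("bandpass: band upper edge must be below Nyquist")
  if (band[1L] >= band[2L]) stop("bandpass: band low must be < high")
  d <- epochs$data
  n <- dim(d)[3L]
  gain <- bandpass_gain(n, epochs$sfreq, band)
  out <- d
  for (e in seq_len(dim(d)[1L]))
    out[e, , ] <- t(fft_filter_matrix(t(d[e, , , drop = TRUE]), gain))
  replace_data(epochs, out)
}

#' Crop epochs and subtract the baseline mean
#'
#' Epochs are cropped to `window` and the per-channel mean over
#' `baseline` is subtracted from the whole epoch (standard baseline
#' correction: the pre-cue DC level defines zero).
#'
#' @param epochs an [epoch_set()].
#' @param window,baseline `c(start, end)` seconds relative to cue; both
#'   must lie within the recorded span and `baseline` within `window`.
#' @return The cropped, baseline-corrected [epoch_set()].
#' @export
crop_baseline <- function(epochs, window = c(-1, 2), baseline = c(-1, 0)) {
  t <- epoch_times(epochs)
  keep <- which(t >= window[1L] - 1e-9 & t < window[2L] - 1e-9)
  if (length(keep) == 0L) stop("crop_baseline: window outside recorded span")
  bl <- which(t >= baseline[1L] - 1e-9 & t < baseline[2L] - 1e-9)
  if (length(bl) == 0L) stop("crop_baseline: empty baseline window")
  d <- epochs$data
  mu <- apply(d[, , bl, drop = FALSE], c(1L, 2L), mean)
  out <- d[, , keep, drop = FALSE] - as.vector(mu)  # recycles over samples
  replace_data(epochs, out, t0 = t[keep[1L]])
}

#' Common-average reference
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so
#' channel values sum to zero. Intended for EEG; on MEG data it warns and
#' returns the input unchanged (the reference electrode concept does not
#' apply to gradiometers).
#'
#' @param epochs an [epoch_set()].
#' @return The re-referenced [epoch_set()].
#' @export
common_average_reference <- function(epochs) {
  if (epochs$modality != "EEG") {
    warning("common_average_reference: non-EEG modality, returning input unchanged")
    return(epochs)
  }
  d <- epochs$data
  m <- apply(d, c(1L, 3L), mean)              # epochs x samples
  for (ch in seq_len(dim(d)[2L])) d[, ch, ] <- d[, ch, ] - m
  replace_data(epochs, d)
}

#' Decimate epochs by strided sample selection
#'
#' Keeps every `factor`-th sample starting at the first one (no additional
#' anti-alias filtering: the data are assumed already low-passed well below
#' the decimated Nyquist, as after the 6-45 Hz band-pass). The sampling rate
#' is divided by `factor`.
#'
#' @param epochs an [epoch_set()].
#' @param factor positive integer stride.
#' @return The decimated [epoch_set()].
#' @export
decimate_epochs <- function(epochs, factor = 10L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("decimate_epochs: factor must be >= 1")
  n <- dim(epochs$data)[3L]
  if (factor > n) stop("decimate_epochs: factor exceeds epoch length")
  if (factor == 1L) return(epochs)
  keep <- seq(1L, n, by = factor)
  replace_data(epochs, epochs$data[, , keep, drop = FALSE],
               sfreq = epochs$sfreq / factor)
}

#' Run the standard preprocessing chain on one epoch set
#'
#' Band-pass filter, optional common-average reference (EEG), then crop and
#' baseline-correct. Decimation is not applied here: it belongs to the
#' sparse-regression feature path only.
#'
#' @param epochs an [epoch_set()].
#' @param cfg a [preproc_config()].
#' @return The preprocessed [epoch_set()].
#' @export
preprocess_epochs <- function(epochs, cfg = preproc_config()) {
  out <- bandpass(epochs, cfg$band)
  if (cfg$reference == "common_average" && epochs$modality == "EEG")
    out <- common_average_reference(out)
  crop_baseline(out, cfg$epoch_window, cfg$baseline_window)
}
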