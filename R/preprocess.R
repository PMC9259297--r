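#' Filter specification for EEG preprocessing
#'
#' Parameters of the two IIR cleaning stages: a narrow band-stop (notch)
#' filter at the mains frequency and a Butterworth band-pass isolating the
#' low-frequency band where blink artifacts live (1-12 Hz). Both filters are
#' applied forward-backward (zero phase), so event markers stay aligned with
#' the waveforms they tag.
#'
#' @param notch_freq mains frequency to suppress, Hz (default 60).
#' @param notch_q dimensionless quality factor of the notch; the stop band is
#'   `notch_freq / notch_q` wide (default 30, i.e. a 2 Hz band at 60 Hz).
#' @param band_low,band_high band-pass edges in Hz (defaults 1 and 12).
#' @param order Butterworth band-pass order (default 4).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(notch_freq = 60, notch_q = 30,
                        band_low = 1, band_high = 12, order = 4) {
  if (band_low <= 0 || band_high <= band_low)
    stop("need 0 < band_low < band_high")
  if (notch_q <= 0) stop("`notch_q` must be positive")
  if (order < 1) stop("`order` must be >= 1")
  structure(list(notch_freq = notch_freq, notch_q = notch_q,
                 band_low = band_low, band_high = band_high, order = order),
            class = "filter_spec")
}

apply_channelwise <- function(rec, filt) {
  out <- rec
  out$data <- t(apply(rec$data, 1L, filt))
  if (n_samples(rec) == 1L) out$data <- matrix(out$data, nrow = n_channels(rec))
  out
}

#' Mains notch filter
#'
#' Suppresses a narrow band around the mains frequency (50/60 Hz interference
#' from the amplifier and environment) with a second-order Butterworth
#' band-stop applied forward-backward, leaving the rest of the spectrum and
#' all marker positions untouched.
#'
#' @param rec an [eeg_recording()].
#' @param spec a [filter_spec()].
#' @return A new `eeg_recording` with the filtered signal.
#' @export
notch_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (spec$notch_freq >= nyq)
    stop("notch frequency ", spec$notch_freq,
         " Hz is not below the Nyquist frequency ", nyq, " Hz")
  bw <- spec$notch_freq / spec$notch_q
  edges <- c(spec$notch_freq - bw / 2, spec$notch_freq + bw / 2) / nyq
  ba <- signal::butter(2, edges, type = "stop")
  apply_channelwise(rec, function(x) signal::filtfilt(ba, x))
}

#' Band-pass filter
#'
#' Isolates the configured frequency band (1-12 Hz by default, covering the
#' low-frequency range contaminated by eye blinks) with a Butterworth
#' band-pass applied forward-backward.
#'
#' @inheritParams notch_filter
#' @return A new `eeg_recording` with the filtered signal.
#' @export
bandpass_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (spec$band_high >= nyq)
    stop("band edge ", spec$band_high,
         " Hz is not below the Nyquist frequency ", nyq, " Hz")
  ba <- signal::butter(spec$order,
                       c(spec$band_low, spec$band_high) / nyq, type = "pass")
  apply_channelwise(rec, function(x) signal::filtfilt(ba, x))
}

#' Per-channel min-max normalization
#'
#' Rescales every channel independently to `[0, 1]`:
#' `x' = (x - min) / (max - min)`, with the extremes taken over the reference
#' samples of that channel. By default the reference is the full channel; a
#' leading portion can be used instead (e.g. the training segment only) to
#' avoid using validation samples when computing the scaling constants.
#'
#' @param rec an [eeg_recording()].
#' @param reference_samples optional integer: use only the first
#'   `reference_samples` samples of each channel to compute min and max
#'   (values outside the reference range may then fall outside `[0, 1]`).
#' @return A new `eeg_recording` with normalized values.
#' @export
minmax_normalize <- function(rec, reference_samples = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  ref <- if (is.null(reference_samples)) rec$data
         else rec$data[, seq_len(reference_samples), drop = FALSE]
  mins <- apply(ref, 1L, min)
  maxs <- apply(ref, 1L, max)
  flat <- maxs - mins <= 0
  if (any(flat))
    stop("degenerate (constant) channel(s): ",
         paste(rec$channel_labels[flat], collapse = ", "))
  out <- rec
  out$data <- (rec$data - mins) / (maxs - mins)
  out
}

#' Standard preprocessing chain
#'
#' Applies, in order: mains notch, band-pass, and per-channel min-max
#' normalization. The order is fixed; each stage preserves the recording's
#' shape, sampling rate, and markers.
#'
#' @inheritParams notch_filter
#' @param normalize_scope `"full"` (default) computes the min-max reference
#'   over the whole recording; `"train_only"` restricts it to the first
#'   `train_frac` fraction of samples.
#' @param train_frac fraction used when `normalize_scope = "train_only"`.
#' @return A preprocessed `eeg_recording`.
#' @export
preprocess <- function(rec, spec = filter_spec(),
                       normalize_scope = c("full", "train_only"),
                       train_frac = 0.7) {
  normalize_scope <- match.arg(normalize_scope)
  rec <- notch_filter(rec, spec)
  rec <- bandpass_filter(rec, spec)
  ref <- if (normalize_scope == "train_only")
    max(1L, floor(train_frac * n_samples(rec))) else NULL
  minmax_normalize(rec, reference_samples = ref)
}
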