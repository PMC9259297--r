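#' Default 10-20 channel montage
#'
#' Channel labels of the eight-electrode montage used throughout: prefrontal
#' Fp1/Fp2, frontal F3/F4, parietal P1/P2, and occipital O1/O2.
#'
#' @export
DEFAULT_CHANNELS <- c("Fp1", "Fp2", "F3", "F4", "P1", "P2", "O1", "O2")

#' Construct an EEG recording
#'
#' The canonical in-memory container for a multichannel EEG: a channel-major
#' voltage matrix, a sampling rate, channel labels, and a set of event
#' markers. All sample indices in this package are 1-based, and window
#' intervals are half-open: a window starting at `s` of size `w` covers
#' samples `s, ..., s + w - 1`.
#'
#' @param data numeric matrix of voltages in microvolts, `n_channels` rows by
#'   `n_samples` columns.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of unique channel names; defaults to
#'   the first `n_channels` entries of [DEFAULT_CHANNELS] when there are at
#'   most eight channels, positional labels otherwise.
#' @param markers integer vector of 1-based sample indices of labelled events,
#'   or a data frame with columns `sample_index` and (optionally) `label`.
#' @param marker_labels optional character vector of event labels, recycled to
#'   the marker count; defaults to `"blink"`.
#'
#' @return An object of class `eeg_recording` with elements `data`, `fs`,
#'   `channel_labels`, and `markers` (a data frame with `sample_index` and
#'   `label`, sorted ascending by `sample_index`).
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL, markers = integer(),
                          marker_labels = "blink") {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  dimnames(data) <- NULL
  n_ch <- nrow(data)
  n_s <- ncol(data)
  if (n_ch < 1L || n_s < 1L)
    stop("recording must have at least one channel and one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (is.null(channel_labels)) {
    channel_labels <- if (n_ch <= length(DEFAULT_CHANNELS))
      DEFAULT_CHANNELS[seq_len(n_ch)] else paste0("Ch", seq_len(n_ch))
  }
  if (length(channel_labels) != n_ch || anyDuplicated(channel_labels))
    stop("`channel_labels` must be unique and match the number of channels")

  if (is.data.frame(markers)) {
    if (!"sample_index" %in% names(markers))
      stop("marker data frame needs a `sample_index` column")
    idx <- markers$sample_index
    lab <- if ("label" %in% names(markers)) as.character(markers$label)
           else rep_len(marker_labels, length(idx))
  } else {
    idx <- markers
    lab <- rep_len(marker_labels, length(idx))
  }
  idx <- as.integer(idx)
  if (length(idx) && (anyNA(idx) || any(idx < 1L) || any(idx > n_s)))
    stop("marker sample indices must lie in [1, n_samples] = [1, ", n_s, "]")
  ord <- order(idx)
  mk <- data.frame(sample_index = idx[ord],
                   label = if (length(idx)) lab[ord] else character(),
                   stringsAsFactors = FALSE)

  structure(
    list(data = data, fs = fs, channel_labels = channel_labels, markers = mk),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              n_channels(x), n_samples(x), x$fs, n_samples(x) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  cat(sprintf("  markers:  %d event(s)\n", nrow(x$markers)))
  invisible(x)
}

#' Recording dimensions
#'
#' @param rec an [eeg_recording()].
#' @return Integer count of channels or samples.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Read an EEG recording from CSV files
#'
#' Reads a signal CSV (one row per sample, one numeric column per channel,
#' optional header row of channel labels) and a sidecar marker file (one
#' 1-based sample index per line, optionally followed by a label column).
#' Markers are returned sorted ascending regardless of file order.
#'
#' @param csv_path path to the signal CSV.
#' @param marker_path path to the marker file; `NULL` or a missing/empty file
#'   yields a recording with no markers.
#' @param fs sampling rate in Hz (default 250).
#' @return An [eeg_recording()].
#' @export
read_eeg_recording <- function(csv_path, marker_path = NULL, fs = 250) {
  if (!file.exists(csv_path)) stop("signal file not found: ", csv_path)
  first <- readLines(csv_path, n = 1L)
  cells <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(cells)))
  df <- utils::read.csv(csv_path, header = has_header,
                        colClasses = "character",
                        stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 1L || nrow(df) < 1L) stop("signal file is empty: ", csv_path)
  num <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(df)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell in %s at row %d, column %d ('%s')",
                 csv_path, bad[1L] + has_header, bad[2L],
                 df[bad[1L], bad[2L]]))
  }
  labels <- if (has_header) colnames(df) else NULL
  markers <- read_markers(marker_path)
  eeg_recording(t(num), fs = fs, channel_labels = labels, markers = markers)
}

read_markers <- function(marker_path) {
  if (is.null(marker_path) || !file.exists(marker_path) ||
      file.size(marker_path) == 0)
    return(data.frame(sample_index = integer(), label = character(),
                      stringsAsFactors = FALSE))
  lines <- readLines(marker_path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(sample_index = integer(), label = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, ",", fixed = TRUE)
  # optional header line
  if (is.na(suppressWarnings(as.numeric(parts[[1]][1])))) {
    parts <- parts[-1]
    if (!length(parts))
      return(data.frame(sample_index = integer(), label = character(),
                        stringsAsFactors = FALSE))
  }
  idx <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  if (anyNA(idx))
    stop("non-numeric marker index at line ", which(is.na(idx))[1L],
         " of ", marker_path)
  lab <- vapply(parts, function(p) if (length(p) > 1L) trimws(p[2L]) else "blink", "")
  data.frame(sample_index = as.integer(idx), label = lab,
             stringsAsFactors = FALSE)
}

#' Write an EEG recording to CSV files
#'
#' Inverse of [read_eeg_recording()]: the signal goes to a CSV with a header
#' row of channel labels and one row per sample; markers go to a sidecar CSV
#' with columns `sample_index,label`. A read-back reproduces markers exactly
#' and voltages to formatting precision (15 significant digits).
#'
#' @param rec an [eeg_recording()].
#' @param csv_path output path for the signal CSV.
#' @param marker_path output path for the marker file.
#' @return Invisibly, `rec`.
#' @export
write_eeg_recording <- function(rec, csv_path, marker_path) {
  stopifnot(inherits(rec, "eeg_recording"))
  sig <- as.data.frame(t(rec$data))
  names(sig) <- rec$channel_labels
  utils::write.csv(format(sig, digits = 15, trim = TRUE, scientific = FALSE),
                   csv_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(rec$markers, marker_path, row.names = FALSE, quote = FALSE)
  invisible(rec)
}
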