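#' Split a recording into training and validation parts by event count
#'
#' The leading segment of the recording that encompasses the first
#' `round(train_frac * n_events)` markers becomes the training recording; the
#' remainder (with its markers re-based) becomes the validation recording.
#' The cut falls at the midpoint between the last training marker and the
#' first validation marker, the natural sample-level boundary between the two
#' event groups.
#'
#' @param rec an [eeg_recording()] with at least one marker.
#' @param train_frac fraction of events assigned to training (default 0.7).
#' @return A list with elements `train` and `validation`, both
#'   `eeg_recording` objects.
#' @export
split_by_events <- function(rec, train_frac = 0.7) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_ev <- nrow(rec$markers)
  if (n_ev < 1L) stop("cannot split a recording with no markers")
  if (train_frac <= 0 || train_frac >= 1)
    stop("`train_frac` must lie strictly between 0 and 1")
  k <- round(train_frac * n_ev)
  k <- min(max(k, 1L), n_ev)
  m <- rec$markers$sample_index
  cut <- if (k < n_ev) floor((m[k] + m[k + 1L]) / 2) else
    floor((m[k] + n_samples(rec) + 1L) / 2)
  cut <- max(cut, m[k] + 1L)  # cut is the first sample of the validation part

  tr_mk <- rec$markers[m < cut, , drop = FALSE]
  va_mk <- rec$markers[m >= cut, , drop = FALSE]
  va_mk$sample_index <- va_mk$sample_index - (cut - 1L)
  train <- eeg_recording(rec$data[, seq_len(cut - 1L), drop = FALSE], rec$fs,
                         rec$channel_labels, tr_mk)
  validation <- eeg_recording(
    rec$data[, cut:n_samples(rec), drop = FALSE], rec$fs,
    rec$channel_labels, va_mk)
  list(train = train, validation = validation)
}

window_stride <- function(size, overlap) {
  if (overlap < 0 || overlap >= 1)
    stop("`overlap` must lie in [0, 1)")
  max(1L, as.integer(round(size * (1 - overlap))))
}

# Extract windows at the given 1-based start samples and flatten channel-major
# (all samples of channel 1, then channel 2, ...). Returns n_windows x
# (n_channels * size).
extract_windows <- function(data, starts, size) {
  nw <- length(starts)
  n_ch <- nrow(data)
  if (!nw) return(matrix(numeric(), 0L, n_ch * size))
  idx <- outer(starts, 0:(size - 1L), `+`)
  do.call(cbind, lapply(seq_len(n_ch), function(ch)
    matrix(data[ch, idx], nw, size)))
}

markers_in_window <- function(marker_idx, start, size) {
  which(marker_idx >= start & marker_idx < start + size)
}

new_window_dataset <- function(X, label, start, marker_ids, size, overlap,
                               role, channel_labels) {
  structure(list(X = X, label = as.integer(label), start = as.integer(start),
                 marker_ids = marker_ids, size = as.integer(size),
                 overlap = overlap, role = role,
                 channel_labels = channel_labels),
            class = "window_dataset")
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf("window dataset (%s): %d windows of %d samples x %d channels, overlap %.0f%%\n",
              x$role, nrow(x$X), x$size, length(x$channel_labels),
              100 * x$overlap))
  cat(sprintf("  positives: %d  negatives: %d\n",
              sum(x$label == 1L), sum(x$label == 0L)))
  invisible(x)
}

#' Event-centred training windows
#'
#' Builds the training set: each marker becomes the centre of one positive
#' window, the union of those window ranges is removed from the signal, and
#' every remaining contiguous run is cut into negative windows of the same
#' size advancing by `stride = round(size * (1 - overlap))`. Markers too
#' close to an edge for a centred window are skipped with a warning, and
#' their (clipped) neighbourhood is still excluded from the negative runs so
#' no negative window contains an event.
#'
#' @param rec an [eeg_recording()].
#' @param size window length in samples (default 250).
#' @param overlap fractional overlap of consecutive negative windows in
#'   `[0, 1)` (default 0).
#' @return A `window_dataset` with `role = "train"`. Positive windows come
#'   first (in marker order), then negatives in positional order.
#' @export
make_training_set <- function(rec, size = 250, overlap = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- n_samples(rec)
  if (size > n) stop("window size ", size, " exceeds recording length ", n)
  stride <- window_stride(size, overlap)
  half <- floor(size / 2)
  m <- rec$markers$sample_index

  pos_start <- m - half
  usable <- pos_start >= 1L & pos_start + size - 1L <= n
  if (any(!usable))
    warning(sum(!usable), " marker(s) too close to a recording edge to centre",
            " a window of size ", size, "; skipped")

  removed <- rep(FALSE, n)
  for (i in seq_along(m)) {  # clip skipped markers' ranges to the recording
    lo <- max(1L, pos_start[i])
    hi <- min(n, pos_start[i] + size - 1L)
    removed[lo:hi] <- TRUE
  }

  starts_pos <- pos_start[usable]
  mk_pos <- lapply(starts_pos, function(s) markers_in_window(m, s, size))

  # maximal runs of un-removed samples
  keep <- !removed
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  run_b <- begins[r$values]
  run_e <- ends[r$values]
  starts_neg <- integer()
  for (j in seq_along(run_b)) {
    L <- run_e[j] - run_b[j] + 1L
    if (L >= size)
      starts_neg <- c(starts_neg,
                      run_b[j] + seq(0L, L - size, by = stride))
  }

  starts <- c(starts_pos, starts_neg)
  X <- extract_windows(rec$data, starts, size)
  label <- c(rep(1L, length(starts_pos)), rep(0L, length(starts_neg)))
  marker_ids <- c(mk_pos, rep(list(integer()), length(starts_neg)))
  new_window_dataset(X, label, starts, marker_ids, size, overlap, "train",
                     rec$channel_labels)
}

#' Overlapped sliding windows
#'
#' Segments the whole recording into consecutive windows starting at
#' `1, 1 + stride, 1 + 2 * stride, ...` while the window fits. Each window is
#' labelled 1 iff at least one marker falls inside its half-open range;
#' `marker_ids` records which, so a single marker may appear in several
#' consecutive overlapping windows. Used for validation and test sets, where
#' the recording is scanned the way a real-time detector would.
#'
#' @inheritParams make_training_set
#' @param role `"validation"` (default) or `"test"`.
#' @return A `window_dataset`.
#' @export
make_sliding_set <- function(rec, size = 250, overlap = 0,
                             role = c("validation", "test")) {
  stopifnot(inherits(rec, "eeg_recording"))
  role <- match.arg(role)
  n <- n_samples(rec)
  if (size > n) stop("window size ", size, " exceeds recording length ", n)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must lie in [0, 1)")
  stride <- as.integer(round(size * (1 - overlap)))
  if (stride < 1L)
    stop("overlap ", overlap, " gives a zero stride at window size ", size)

  starts <- seq(1L, n - size + 1L, by = stride)
  m <- rec$markers$sample_index
  marker_ids <- lapply(starts, function(s) markers_in_window(m, s, size))
  label <- as.integer(lengths(marker_ids) > 0L)
  X <- extract_windows(rec$data, starts, size)
  new_window_dataset(X, label, starts, marker_ids, size, overlap, role,
                     rec$channel_labels)
}
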