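# Small deterministic fixtures used across test files.

# Sine-wave recording: one channel per frequency, optional markers.
sine_recording <- function(freqs, fs = 250, seconds = 4, markers = integer()) {
  tt <- (seq_len(fs * seconds) - 1) / fs
  data <- t(vapply(freqs, function(f) sin(2 * pi * f * tt), tt))
  eeg_recording(data, fs, channel_labels = paste0("S", seq_along(freqs)),
                markers = markers)
}

# White-noise recording with markers at given positions.
noise_recording <- function(n_channels = 2, n = 1000, markers = integer(),
                            seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_channels * n), n_channels, n), fs = 250,
                channel_labels = paste0("N", seq_len(n_channels)),
                markers = markers)
}

# FFT amplitude at a single frequency (independent spectral oracle).
fft_amplitude <- function(x, freq, fs) {
  n <- length(x)
  bin <- round(freq * n / fs) + 1L
  abs(fft(x))[bin] * 2 / n
}

# Brute-force window enumeration oracle for the training segmentation:
# returns the expected negative-window start positions given marker-centred
# removal, by literal scanning.
enumerate_training_windows <- function(n, marker_pos, size, overlap) {
  stride <- max(1L, as.integer(round(size * (1 - overlap))))
  half <- floor(size / 2)
  removed <- rep(FALSE, n)
  pos_starts <- integer()
  for (m in marker_pos) {
    s <- m - half
    if (s >= 1L && s + size - 1L <= n) pos_starts <- c(pos_starts, s)
    lo <- max(1L, s); hi <- min(n, s + size - 1L)
    removed[lo:hi] <- TRUE
  }
  neg_starts <- integer()
  run_start <- NA_integer_
  for (i in seq_len(n + 1L)) {
    inside <- i <= n && !removed[i]
    if (inside && is.na(run_start)) run_start <- i
    if (!inside && !is.na(run_start)) {
      run_len <- i - run_start
      if (run_len >= size) {
        s <- run_start
        while (s + size - 1L <= run_start + run_len - 1L) {
          neg_starts <- c(neg_starts, s)
          s <- s + stride
        }
      }
      run_start <- NA_integer_
    }
  }
  list(pos = pos_starts, neg = neg_starts)
}

# Reference MLP forward pass written independently (plain loops over units).
reference_forward <- function(weights, x) {
  a <- x
  for (l in 1:2) {
    z <- drop(a %*% weights[[l]]$W) + weights[[l]]$b
    a <- ifelse(z > 0, z, 0)
  }
  z <- drop(a %*% weights[[3]]$W) + weights[[3]]$b
  1 / (1 + exp(-z))
}
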