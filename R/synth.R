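#' Synthetic EEG configuration
#'
#' Parameters of the synthetic 8-channel EEG generator. The background model
#' is white Gaussian noise plus a 10 Hz oscillatory component per channel;
#' mains interference is an additive 60 Hz sinusoid on every channel (so the
#' notch stage has real work to do); each eye blink is a large positive
#' half-sine deflection confined to the frontal channels, with a marker at
#' its peak. Amplitude defaults are in the range a practitioner would call
#' typical for scalp EEG: background of ~10 uV RMS, tens of uV of line
#' interference, and blink artifacts of a couple of hundred uV on Fp1/Fp2.
#'
#' @param n_channels number of channels (default 8).
#' @param fs sampling rate, Hz (default 250).
#' @param duration recording length in seconds (default 120; ignored when
#'   `n_samples` is given).
#' @param n_samples exact sample count; overrides `duration`.
#' @param n_events number of blink events (default 40, i.e. one blink every
#'   three seconds, within the range of the reference capture sessions).
#' @param blink_channels channel indices carrying the blink artifact
#'   (default `c(1, 2)`, the Fp1/Fp2 pair).
#' @param blink_amplitude blink pulse peak amplitude, uV (default 200).
#' @param blink_width blink pulse width, ms (default 400; the full
#'   closure-plus-opening deflection of a deliberate blink).
#' @param background_sd white-noise standard deviation, uV (default 10).
#' @param osc_amp amplitude of the 10 Hz background oscillation, uV
#'   (default 10).
#' @param line_amp amplitude of the 60 Hz mains component, uV (default 20).
#' @param min_gap minimum spacing between consecutive markers, samples
#'   (default 500, i.e. two seconds at 250 Hz).
#' @param transient_rate rate (per second) of single-electrode transient
#'   artifacts: blink-sized half-sine deflections of 150-400 ms placed on one
#'   random channel at a time, emulating electrode pops and motion artifacts
#'   (default 1). These are what make a lone frontal channel an unreliable
#'   blink detector: a deflection on one electrode only is noise, a joint
#'   deflection on both frontal electrodes is a blink.
#' @param seed RNG seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 8, fs = 250, duration = 120,
                         n_samples = NULL, n_events = 40,
                         blink_channels = c(1, 2), blink_amplitude = 200,
                         blink_width = 400, background_sd = 10, osc_amp = 10,
                         line_amp = 20, min_gap = 500, transient_rate = 1,
                         seed = 1) {
  n <- if (is.null(n_samples)) as.integer(round(duration * fs))
       else as.integer(n_samples)
  if (any(blink_channels < 1) || any(blink_channels > n_channels))
    stop("`blink_channels` must be valid channel indices")
  structure(list(n_channels = as.integer(n_channels), fs = fs, n_samples = n,
                 n_events = as.integer(n_events),
                 blink_channels = as.integer(blink_channels),
                 blink_amplitude = blink_amplitude, blink_width = blink_width,
                 background_sd = background_sd, osc_amp = osc_amp,
                 line_amp = line_amp, min_gap = as.integer(min_gap),
                 transient_rate = transient_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# n_events marker positions in [margin, n - margin], pairwise gaps >= min_gap
place_markers <- function(n, n_events, min_gap, margin) {
  if (!n_events) return(integer())
  slack <- (n - 2 * margin) - (n_events - 1) * min_gap
  if (slack < 0)
    stop("cannot place ", n_events, " events with minimum gap ", min_gap,
         " in ", n, " samples")
  u <- sort(stats::runif(n_events, 0, slack))
  as.integer(round(margin + u + (seq_len(n_events) - 1) * min_gap))
}

#' Generate a synthetic EEG recording with ground-truth blinks
#'
#' @param cfg a [synth_config()].
#' @return An [eeg_recording()] whose markers sit at the blink pulse peaks.
#' @export
generate_eeg <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    tt <- (seq_len(n) - 1) / cfg$fs
    width <- as.integer(round(cfg$blink_width / 1000 * cfg$fs))
    margin <- max(cfg$fs, width)  # keeps centred windows and pulses in-range
    markers <- place_markers(n, cfg$n_events, cfg$min_gap, margin)

    line <- cfg$line_amp * sin(2 * pi * 60 * tt + stats::runif(1, 0, 2 * pi))
    data <- matrix(0, cfg$n_channels, n)
    for (ch in seq_len(cfg$n_channels)) {
      data[ch, ] <- stats::rnorm(n, 0, cfg$background_sd) +
        cfg$osc_amp * sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi)) +
        line
    }

    n_trans <- as.integer(round(cfg$transient_rate * n / cfg$fs))
    if (n_trans > 0L) {
      for (k in seq_len(n_trans)) {
        tw <- as.integer(round(stats::runif(1, 0.150, 0.400) * cfg$fs))
        tch <- sample.int(cfg$n_channels, 1L)
        tstart <- sample.int(n - tw, 1L)
        tamp <- cfg$blink_amplitude * stats::runif(1, 0.6, 1.2)
        data[tch, tstart:(tstart + tw - 1L)] <-
          data[tch, tstart:(tstart + tw - 1L)] +
          tamp * sin(pi * (0:(tw - 1L)) / (tw - 1L))
      }
    }

    if (width >= 2L) {
      pulse <- cfg$blink_amplitude * sin(pi * (0:(width - 1L)) / (width - 1L))
      half <- floor(width / 2)
      for (m in markers) {
        span <- (m - half):(m - half + width - 1L)
        data[cfg$blink_channels, span] <-
          sweep(data[cfg$blink_channels, span, drop = FALSE], 2L, pulse, `+`)
      }
    }
    eeg_recording(data, cfg$fs, markers = markers)
  })
}

#' Synthetic two-session problem suite
#'
#' Emits four pairs of recordings (a long first-session recording `A` used
#' for training/validation and a shorter second-session recording `B` used
#' for testing) whose event and sample counts match the acquisition
#' statistics of the reference capture campaign: A recordings of 120k-183k
#' samples with 27-218 events, B recordings of ~60k samples with 12-129
#' events.
#'
#' @param seed master seed; each recording derives its own sub-seed.
#' @param min_gap marker spacing in samples (default 250: the densest
#'   reference session has ~2 blinks per second of margin, so a one-second
#'   floor keeps the campaign's event counts feasible).
#' @param ... further arguments passed to [synth_config()] (e.g. amplitudes).
#' @return A list of four elements, each `list(A = , B = )` of
#'   [eeg_recording()]s.
#' @export
make_problem_suite <- function(seed = 1, min_gap = 250, ...) {
  specs <- list(
    list(A = c(183L, 183114L), B = c(129L, 60123L)),
    list(A = c(218L, 120123L), B = c(63L, 63114L)),
    list(A = c(66L, 183087L), B = c(12L, 60114L)),
    list(A = c(27L, 120114L), B = c(22L, 63087L))
  )
  out <- lapply(seq_along(specs), function(i) {
    mk <- function(ev_n, sub) {
      cfg <- synth_config(n_events = ev_n[1L], n_samples = ev_n[2L],
                          min_gap = min_gap,
                          seed = (seed * 8L + sub) %% 2147483629L, ...)
      generate_eeg(cfg)
    }
    list(A = mk(specs[[i]]$A, 2L * i - 1L), B = mk(specs[[i]]$B, 2L * i))
  })
  names(out) <- paste0("problem", seq_along(out))
  out
}
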