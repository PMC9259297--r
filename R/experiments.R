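#' Multi-run feature-extraction experiment
#'
#' Runs the full selection pipeline `n_runs` times with independent seeds on
#' each recording and tabulates, per run, the best solution's overlap, the
#' per-channel selected-feature counts, the total, and the validation
#' confusion counts and metrics. Rows are sorted ascending by F1 and then by
#' total selected features, mirroring the double sort used when ranking
#' solutions (F1 is maximized; among equal F1, sparser subsets rank higher).
#'
#' @param recordings a list of [eeg_recording()]s (session-A recordings), or
#'   a single recording.
#' @param n_runs independent runs per recording (default 5).
#' @param seed master seed; run `r` of recording `i` uses a sub-seed derived
#'   from it by counter.
#' @param ... settings forwarded to [eegselect()] (GA scale, window size,
#'   classifier settings, ...).
#' @return A list of `experiment_report` objects, one per recording, each
#'   with `rows` (the sorted per-run table), `summary` (a
#'   [summarize_runs()] over the totals), `best_row` (index chosen by
#'   [pick_best_solution()]), and `fits` (the per-run [eegselect()] objects,
#'   in row order).
#' @export
experiment1 <- function(recordings, n_runs = 5, seed = 1, ...) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    fits <- lapply(seq_len(n_runs), function(r) {
      eegselect(rec, seed = (seed + 1000L * i + r) %% 2147483629L, ...)
    })
    experiment_report(fits)
  })
}

#' Tabulate a set of fitted selectors
#'
#' @param fits list of [eegselect()] objects on the same recording.
#' @return An `experiment_report`; see [experiment1()].
#' @export
experiment_report <- function(fits) {
  labels <- fits[[1L]]$channel_labels
  full_input <- fits[[1L]]$window_size * length(labels)
  rows <- do.call(rbind, lapply(fits, function(f) {
    counts <- as.list(f$phenotype$per_channel)
    names(counts) <- labels
    cbind(data.frame(overlap_pct = f$phenotype$overlap_pct),
          as.data.frame(counts, check.names = FALSE),
          data.frame(total = f$phenotype$total_selected,
                     TP = f$validation$TP, FP = f$validation$FP,
                     TN = f$validation$TN, FN = f$validation$FN,
                     PPV = f$validation$PPV, TPR = f$validation$TPR,
                     F1 = f$validation$F1))
  }))
  ord <- order(rows$F1, rows$total)
  rows <- rows[ord, , drop = FALSE]
  fits <- fits[ord]
  rows$channels <- lapply(fits, function(f) f$phenotype$active_channels)
  rownames(rows) <- NULL
  structure(list(rows = rows,
                 summary = summarize_runs(rows$total, full_input),
                 best_row = pick_best_solution(rows),
                 fits = fits),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Feature-extraction experiment:", nrow(x$rows), "run(s)\n")
  print(x$rows[, setdiff(names(x$rows), "channels")], digits = 6)
  print(x$summary)
  cat("best row (analyst criteria):", x$best_row, "\n")
  invisible(x)
}

#' Generalization experiment on a held-out recording
#'
#' Re-evaluates a fitted selector on a second-session recording never seen
#' during selection: the recording is preprocessed identically, segmented
#' into sliding test windows at the fitted overlap, and scored against its
#' markers.
#'
#' @param fit an [eegselect()] object (typically the best run of
#'   [experiment1()]).
#' @param rec_b the held-out [eeg_recording()].
#' @return An `eval_result` with the test confusion counts and PPV/TPR/F1.
#' @export
experiment2 <- function(fit, rec_b) {
  stopifnot(inherits(fit, "eegselect"))
  predict(fit, rec_b, type = "eval")
}

#' Write an experiment report to CSV
#'
#' @param report an `experiment_report`.
#' @param path output CSV path.
#' @return Invisibly, the written data frame.
#' @export
write_report_csv <- function(report, path) {
  df <- report$rows[, setdiff(names(report$rows), "channels")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
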