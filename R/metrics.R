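#' Confusion counts and PPV/TPR/F1
#'
#' Accumulates the confusion matrix of binary predictions against truths and
#' computes precision (PPV = TP / (TP + FP)), sensitivity
#' (TPR = TP / (TP + FN)), and their harmonic mean
#' F1 = 2 * PPV * TPR / (PPV + TPR). A ratio whose denominator is zero is
#' reported as 0 and flagged in `undefined`, which also gives degenerate
#' classifiers a well-defined (worst) fitness.
#'
#' @param predictions binary (0/1) predicted labels.
#' @param truths binary true labels of the same length.
#' @return A list of class `eval_result` with `TP`, `FP`, `TN`, `FN`, `PPV`,
#'   `TPR`, `F1`, and `undefined` (character vector naming flagged metrics).
#' @export
score <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stop("predictions (", length(predictions), ") and truths (",
         length(truths), ") differ in length")
  p <- as.integer(predictions)
  t <- as.integer(truths)
  if (anyNA(p) || anyNA(t) || !all(p %in% 0:1) || !all(t %in% 0:1))
    stop("labels must be 0 or 1")
  eval_result(TP = sum(p == 1L & t == 1L), FP = sum(p == 1L & t == 0L),
              TN = sum(p == 0L & t == 0L), FN = sum(p == 0L & t == 1L))
}

#' Build an evaluation result from raw confusion counts
#'
#' @param TP,FP,TN,FN confusion-matrix counts.
#' @return An `eval_result`; see [score()].
#' @export
eval_result <- function(TP, FP, TN, FN) {
  undefined <- character()
  PPV <- if (TP + FP > 0) TP / (TP + FP) else {
    undefined <- c(undefined, "PPV"); 0 }
  TPR <- if (TP + FN > 0) TP / (TP + FN) else {
    undefined <- c(undefined, "TPR"); 0 }
  F1 <- if (PPV + TPR > 0) 2 * PPV * TPR / (PPV + TPR) else {
    undefined <- c(undefined, "F1"); 0 }
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 PPV = PPV, TPR = TPR, F1 = F1, undefined = undefined),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d | PPV %.6f  TPR %.6f  F1 %.6f\n",
              x$TP, x$FP, x$TN, x$FN, x$PPV, x$TPR, x$F1))
  if (length(x$undefined))
    cat("  undefined (reported as 0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Score predictions on a window dataset
#'
#' Evaluates window predictions against a [make_sliding_set()] dataset. With
#' `mode = "event"` (the default), overlapping positive windows that share an
#' event marker are collapsed into one detection instance: a group counts as
#' a true positive when at least one of its windows fires, and as a false
#' negative when none does. Negative windows are always scored individually
#' (a firing no-event window is one false positive). This mirrors how a
#' sliding-window detector is judged in practice: an event is either caught
#' or missed once, however many overlapped windows cover it, while every
#' spurious alarm counts. `mode = "window"` scores every window as an
#' independent instance.
#'
#' @param dataset a `window_dataset` (validation or test role).
#' @param predictions 0/1 vector, one per window.
#' @param mode `"event"` or `"window"`.
#' @return An `eval_result`.
#' @export
score_windows <- function(dataset, predictions, mode = c("event", "window")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "window_dataset"))
  if (length(predictions) != nrow(dataset$X))
    stop("need one prediction per window")
  p <- as.integer(predictions)
  lab <- dataset$label
  if (mode == "window") return(score(p, lab))

  pos <- which(lab == 1L)
  neg <- which(lab == 0L)
  FP <- sum(p[neg] == 1L)
  TN <- sum(p[neg] == 0L)
  # group consecutive positive windows that share at least one marker
  TP <- 0L; FN <- 0L
  grp_markers <- integer(); grp_hit <- FALSE
  close_group <- function() {
    if (length(grp_markers)) {
      if (grp_hit) TP <<- TP + 1L else FN <<- FN + 1L
    }
  }
  for (i in pos) {
    mk <- dataset$marker_ids[[i]]
    if (length(intersect(mk, grp_markers))) {
      grp_markers <- union(grp_markers, mk)
      grp_hit <- grp_hit || p[i] == 1L
    } else {
      close_group()
      grp_markers <- mk
      grp_hit <- p[i] == 1L
    }
  }
  close_group()
  eval_result(TP = TP, FP = FP, TN = TN, FN = FN)
}

#' Data-exclusion percentage
#'
#' Percentage of the full classifier input omitted by a feature subset:
#' `phi = (1 - mean_selected / full_input) * 100`, where the full input is
#' `window_size * n_channels` values (2000 for one-second windows of the
#' eight-channel montage at 250 Hz).
#'
#' @param mean_selected mean number of selected features over runs.
#' @param full_input total available features.
#' @return The exclusion percentage.
#' @export
reduction_phi <- function(mean_selected, full_input) {
  if (full_input <= 0) stop("`full_input` must be positive")
  if (mean_selected < 0 || mean_selected > full_input)
    stop("`mean_selected` must lie in [0, full_input]")
  (1 - mean_selected / full_input) * 100
}

#' Correlation between event counts and data exclusion
#'
#' Pearson product-moment correlation between the number of events in each
#' recording and the mean exclusion percentage achieved on it; a strong
#' negative value indicates that recordings with more event examples support
#' sparser feature subsets.
#'
#' @param event_counts numeric vector of per-recording event counts.
#' @param phi_values matching vector of exclusion percentages.
#' @return The Pearson correlation coefficient.
#' @export
events_exclusion_correlation <- function(event_counts, phi_values) {
  if (length(event_counts) != length(phi_values))
    stop("input vectors differ in length")
  if (length(event_counts) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(event_counts) == 0 || stats::sd(phi_values) == 0)
    stop("correlation undefined: an input has zero variance")
  stats::cor(event_counts, phi_values, method = "pearson")
}

#' Summary statistics of per-run feature-selection totals
#'
#' Order statistics and moments of the total selected-feature counts over a
#' set of independent runs, plus the exclusion percentage `phi` derived from
#' the mean. The spread `sigma` is the sample standard deviation (n - 1
#' denominator).
#'
#' @param totals numeric vector of per-run selected-feature totals.
#' @param full_input total available features (default 2000).
#' @return A list of class `selection_stats` with `min`, `median`, `max`,
#'   `mean`, `sigma`, `phi`, and `n_runs`.
#' @export
summarize_runs <- function(totals, full_input = 2000) {
  if (!length(totals)) stop("`totals` must be non-empty")
  structure(list(min = min(totals), median = stats::median(totals),
                 max = max(totals), mean = mean(totals),
                 sigma = if (length(totals) > 1L) stats::sd(totals) else 0,
                 phi = reduction_phi(mean(totals), full_input),
                 n_runs = length(totals)),
            class = "selection_stats")
}

#' @export
print.selection_stats <- function(x, ...) {
  cat(sprintf("selection over %d run(s): min %g  median %g  max %g  mean %.2f  sigma %.2f  phi %.3f%%\n",
              x$n_runs, x$min, x$median, x$max, x$mean, x$sigma, x$phi))
  invisible(x)
}
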