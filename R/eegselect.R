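#' Evolutionary feature selection for EEG event detection
#'
#' The package's main fitting function. Starting from a marker-labelled EEG
#' recording it (optionally) applies the standard preprocessing chain (mains
#' notch, 1-12 Hz band-pass, per-channel min-max normalization), splits the
#' recording 70/30 by events into training and validation parts, and runs a
#' genetic algorithm whose individuals encode a window overlap, an active
#' channel subset, and per-channel sample points. Each candidate is scored by
#' the validation F1 of a pyramid-sized MLP trained on event-centred windows
#' (wrapper feature selection). The returned object carries the best feature
#' subset, its trained classifier, and the evolution log.
#'
#' @param rec an [eeg_recording()] with event markers.
#' @param window_size window length in samples; also the number of candidate
#'   sample points per channel in the chromosome (default 250, one second at
#'   250 Hz).
#' @param train_frac event fraction assigned to training (default 0.7).
#' @param pop_size,generations,crossover_rate GA parameters, see
#'   [ga_config()].
#' @param epochs,learning_rate,batch_size,threshold,sizing_rule classifier
#'   parameters, see [mlp_spec()].
#' @param scoring how validation/test windows are scored, see
#'   [score_windows()]; `"event"` (default) collapses overlapped positive
#'   windows sharing a marker into one detection instance.
#' @param filter filter settings, a [filter_spec()].
#' @param preprocess apply the preprocessing chain first (default `TRUE`;
#'   set `FALSE` if `rec` is already filtered and normalized).
#' @param normalize_scope passed to [preprocess()].
#' @param seed run seed; the whole fit is reproducible from it.
#' @return An object of class `eegselect` with components `phenotype` (best
#'   decoded solution), `model` (trained [mlp_train()] classifier),
#'   `validation` (an `eval_result` on the validation windows), `ga` (the
#'   [ga_run()] result), `split` (event/sample counts of the 70/30 split),
#'   and the call settings.
#' @examples
#' rec <- generate_eeg(synth_config(duration = 30, n_events = 10, seed = 4))
#' fit <- eegselect(rec, window_size = 100, pop_size = 6, generations = 3,
#'                  seed = 4)
#' print(fit)
#' @export
eegselect <- function(rec, window_size = 250, train_frac = 0.7,
                      pop_size = 50, generations = 200, crossover_rate = 0.9,
                      epochs = 10, learning_rate = 0.1, batch_size = 32,
                      threshold = 0.5, sizing_rule = "cube_root",
                      scoring = c("event", "window"),
                      filter = filter_spec(), preprocess = TRUE,
                      normalize_scope = "full", seed = 1) {
  scoring <- match.arg(scoring)
  stopifnot(inherits(rec, "eeg_recording"))
  if (!nrow(rec$markers)) stop("recording has no event markers")
  if (preprocess)
    rec <- preprocess(rec, filter, normalize_scope, train_frac)
  parts <- split_by_events(rec, train_frac)
  layout <- chromosome_layout(n_channels(rec), window_size)
  cfg <- ga_config(pop_size, generations, crossover_rate, seed = seed)
  ga <- ga_run(parts$train, parts$validation, cfg, layout,
               epochs = epochs, learning_rate = learning_rate,
               batch_size = batch_size, threshold = threshold,
               sizing_rule = sizing_rule, scoring = scoring)
  phen <- ga$best_phenotype

  # refit the winning subset deterministically (same derived seed as the GA
  # used) and score it on the validation windows
  train_ds <- suppressWarnings(
    make_training_set(parts$train, window_size, phen$overlap))
  val_ds <- make_sliding_set(parts$validation, window_size, phen$overlap)
  cols <- mask_to_columns(phen$feature_mask)
  mseed <- (seed * 7919 + chromosome_hash(ga$best$bits)) %% 2147483629
  spec <- mlp_spec(IL = length(cols), epochs = epochs,
                   learning_rate = learning_rate, batch_size = batch_size,
                   threshold = threshold, seed = mseed,
                   sizing_rule = sizing_rule)
  model <- suppressWarnings(
    mlp_train(train_ds$X[, cols, drop = FALSE], train_ds$label, spec))
  val_eval <- score_windows(val_ds,
                            predict(model, val_ds$X[, cols, drop = FALSE]),
                            scoring)

  structure(list(
    phenotype = phen, model = model, validation = val_eval, ga = ga,
    split = list(train_events = nrow(parts$train$markers),
                 train_samples = n_samples(parts$train),
                 validation_events = nrow(parts$validation$markers),
                 validation_samples = n_samples(parts$validation)),
    channel_labels = rec$channel_labels, fs = rec$fs,
    window_size = as.integer(window_size), train_frac = train_frac,
    filter = filter, preprocessed = preprocess,
    normalize_scope = normalize_scope,
    mlp_settings = list(epochs = epochs, learning_rate = learning_rate,
                        batch_size = batch_size, threshold = threshold,
                        sizing_rule = sizing_rule),
    scoring = scoring,
    seed = seed), class = "eegselect")
}

#' @export
print.eegselect <- function(x, ...) {
  cat("Evolutionary EEG feature selection\n")
  cat(sprintf("  split: %d training / %d validation events\n",
              x$split$train_events, x$split$validation_events))
  cat(sprintf("  best solution: overlap %d%%, %d of %d features, channels {%s}\n",
              x$phenotype$overlap_pct, x$phenotype$total_selected,
              x$window_size * length(x$channel_labels),
              paste(x$channel_labels[x$phenotype$active_channels],
                    collapse = ", ")))
  cat(sprintf("  data reduction: %.1f%%\n",
              reduction_phi(x$phenotype$total_selected,
                            x$window_size * length(x$channel_labels))))
  cat("  validation: ")
  print(x$validation)
  invisible(x)
}

#' @export
summary.eegselect <- function(object, ...) {
  sel <- object$phenotype$per_channel
  names(sel) <- object$channel_labels
  out <- list(
    selected_per_channel = sel,
    total_selected = object$phenotype$total_selected,
    full_input = object$window_size * length(object$channel_labels),
    reduction_pct = reduction_phi(
      object$phenotype$total_selected,
      object$window_size * length(object$channel_labels)),
    overlap_pct = object$phenotype$overlap_pct,
    validation = object$validation,
    generations = nrow(object$ga$log),
    best_f1_trace = object$ga$log$best_f1)
  class(out) <- "summary.eegselect"
  out
}

#' @export
print.summary.eegselect <- function(x, ...) {
  cat("Selected features per channel:\n")
  print(x$selected_per_channel)
  cat(sprintf("Total %d of %d (%.1f%% of the input excluded), overlap %d%%\n",
              x$total_selected, x$full_input, x$reduction_pct, x$overlap_pct))
  cat("Validation: ")
  print(x$validation)
  invisible(x)
}

#' @export
coef.eegselect <- function(object, ...) {
  sel <- object$phenotype$per_channel
  names(sel) <- object$channel_labels
  c(overlap = object$phenotype$overlap_pct / 100, sel)
}

#' @export
plot.eegselect <- function(x, ...) {
  log <- x$ga$log
  graphics::plot(log$generation, log$best_f1, type = "s", ylim = c(0, 1),
                 xlab = "generation", ylab = expression(F[1]),
                 main = "GA fitness trace", ...)
  graphics::lines(log$generation, log$mean_f1, lty = 2)
  graphics::legend("bottomright", legend = c("best", "population mean"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Apply a fitted selector to a new recording
#'
#' Preprocesses the new recording the same way the fit did, segments it into
#' sliding windows at the fitted overlap, and classifies each window with the
#' trained MLP.
#'
#' @param object an [eegselect()] fit.
#' @param newdata an [eeg_recording()] with the same channel count.
#' @param type `"eval"` (default) scores against the recording's markers and
#'   returns an `eval_result`; `"label"` returns the 0/1 window decisions;
#'   `"response"` the raw sigmoid outputs.
#' @param preprocess apply the fit's preprocessing chain to `newdata`
#'   (default follows the fit).
#' @param ... unused.
#' @return See `type`.
#' @export
predict.eegselect <- function(object, newdata,
                              type = c("eval", "label", "response"),
                              preprocess = object$preprocessed, ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "eeg_recording"))
  if (n_channels(newdata) != length(object$channel_labels))
    stop("newdata has ", n_channels(newdata), " channels; the fit expects ",
         length(object$channel_labels))
  if (preprocess)
    newdata <- preprocess(newdata, object$filter, object$normalize_scope,
                          object$train_frac)
  ds <- make_sliding_set(newdata, object$window_size,
                         object$phenotype$overlap, role = "test")
  cols <- mask_to_columns(object$phenotype$feature_mask)
  X <- ds$X[, cols, drop = FALSE]
  switch(type,
         response = predict(object$model, X, type = "response"),
         label = predict(object$model, X),
         eval = score_windows(ds, predict(object$model, X), object$scoring))
}
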