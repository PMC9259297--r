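# Run code with a private RNG stream, restoring the caller's state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Geometric pyramid layer sizing
#'
#' Sizes the two hidden layers of the classifier from the input and output
#' widths so the topology forms a horizontal pyramid, each layer strictly no
#' wider than the one before. A proportion factor `kappa = (IL/OL)^(1/3)`
#' places the hidden layers at the intermediate points of the geometric
#' progression from `IL` down to `OL`: `HL1 = round(OL * kappa^2)`,
#' `HL2 = round(OL * kappa)`. After rounding, sizes are clamped so
#' `IL >= HL1 >= HL2 >= OL`.
#'
#' @param IL input layer width (number of selected features).
#' @param OL output layer width (1 for binary event detection).
#' @param sizing_rule `"cube_root"` (default, the pyramid reading) or
#'   `"sqrt"`, which uses `kappa = sqrt(IL/OL)` and therefore makes the first
#'   hidden layer as wide as the input.
#' @return A list with `IL`, `HL1`, `HL2`, `OL`, and `kappa`.
#' @export
size_layers <- function(IL, OL = 1, sizing_rule = c("cube_root", "sqrt")) {
  sizing_rule <- match.arg(sizing_rule)
  if (IL < OL) stop("input width IL (", IL, ") must be >= output width OL (",
                    OL, ")")
  if (OL < 1) stop("OL must be >= 1")
  kappa <- if (sizing_rule == "cube_root") (IL / OL)^(1 / 3) else sqrt(IL / OL)
  HL1 <- round(OL * kappa^2)
  HL2 <- round(OL * kappa)
  HL1 <- min(max(HL1, OL), IL)
  HL2 <- min(max(HL2, OL), HL1)
  list(IL = as.integer(IL), HL1 = as.integer(HL1), HL2 = as.integer(HL2),
       OL = as.integer(OL), kappa = kappa)
}

#' MLP hyper-parameter specification
#'
#' @param IL input width.
#' @param OL output width (fixed at 1 in this package's pipelines).
#' @param epochs training epochs (default 10).
#' @param learning_rate gradient-descent step size (default 0.1).
#' @param batch_size minibatch size (default 32).
#' @param threshold decision cutoff on the sigmoid output (default 0.5,
#'   inclusive: outputs equal to the threshold are labelled 1).
#' @param seed RNG seed for weight initialization and minibatch shuffling.
#' @param sizing_rule passed to [size_layers()].
#' @return A list of class `mlp_spec` including the computed `HL1`/`HL2`.
#' @export
mlp_spec <- function(IL, OL = 1, epochs = 10, learning_rate = 0.1,
                     batch_size = 32, threshold = 0.5, seed = 1,
                     sizing_rule = "cube_root") {
  sz <- size_layers(IL, OL, sizing_rule)
  structure(c(sz, list(epochs = as.integer(epochs),
                       learning_rate = learning_rate,
                       batch_size = as.integer(batch_size),
                       threshold = threshold, seed = as.integer(seed))),
            class = "mlp_spec")
}

init_layer <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  list(W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = rep(0, n_out))
}

mlp_forward <- function(weights, X) {
  A1 <- relu(sweep(X %*% weights[[1]]$W, 2L, weights[[1]]$b, `+`))
  A2 <- relu(sweep(A1 %*% weights[[2]]$W, 2L, weights[[2]]$b, `+`))
  out <- sigmoid(sweep(A2 %*% weights[[3]]$W, 2L, weights[[3]]$b, `+`))
  list(A1 = A1, A2 = A2, out = out)
}

#' Train the event classifier
#'
#' Minibatch gradient-descent backpropagation minimizing the mean squared
#' error between sigmoid outputs and binary labels, for a fixed number of
#' epochs. Hidden layers use ReLU activations; the single output unit is a
#' sigmoid read against the decision threshold. Weight initialization and
#' per-epoch example shuffling are driven by `spec$seed`, so training is
#' fully reproducible; the caller's RNG stream is left untouched.
#'
#' @param X numeric matrix, one row per training window, one column per
#'   selected feature (must have `spec$IL` columns).
#' @param y binary labels (0/1), one per row of `X`.
#' @param spec an [mlp_spec()].
#' @return An object of class `mlp_model` with the trained `weights`, the
#'   `spec`, and `mse`, the full-set mean squared error logged after each
#'   epoch.
#' @export
mlp_train <- function(X, y, spec) {
  stopifnot(inherits(spec, "mlp_spec"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (ncol(X) != spec$IL)
    stop("X has ", ncol(X), " feature columns but spec$IL = ", spec$IL)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) < 1L) stop("empty training set")
  if (length(unique(y)) < 2L)
    warning("training set contains a single class; the fitted model is degenerate")

  n <- nrow(X)
  lr <- spec$learning_rate
  with_seed(spec$seed, {
    weights <- list(init_layer(spec$IL, spec$HL1),
                    init_layer(spec$HL1, spec$HL2),
                    init_layer(spec$HL2, spec$OL))
    mse_log <- numeric(spec$epochs)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1L, n, by = spec$batch_size)) {
        rows <- ord[b0:min(b0 + spec$batch_size - 1L, n)]
        Xb <- X[rows, , drop = FALSE]
        yb <- y[rows]
        nb <- length(rows)

        Z1 <- sweep(Xb %*% weights[[1]]$W, 2L, weights[[1]]$b, `+`)
        A1 <- relu(Z1)
        Z2 <- sweep(A1 %*% weights[[2]]$W, 2L, weights[[2]]$b, `+`)
        A2 <- relu(Z2)
        Z3 <- sweep(A2 %*% weights[[3]]$W, 2L, weights[[3]]$b, `+`)
        out <- sigmoid(Z3)

        # d MSE / d Z3 for MSE = mean((y - out)^2), sigmoid output
        d3 <- (2 / nb) * (out - yb) * out * (1 - out)
        d2 <- (d3 %*% t(weights[[3]]$W)) * (Z2 > 0)
        d1 <- (d2 %*% t(weights[[2]]$W)) * (Z1 > 0)

        weights[[3]]$W <- weights[[3]]$W - lr * crossprod(A2, d3)
        weights[[3]]$b <- weights[[3]]$b - lr * colSums(d3)
        weights[[2]]$W <- weights[[2]]$W - lr * crossprod(A1, d2)
        weights[[2]]$b <- weights[[2]]$b - lr * colSums(d2)
        weights[[1]]$W <- weights[[1]]$W - lr * crossprod(Xb, d1)
        weights[[1]]$b <- weights[[1]]$b - lr * colSums(d1)
      }
      mse_log[ep] <- mean((y - mlp_forward(weights, X)$out)^2)
    }
    structure(list(spec = spec, weights = weights, mse = mse_log,
                   trained = TRUE),
              class = "mlp_model")
  })
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("MLP %d-%d-%d-%d (ReLU/ReLU/sigmoid), %d epoch(s), final MSE %.5f\n",
              x$spec$IL, x$spec$HL1, x$spec$HL2, x$spec$OL,
              x$spec$epochs, x$mse[length(x$mse)]))
  invisible(x)
}

#' Classifier predictions
#'
#' @param object a trained `mlp_model`.
#' @param newdata numeric matrix with `spec$IL` feature columns.
#' @param type `"label"` (default) for 0/1 decisions at the spec threshold,
#'   `"response"` for raw sigmoid outputs.
#' @param ... unused.
#' @return Numeric vector of predictions, one per row of `newdata`.
#' @export
predict.mlp_model <- function(object, newdata, type = c("label", "response"),
                              ...) {
  type <- match.arg(type)
  if (!isTRUE(object$trained)) stop("model is not trained")
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$spec$IL)
    stop("newdata has ", ncol(newdata), " columns but the model expects ",
         object$spec$IL)
  out <- as.numeric(mlp_forward(object$weights, newdata)$out)
  if (type == "response") out else as.integer(out >= object$spec$threshold)
}
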