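#' Initialize a linear feed-forward network
#'
#' Builds the three-layer network used as the second calibrator: an input
#' layer (one neuron per wavelength of the working window; 251 for the
#' 250--300 nm window at 0.2 nm), a hidden layer, and an output layer with
#' one neuron per analyte. All transfer functions are linear ("purelin"), so
#' the network computes an affine map whose effective rank is bounded by the
#' hidden width. Weights are drawn uniformly from a small symmetric interval
#' scaled by the fan-in; biases start at zero.
#'
#' @param n_in Number of input neurons (wavelengths).
#' @param n_hidden Hidden-layer width; the reference configuration uses 4.
#' @param n_out Number of output neurons (analytes); 5 for this assay.
#' @param seed Integer seed for reproducible initialization.
#' @return An object of class `ann_model` with weight matrices `W1`
#'   (hidden x inputs), `W2` (outputs x hidden), bias vectors `b1`, `b2`, and
#'   the configuration. Scaling transforms are attached by [train_ann()].
#' @export
init_ann <- function(n_in, n_hidden = 4, n_out = 5, seed = 1) {
  if (n_in < 1 || n_hidden < 1 || n_out < 1) {
    stop("All layer sizes must be positive.", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    W1 <- matrix(stats::runif(n_hidden * n_in, -0.5, 0.5) / sqrt(n_in),
                 n_hidden, n_in)
    W2 <- matrix(stats::runif(n_out * n_hidden, -0.5, 0.5) / sqrt(n_hidden),
                 n_out, n_hidden)
  })
  structure(
    list(W1 = W1, b1 = numeric(n_hidden), W2 = W2, b2 = numeric(n_out),
         scaler = NULL, config = list(n_in = n_in, n_hidden = n_hidden,
                                      n_out = n_out, seed = as.integer(seed)),
         loss_trace = numeric(0)),
    class = "ann_model"
  )
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("<ann_model> %d-%d-%d purelin network (%s)\n",
              x$config$n_in, x$config$n_hidden, x$config$n_out,
              if (is.null(x$scaler)) "untrained" else
                sprintf("trained, final loss %.3g", utils::tail(x$loss_trace, 1))))
  invisible(x)
}

# input scaling: mean-center, divide by the single global SD of the centered
# calibration absorbances; targets scaled per component to [-1, 1]
fit_ann_scaler <- function(X, Y) {
  x_means <- colMeans(X)
  Xc <- sweep(X, 2, x_means, `-`)
  x_sd <- stats::sd(as.vector(Xc))
  if (!is.finite(x_sd) || x_sd == 0) x_sd <- 1
  y_min <- apply(Y, 2, min)
  y_max <- apply(Y, 2, max)
  y_span <- pmax(y_max - y_min, .Machine$double.eps)
  list(x_means = x_means, x_sd = x_sd, y_min = y_min, y_span = y_span)
}

ann_scale_x <- function(scaler, X) {
  sweep(as.matrix(X), 2, scaler$x_means, `-`) / scaler$x_sd
}
ann_scale_y <- function(scaler, Y) {
  sweep(sweep(as.matrix(Y), 2, scaler$y_min, `-`), 2, scaler$y_span, `/`) * 2 - 1
}
ann_unscale_y <- function(scaler, Ys) {
  sweep(sweep((as.matrix(Ys) + 1) / 2, 2, scaler$y_span, `*`), 2, scaler$y_min, `+`)
}

ann_forward <- function(m, Xs) {
  H <- tcrossprod(Xs, m$W1) + matrix(m$b1, nrow(Xs), length(m$b1), byrow = TRUE)
  tcrossprod(H, m$W2) + matrix(m$b2, nrow(Xs), length(m$b2), byrow = TRUE)
}

# loss and analytic gradient of mean((Yhat - Ys)^2) over all entries
ann_gradient <- function(m, Xs, Ys) {
  n <- nrow(Xs)
  H <- tcrossprod(Xs, m$W1) + matrix(m$b1, n, length(m$b1), byrow = TRUE)
  Yhat <- tcrossprod(H, m$W2) + matrix(m$b2, n, length(m$b2), byrow = TRUE)
  E <- Yhat - Ys
  scale <- 2 / length(E)
  dH <- E %*% m$W2
  list(
    loss = mean(E^2),
    dW2 = scale * crossprod(E, H),
    db2 = scale * colSums(E),
    dW1 = scale * crossprod(dH, Xs),
    db1 = scale * colSums(dH)
  )
}

#' Train the network by full-batch gradient descent
#'
#' Minimizes the mean squared error on scaled data with plain full-batch
#' gradient descent. Inputs are mean-centered and divided by the global
#' standard deviation of the calibration absorbances; targets are scaled per
#' component to \eqn{[-1, 1]} from the calibration minima/maxima and
#' unscaled at prediction. The reference configuration trains for 50 epochs
#' at learning rate 0.1.
#'
#' @param model An [init_ann()] network (or a trained one to continue).
#' @param X Calibration spectra, samples x wavelengths (raw absorbances).
#' @param Y Calibration concentrations, samples x components (ug/mL).
#' @param epochs Number of full-batch passes, >= 1.
#' @param lr Learning rate on the scaled problem.
#' @return The trained `ann_model`, with the fitted scaler and a
#'   `loss_trace` of length `epochs` (scaled-MSE after each epoch).
#' @export
train_ann <- function(model, X, Y, epochs = 50, lr = 0.1) {
  X <- as.matrix(X); Y <- conc_to_matrix(Y)
  if (epochs < 1) stop("`epochs` must be >= 1.", call. = FALSE)
  if (ncol(X) != model$config$n_in || ncol(Y) != model$config$n_out) {
    stop("Data dimensions do not match the network (",
         model$config$n_in, " inputs, ", model$config$n_out, " outputs).",
         call. = FALSE)
  }
  if (is.null(model$scaler)) model$scaler <- fit_ann_scaler(X, Y)
  if (is.null(model$component_names)) model$component_names <- colnames(Y)
  Xs <- unname(ann_scale_x(model$scaler, X))
  Ys <- unname(ann_scale_y(model$scaler, Y))

  trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    g <- ann_gradient(model, Xs, Ys)
    model$W1 <- model$W1 - lr * g$dW1
    model$b1 <- model$b1 - lr * g$db1
    model$W2 <- model$W2 - lr * g$dW2
    model$b2 <- model$b2 - lr * g$db2
    trace[e] <- mean((ann_forward(model, Xs) - Ys)^2)
    if (!is.finite(trace[e])) {
      stop("Training diverged (non-finite loss) at epoch ", e,
           "; lower the learning rate or check input scaling.", call. = FALSE)
    }
  }
  model$loss_trace <- c(model$loss_trace, trace)
  model$config$lr <- lr
  model
}

#' Fit the network calibrator in one call
#'
#' Convenience wrapper: initialize, fit the scaler and train. Two presets
#' are provided. `"reference"` is the literal historical configuration
#' (4 hidden neurons, learning rate 0.1, 50 epochs); with arbitrary band
#' libraries it may converge poorly or diverge, which the error message
#' reports. `"accurate"` uses 5 hidden neurons (a linear network needs
#' hidden width at least the number of analytes to represent the exact
#' inverse map of a five-component system), a conservative learning rate and
#' many more epochs, and is the preset property tests rely on.
#'
#' @param X,Y Calibration spectra and concentrations.
#' @param preset `"reference"` or `"accurate"`.
#' @param seed Seed for weight initialization.
#' @param n_hidden,epochs,lr Optional overrides of the preset.
#' @return A trained `ann_model`.
#' @export
fit_ann <- function(X, Y, preset = c("accurate", "reference"), seed = 1,
                    n_hidden = NULL, epochs = NULL, lr = NULL) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    reference = list(n_hidden = 4L, epochs = 50L, lr = 0.1),
    accurate = list(n_hidden = 5L, epochs = 20000L, lr = 0.05)
  )
  n_hidden <- n_hidden %||% cfg$n_hidden
  epochs <- epochs %||% cfg$epochs
  lr <- lr %||% cfg$lr
  X <- as.matrix(X); Y <- conc_to_matrix(Y)
  m <- init_ann(ncol(X), n_hidden = n_hidden, n_out = ncol(Y), seed = seed)
  m$component_names <- colnames(Y)
  train_ann(m, X, Y, epochs = epochs, lr = lr)
}

#' Predict concentrations from the network
#'
#' @param object A trained `ann_model`.
#' @param newdata Raw absorbance matrix or [spectrum_set()].
#' @param ... Unused.
#' @return Matrix of predicted concentrations (ug/mL).
#' @export
predict.ann_model <- function(object, newdata, ...) {
  if (is.null(object$scaler)) stop("Network is untrained.", call. = FALSE)
  X <- if (inherits(newdata, "spectrum_set")) newdata$absorbance else
    as.matrix(newdata)
  if (ncol(X) != object$config$n_in) {
    stop("New data has ", ncol(X), " wavelengths; network expects ",
         object$config$n_in, ".", call. = FALSE)
  }
  out <- ann_unscale_y(object$scaler, ann_forward(object, ann_scale_x(object$scaler, X)))
  colnames(out) <- object$component_names
  out
}

#' Collapse the purelin network to a single affine map
#'
#' Because every transfer function is linear, the layered forward pass
#' equals one affine map `y = A x + c` on the scaled variables, with
#' `A = W2 W1` and `c = W2 b1 + b2`. Useful for verification and for
#' reasoning about the network's rank.
#'
#' @param model A trained or untrained `ann_model`.
#' @return List with matrix `A` (outputs x inputs) and vector `c`.
#' @export
ann_as_affine <- function(model) {
  list(A = model$W2 %*% model$W1,
       c = as.vector(model$W2 %*% model$b1 + model$b2))
}

#' Scan hidden-layer widths
#'
#' Trains one network per hidden width and reports the calibration RMSEC
#' (original concentration units), mirroring the usual width-selection sweep.
#'
#' @param X,Y Calibration spectra and concentrations.
#' @param hidden Integer vector of widths to try.
#' @param seed,epochs,lr Training settings shared by all widths.
#' @return Tibble with columns `n_hidden` and `rmsec`.
#' @export
scan_hidden <- function(X, Y, hidden = 1:8, seed = 1, epochs = 2000, lr = 0.05) {
  X <- as.matrix(X); Y <- conc_to_matrix(Y)
  purrr::map_dfr(hidden, function(h) {
    m <- fit_ann(X, Y, preset = "accurate", seed = seed,
                 n_hidden = h, epochs = epochs, lr = lr)
    tibble::tibble(n_hidden = h,
                   rmsec = sqrt(mean((predict(m, X) - Y)^2)))
  })
}

#' Tidy the training loss trace
#'
#' @param x A trained `ann_model`.
#' @param ... Unused.
#' @return Tibble with `epoch` and `loss` (scaled-MSE).
#' @method tidy ann_model
#' @export
tidy.ann_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' One-row summary of a network
#'
#' @param x An `ann_model`.
#' @param ... Unused.
#' @return Tibble with layer sizes and final training loss.
#' @method glance ann_model
#' @export
glance.ann_model <- function(x, ...) {
  tibble::tibble(
    n_in = x$config$n_in, n_hidden = x$config$n_hidden,
    n_out = x$config$n_out,
    epochs_trained = length(x$loss_trace),
    final_loss = if (length(x$loss_trace)) utils::tail(x$loss_trace, 1) else NA_real_
  )
}
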