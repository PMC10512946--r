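# The inception-block convolutional regressor: a stack of inception
# modules (bottleneck pointwise convolution; three parallel convolutions
# of different kernel lengths; a max-pool + pointwise branch; concatenation,
# batch normalisation and a rectifier), a residual shortcut every
# `residual_period` blocks, global average pooling over time, and a linear
# dense head producing one angular-velocity value per window.  Trained
# with a mean-squared-error objective.

#' Regressor architecture specification
#'
#' Task-tuned configurations used in the study protocol: bulb — depth 5,
#' kernels (64, 16, 4), 128 filters; screw — depth 8, same kernels;
#' hammer — depth 4, same kernels; cup — depth 3, kernels (128, 32, 8).
#'
#' @param depth Number of inception blocks (>= 1).
#' @param kernel_sizes Three kernel lengths for the parallel convolutions.
#' @param n_filters Filters per parallel branch; the block output has
#'   `4 * n_filters` channels.
#' @param bottleneck_size Channels of the pointwise bottleneck feeding the
#'   parallel convolutions (must not exceed `n_filters`).
#' @param residual_period A linear shortcut joins the trunk every this
#'   many blocks.
#' @param output_dim Size of the dense regression head (1 velocity).
#' @return An object of class `regressor_spec`.
#' @export
regressor_spec <- function(depth, kernel_sizes = c(64L, 16L, 4L),
                           n_filters = 128L, bottleneck_size = 32L,
                           residual_period = 3L, output_dim = 1L) {
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1)
    wv_stop("depth must be a positive integer (got ", depth, ")")
  if (length(kernel_sizes) != 3L || any(kernel_sizes < 1))
    wv_stop("kernel_sizes must be three positive integers")
  assert_scalar_num(n_filters, "n_filters")
  assert_scalar_num(bottleneck_size, "bottleneck_size")
  assert_scalar_num(residual_period, "residual_period")
  assert_scalar_num(output_dim, "output_dim")
  if (bottleneck_size > n_filters)
    wv_stop("bottleneck_size (", bottleneck_size,
            ") must not exceed n_filters (", n_filters, ")")
  structure(list(depth = as.integer(depth),
                 kernel_sizes = as.integer(kernel_sizes),
                 n_filters = as.integer(n_filters),
                 bottleneck_size = as.integer(bottleneck_size),
                 residual_period = as.integer(residual_period),
                 output_dim = as.integer(output_dim)),
            class = "regressor_spec")
}

#' @export
print.regressor_spec <- function(x, ...) {
  cat(sprintf(
    "<regressor_spec> depth %d, kernels (%s), %d filters, bottleneck %d\n",
    x$depth, paste(x$kernel_sizes, collapse = ", "), x$n_filters,
    x$bottleneck_size))
  invisible(x)
}

#' Build an (untrained) inception-block regressor
#'
#' Same-padding convolutions keep the temporal length constant, and the
#' global average pool makes the network length-agnostic: `input_len` is
#' recorded for documentation but any window length can be processed.
#' Weights use fan-in-scaled random initialisation.
#'
#' @param spec A [regressor_spec()].
#' @param input_len Nominal window length in samples (default 250).
#' @param n_channels Number of sEMG channels (default 8).
#' @param seed Optional seed for weight initialisation; the global RNG
#'   state is restored afterwards.
#' @return An object of class `inception_regressor`.
#' @export
build_regressor <- function(spec, input_len = 250L, n_channels = 8L,
                            seed = NULL) {
  stopifnot(inherits(spec, "regressor_spec"))
  assert_scalar_num(input_len, "input_len")
  assert_scalar_num(n_channels, "n_channels")
  params <- with_seed(seed, init_params(spec, as.integer(n_channels)))
  structure(list(spec = spec,
                 input_len = as.integer(input_len),
                 n_channels = as.integer(n_channels),
                 params = params,
                 bn_state = init_bn_state(spec),
                 plan = plan_blocks(spec, as.integer(n_channels)),
                 # label standardisation applied during training and
                 # inverted at prediction; frozen once fitted on the
                 # pre-training labels (same-scaler discipline)
                 label_center = 0, label_scale = 1),
            class = "inception_regressor")
}

#' Number of trainable parameters
#'
#' Deterministic given the spec and input channel count; strictly
#' increasing in depth and in the filter count.
#'
#' @param model An `inception_regressor`.
#' @return Integer parameter count.
#' @export
parameter_count <- function(model) {
  stopifnot(inherits(model, "inception_regressor"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.inception_regressor <- function(x, ...) {
  cat(sprintf(
    "<inception_regressor> depth %d, %d filters, %d channels, %d parameters\n",
    x$spec$depth, x$spec$n_filters, x$n_channels, parameter_count(x)))
  invisible(x)
}

#' Predict joint velocities for a window set
#'
#' Inference is deterministic: batch-normalisation uses the frozen
#' running statistics and no parameter is updated.
#'
#' @param object An `inception_regressor`.
#' @param windows A [window_set()] or a 3-D feature array
#'   `(n, window_len, n_channels)`.
#' @param batch_size Windows per forward batch.
#' @param ... Unused.
#' @return Numeric vector of predicted velocities (deg/s), one per
#'   window (a matrix when `output_dim > 1`).
#' @export
predict.inception_regressor <- function(object, windows,
                                        batch_size = 256L, ...) {
  feats <- if (inherits(windows, "window_set")) windows$features
           else windows
  if (length(dim(feats)) != 3L)
    wv_stop("predict: expected a window_set or (n, len, channels) array")
  if (dim(feats)[3] != object$n_channels)
    wv_stop("predict: model expects ", object$n_channels,
            " channels but windows have ", dim(feats)[3])
  n <- dim(feats)[1]
  out <- matrix(0, n, object$spec$output_dim)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    X <- windows_to_matrix(feats, idx)
    fw <- nn_forward(object, X, n_win = length(idx), training = FALSE)
    out[idx, ] <- fw$yhat
  }
  out <- out * object$label_scale + object$label_center
  if (object$spec$output_dim == 1L) drop(out) else out
}

#' Training loss and gradient for one batch (internal use and testing)
#'
#' @param model An `inception_regressor`.
#' @param X Batch matrix `(n_win * win_len) x n_channels`.
#' @param y Target vector (or matrix for multi-output heads).
#' @param n_win Number of windows in the batch.
#' @return List with `loss` (mean squared error), `grads`, and the
#'   updated `bn_state`.
#' @keywords internal
nn_loss_grad <- function(model, X, y, n_win) {
  fw <- nn_forward(model, X, n_win, training = TRUE)
  y <- matrix(y, n_win, model$spec$output_dim)
  err <- fw$yhat - y
  loss <- mean(err^2)
  dyhat <- 2 * err / length(err)
  grads <- nn_backward(model, fw$cache, dyhat)
  list(loss = loss, grads = grads, bn_state = fw$bn_state)
}

#' Save / load a trained regressor
#'
#' The checkpoint is a single file holding the parameters, the
#' architecture spec and the batch-normalisation statistics; a load/save
#' round trip reproduces predictions bit-identically.
#'
#' @param model An `inception_regressor`.
#' @param path Checkpoint path.
#' @return `path` (for `save_model`); the model (for `load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "inception_regressor"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) wv_stop("model checkpoint not found: ", path)
  model <- tryCatch(readRDS(path),
                    error = function(e) wv_stop("corrupt checkpoint: ",
                                                conditionMessage(e)))
  if (!inherits(model, "inception_regressor"))
    wv_stop(path, " is not a saved inception_regressor")
  model
}
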