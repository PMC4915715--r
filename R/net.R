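#' Logistic (sigmoid) activation
#'
#' Elementwise `1 / (1 + exp(-a))`. Saturates to 0/1 at large `|a|` without
#' ever producing `NaN`.
#'
#' @param a Numeric vector or matrix of pre-activations.
#' @return Object of the same shape with entries strictly in `(0, 1)`
#'   (up to floating-point saturation).
#' @export
#' @examples
#' sigmoid(0)            # 0.5
#' sigmoid(c(-2, 0, 2))
sigmoid <- function(a) 1 / (1 + exp(-a))

#' Training configuration for the SGD update rule
#'
#' Bundles every constant of the update rule
#' `w(t+1) = w(t) - eta * dE/dw + alpha * (w(t) - w(t-1)) + noise`,
#' where `eta = eta0 * decay^t` decays per epoch and the injected noise is
#' zero-mean Gaussian with standard deviation `noise_coeff * sqrt(2 * eta)`.
#'
#' @param eta0 Initial learning rate (default 0.4).
#' @param decay Per-epoch multiplicative decay of the learning rate (0.99).
#' @param lambda_l1 L1 (lasso) penalty coefficient applied to all weights and
#'   biases (default `4e-7`).
#' @param alpha Momentum coefficient on the previous realized step (0.025).
#' @param noise_coeff Multiplier in the noise standard deviation
#'   `noise_coeff * sqrt(2 * eta)` (default 0.5).
#' @param epochs Number of sweeps over the training set; each sample triggers
#'   one parameter update per sweep (default 200).
#' @param finetune_passes Epochs used when fine-tuning an assembled model
#'   end to end (default 5).
#' @param init_range Half-width of the uniform initialization interval
#'   `[-init_range, init_range]` (default 0.03).
#' @param noise Logical; inject Gaussian noise into every update (default
#'   `FALSE`). At the published scale `0.5 * sqrt(2 * eta)` the noise
#'   standard deviation (0.45 at `eta = 0.4`) exceeds the trained-weight
#'   scale by an order of magnitude and the accumulated random walk
#'   saturates the sigmoids, so injection is opt-in; see the package
#'   vignette for the analysis.
#' @param shuffle Logical; reshuffle the sample order each epoch.
#' @param finetune_lr_reset Logical; restart the learning-rate schedule at
#'   `eta0` when whole-model fine-tuning begins (default `FALSE`). The
#'   default continues the decay as if fine-tuning were the tail of one
#'   long schedule (three pretraining stages deep, see [finetune_full()]);
#'   restarting at the full initial rate overwrites the pretrained
#'   solution within a few passes (catastrophic interference, see the
#'   vignette).
#' @param seed Optional integer seed applied (via [set.seed()]) by the
#'   higher-level fitting functions before any random draw.
#' @return A list with class `"train_config"`.
#' @export
train_config <- function(eta0 = 0.4, decay = 0.99, lambda_l1 = 4e-7,
                         alpha = 0.025, noise_coeff = 0.5, epochs = 200,
                         finetune_passes = 5, init_range = 0.03,
                         noise = FALSE, shuffle = TRUE,
                         finetune_lr_reset = FALSE, seed = NULL) {
  stopifnot(eta0 > 0, decay > 0, decay <= 1, lambda_l1 >= 0, alpha >= 0,
            epochs >= 0, finetune_passes >= 0, init_range > 0)
  structure(list(eta0 = eta0, decay = decay, lambda_l1 = lambda_l1,
                 alpha = alpha, noise_coeff = noise_coeff, epochs = epochs,
                 finetune_passes = finetune_passes, init_range = init_range,
                 noise = noise, shuffle = shuffle,
                 finetune_lr_reset = finetune_lr_reset, seed = seed),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' `eta0 * decay^t`, where `t` is the epoch index (one full sweep over the
#' training set); the rate is constant within an epoch.
#'
#' @param t Nonnegative epoch index (vectorized).
#' @param config A [train_config()].
#' @return Learning rate(s).
#' @export
lr_schedule <- function(t, config = train_config()) {
  stopifnot(all(t >= 0))
  config$eta0 * config$decay^t
}

#' Create network parameters
#'
#' Allocates the weight matrices and bias vectors of a fully connected
#' sigmoid network. With a numeric `init_range` every weight and bias is
#' drawn uniformly on `[-init_range, init_range]`. With `"glorot"` each
#' layer is drawn on `[-r, r]` with half-width `sqrt(6 / (fan_in + fan_out))` and
#' zero biases, which keeps the signal variance roughly constant through
#' deep sigmoid stacks — the appropriate choice for networks trained from
#' scratch without greedy pretraining.
#'
#' @param layer_sizes Integer vector of unit counts, input layer first.
#' @param init_range Half-width of the uniform initialization interval, or
#'   `"glorot"` for depth-scaled initialization.
#' @return A list with class `"net_params"`: `W` (list of matrices, `W[[l]]`
#'   maps layer `l-1` activations to layer `l` pre-activations), `b` (list of
#'   bias vectors) and `sizes`.
#' @export
net_params <- function(layer_sizes, init_range = 0.03) {
  layer_sizes <- as.integer(layer_sizes)
  stopifnot(length(layer_sizes) >= 2, all(layer_sizes >= 1))
  glorot <- identical(init_range, "glorot")
  if (!glorot) stopifnot(is.numeric(init_range), init_range > 0)
  L <- length(layer_sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    r <- if (glorot) sqrt(6 / (layer_sizes[l] + layer_sizes[l + 1L]))
         else init_range
    W[[l]] <- matrix(runif(layer_sizes[l + 1L] * layer_sizes[l], -r, r),
                     nrow = layer_sizes[l + 1L], ncol = layer_sizes[l])
    b[[l]] <- if (glorot) numeric(layer_sizes[l + 1L])
              else runif(layer_sizes[l + 1L], -r, r)
  }
  structure(list(W = W, b = b, sizes = layer_sizes), class = "net_params")
}

validate_net_params <- function(params) {
  stopifnot(inherits(params, "net_params"))
  L <- length(params$sizes) - 1L
  if (length(params$W) != L || length(params$b) != L)
    stop("net_params: expected ", L, " weight layers")
  for (l in seq_len(L)) {
    if (!all(dim(params$W[[l]]) == c(params$sizes[l + 1L], params$sizes[l])))
      stop("net_params: weight matrix of layer ", l, " has wrong shape")
    if (length(params$b[[l]]) != params$sizes[l + 1L])
      stop("net_params: bias of layer ", l, " has wrong length")
    if (!all(is.finite(params$W[[l]])) || !all(is.finite(params$b[[l]])))
      stop("net_params: non-finite entries in layer ", l)
  }
  invisible(params)
}

#' @export
print.net_params <- function(x, ...) {
  cat("Sigmoid feed-forward network parameters\n")
  cat("  layers:", paste(x$sizes, collapse = " - "), "\n")
  cat("  free parameters:", n_params(x), "\n")
  invisible(x)
}

n_params <- function(params) {
  sum(vapply(params$W, length, 0L)) + sum(vapply(params$b, length, 0L))
}

#' Forward pass returning all layer activations
#'
#' Applies the affine map and sigmoid at every non-input layer; the input
#' layer is passed through untouched. The returned activations are what
#' backpropagation needs.
#'
#' @param params A [net_params()] object.
#' @param x Input vector of length `params$sizes[1]`.
#' @return List of activations, element 1 the input, last element the output.
#' @export
net_forward <- function(params, x) {
  validate_net_params(params)
  if (length(x) != params$sizes[1])
    stop("net_forward: input length ", length(x),
         " does not match layer 1 size ", params$sizes[1])
  lapply(cpp_forward(params$W, params$b, as.numeric(x)), as.numeric)
}

#' Batch network output
#'
#' @param params A [net_params()] object.
#' @param X Matrix with samples in rows (`ncol(X) == params$sizes[1]`).
#' @return Matrix of output-layer activations, samples in rows.
#' @export
net_predict <- function(params, X) {
  validate_net_params(params)
  X <- as.matrix(X)
  if (ncol(X) != params$sizes[1])
    stop("net_predict: input has ", ncol(X),
         " columns but layer 1 expects ", params$sizes[1])
  out <- cpp_forward_batch(params$W, params$b, X)
  rownames(out) <- rownames(X)
  out
}

#' L1 (lasso) penalty
#'
#' `lambda * sum(|w|)` over every weight and bias entry.
#'
#' @param params A [net_params()] object.
#' @param lambda_l1 Nonnegative penalty coefficient.
#' @return Nonnegative scalar.
#' @export
l1_penalty <- function(params, lambda_l1) {
  stopifnot(lambda_l1 >= 0)
  lambda_l1 * (sum(vapply(params$W, function(w) sum(abs(w)), 0)) +
               sum(vapply(params$b, function(v) sum(abs(v)), 0)))
}

#' Per-sample training loss
#'
#' Squared-error sum plus the L1 penalty:
#' `sum((y - x)^2) + lambda * sum(|w|)`.
#'
#' @param y Network output vector.
#' @param x Target vector of the same length.
#' @param params A [net_params()] object (for the penalty term).
#' @param lambda_l1 Penalty coefficient.
#' @return Nonnegative scalar.
#' @export
sample_loss <- function(y, x, params, lambda_l1 = 0) {
  if (length(y) != length(x))
    stop("sample_loss: output and target lengths differ (",
         length(y), " vs ", length(x), ")")
  sum((y - x)^2) + l1_penalty(params, lambda_l1)
}

#' Exact gradient of the per-sample loss
#'
#' Backpropagation through the sigmoid network for the squared-error plus L1
#' objective. The subgradient of `|w|` at 0 is taken as 0; biases are
#' penalized like weights.
#'
#' @param params A [net_params()] object.
#' @param x Input vector.
#' @param target Target vector (output-layer length).
#' @param lambda_l1 Penalty coefficient.
#' @return List with `W` and `b`: gradients shaped like `params`.
#' @export
net_backprop <- function(params, x, target, lambda_l1 = 0) {
  validate_net_params(params)
  if (length(x) != params$sizes[1])
    stop("net_backprop: input length mismatch at layer 1")
  if (length(target) != params$sizes[length(params$sizes)])
    stop("net_backprop: target length mismatch at output layer")
  cpp_backprop(params$W, params$b, as.numeric(x), as.numeric(target),
               lambda_l1)
}

#' Initial gradient state for manual SGD stepping
#'
#' @param params A [net_params()] object.
#' @return List with `prev_delta` (all-zero, shaped like `params`) and
#'   `iteration = 0`.
#' @export
grad_state_init <- function(params) {
  validate_net_params(params)
  list(prev_delta = list(W = lapply(params$W, function(w) w * 0),
                         b = lapply(params$b, function(v) v * 0)),
       iteration = 0L)
}

#' One SGD update step
#'
#' Applies, to every weight and bias,
#' `w <- w - eta * g + alpha * (w - w_prev) + noise`
#' with `eta = lr_schedule(iteration, config)` and noise drawn
#' `N(0, (noise_coeff * sqrt(2 * eta))^2)` when `config$noise` is `TRUE`.
#' The momentum term uses the previous *realized* step (including its noise),
#' and `prev_delta` is updated to the step just taken. This is the reference
#' pure-R implementation of the rule driven in bulk by [train_net()].
#'
#' @param params A [net_params()] object.
#' @param grads Gradient list (`W`, `b`) as returned by [net_backprop()].
#' @param grad_state State from [grad_state_init()] or a previous step. Its
#'   `iteration` field selects the learning rate (epoch index).
#' @param config A [train_config()].
#' @return List with updated `params` and `grad_state` (iteration unchanged;
#'   callers advance it once per epoch).
#' @export
sgd_step <- function(params, grads, grad_state, config = train_config()) {
  eta <- lr_schedule(grad_state$iteration, config)
  noise_sd <- if (isTRUE(config$noise)) config$noise_coeff * sqrt(2 * eta) else 0
  for (l in seq_along(params$W)) {
    dW <- -eta * grads$W[[l]] + config$alpha * grad_state$prev_delta$W[[l]]
    db <- -eta * grads$b[[l]] + config$alpha * grad_state$prev_delta$b[[l]]
    if (noise_sd > 0) {
      dW <- dW + matrix(rnorm(length(dW), 0, noise_sd), nrow = nrow(dW))
      db <- db + rnorm(length(db), 0, noise_sd)
    }
    params$W[[l]] <- params$W[[l]] + dW
    params$b[[l]] <- params$b[[l]] + db
    grad_state$prev_delta$W[[l]] <- dW
    grad_state$prev_delta$b[[l]] <- db
  }
  list(params = params, grad_state = grad_state)
}

#' Train a network by per-sample stochastic gradient descent
#'
#' Runs `epochs` sweeps over the training set, one parameter update per
#' sample, with the decaying learning rate, momentum on the realized step,
#' L1 subgradient and Gaussian noise injection of the update rule. Sample
#' order is reshuffled every epoch when `config$shuffle` is `TRUE`.
#'
#' @param params A [net_params()] object (starting point).
#' @param X Input matrix, samples in rows.
#' @param Y Target matrix, samples in rows (`Y = X` trains an autoencoder).
#' @param config A [train_config()].
#' @param epochs Number of sweeps; defaults to `config$epochs`.
#' @param epoch_offset Shift applied to the learning-rate schedule so that a
#'   continued run decays from where a previous run stopped.
#' @return List with updated `params` and `loss`, the per-epoch mean
#'   squared-error term plus the L1 penalty at epoch end.
#' @export
train_net <- function(params, X, Y, config = train_config(),
                      epochs = config$epochs, epoch_offset = 0) {
  validate_net_params(params)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop("train_net: X and Y row counts differ")
  if (nrow(X) == 0) stop("train_net: empty training set")
  if (ncol(X) != params$sizes[1])
    stop("train_net: input width mismatch at layer 1")
  if (ncol(Y) != params$sizes[length(params$sizes)])
    stop("train_net: target width mismatch at output layer")
  if (epochs == 0)
    return(list(params = params, loss = numeric(0)))
  fit <- cpp_train(params$W, params$b, X, Y,
                   config$eta0, config$decay, config$lambda_l1, config$alpha,
                   config$noise_coeff, as.integer(epochs),
                   as.integer(epoch_offset),
                   isTRUE(config$noise), isTRUE(config$shuffle))
  params$W <- fit$W
  params$b <- fit$b
  list(params = params, loss = as.numeric(fit$loss))
}
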