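#' Autoencoder architecture
#'
#' Geometry of a five-layer (three hidden) autoencoder: input/output width
#' `M`, outer hidden width `K` (first and third hidden layers) and bottleneck
#' width `D` (code dimension). A warning — not an error — is raised when
#' `D < K < M` does not hold, since non-bottleneck shapes are still trainable.
#'
#' @param input_dim Input (and output) width `M`.
#' @param outer_hidden Outer hidden width `K`.
#' @param code_dim Bottleneck width `D`.
#' @param role `"spectrum"` or `"sensory"` — which data block the model
#'   compresses.
#' @return List with class `"ae_architecture"`.
#' @export
ae_architecture <- function(input_dim, outer_hidden, code_dim,
                            role = c("spectrum", "sensory")) {
  role <- match.arg(role)
  stopifnot(input_dim >= 1, outer_hidden >= 1, code_dim >= 1)
  if (!(code_dim < outer_hidden && outer_hidden < input_dim))
    warning("ae_architecture: D < K < M does not hold (",
            code_dim, ", ", outer_hidden, ", ", input_dim,
            "); not a bottleneck")
  structure(list(input_dim = as.integer(input_dim),
                 outer_hidden = as.integer(outer_hidden),
                 code_dim = as.integer(code_dim), role = role),
            class = "ae_architecture")
}

check_unit_interval <- function(data, what) {
  if (length(data) == 0 || nrow(data) == 0 || ncol(data) == 0)
    stop(what, ": empty data")
  if (min(data) < 0 || max(data) > 1)
    stop(what, ": entries must lie in [0, 1]; run normalize_max() first")
  invisible(data)
}

#' Train a three-layer (one hidden) autoencoder
#'
#' Fits a `[M, H, M]` sigmoid network on `(x, x)` pairs with [train_net()].
#' This is the building block of greedy pretraining: its encoder half
#' produces the codes on which the next, narrower autoencoder is trained.
#'
#' @param data Matrix with samples in rows, entries in `[0, 1]`.
#' @param hidden_dim Hidden-layer width `H`.
#' @param config A [train_config()].
#' @param epochs Training sweeps; defaults to `config$epochs`.
#' @return A `"net_params"` object with layer sizes `c(M, H, M)` and the
#'   per-epoch loss attached as attribute `"training_log"`.
#' @export
train_ae3 <- function(data, hidden_dim, config = train_config(),
                      epochs = config$epochs) {
  data <- as.matrix(data)
  check_unit_interval(data, "train_ae3")
  stopifnot(hidden_dim >= 1)
  params <- net_params(c(ncol(data), hidden_dim, ncol(data)),
                       config$init_range)
  fit <- train_net(params, data, data, config, epochs = epochs)
  attr(fit$params, "training_log") <- fit$loss
  fit$params
}

# Encoder half of a 3-layer autoencoder: one affine + sigmoid stage.
encode_ae3 <- function(params, data) {
  cpp_forward_batch(params$W[1], params$b[1], as.matrix(data))
}

#' Greedy pretraining of a five-layer autoencoder
#'
#' Stage 1 trains a `[M, K, M]` autoencoder on the data; stage 2 trains a
#' `[K, D, K]` autoencoder on the stage-1 codes (the sigmoid activations, in
#' `(0, 1)`, used as-is); the five-layer `[M, K, D, K, M]` network is then
#' assembled by copying the stage-1 weights into the outer encoder/decoder
#' layers and the stage-2 weights into the inner pair. Immediately after
#' assembly the composed network reproduces the two stages exactly.
#'
#' @param data Matrix with samples in rows, entries in `[0, 1]`.
#' @param arch An [ae_architecture()].
#' @param config A [train_config()].
#' @return List with class `"ae_model"`: `params` (`[M, K, D, K, M]`
#'   network), `arch`, and `training_log` (per-stage loss traces).
#' @export
pretrain_ae5 <- function(data, arch, config = train_config()) {
  stopifnot(inherits(arch, "ae_architecture"))
  data <- as.matrix(data)
  check_unit_interval(data, "pretrain_ae5")
  if (ncol(data) != arch$input_dim)
    stop("pretrain_ae5: data has ", ncol(data),
         " columns but architecture expects ", arch$input_dim)
  stage1 <- train_ae3(data, arch$outer_hidden, config)
  codes <- encode_ae3(stage1, data)
  stage2 <- train_ae3(codes, arch$code_dim, config)

  params <- structure(
    list(W = list(stage1$W[[1]], stage2$W[[1]], stage2$W[[2]], stage1$W[[2]]),
         b = list(stage1$b[[1]], stage2$b[[1]], stage2$b[[2]], stage1$b[[2]]),
         sizes = c(arch$input_dim, arch$outer_hidden, arch$code_dim,
                   arch$outer_hidden, arch$input_dim)),
    class = "net_params")
  validate_net_params(params)
  structure(list(params = params, arch = arch,
                 training_log = list(stage1 = attr(stage1, "training_log"),
                                     stage2 = attr(stage2, "training_log"),
                                     finetune = numeric(0))),
            class = "ae_model")
}

#' Fine-tune a five-layer autoencoder end to end
#'
#' Continues training the assembled `[M, K, D, K, M]` network on `(x, x)`
#' pairs with the same update rule used for pretraining. With `epochs = 0`
#' the model is returned unchanged.
#'
#' @param model An `"ae_model"` from [pretrain_ae5()].
#' @param data Matrix with samples in rows, entries in `[0, 1]`.
#' @param config A [train_config()].
#' @param epochs Sweeps; defaults to `config$epochs`.
#' @return The fine-tuned `"ae_model"` with its `training_log` extended.
#' @export
finetune_ae5 <- function(model, data, config = train_config(),
                         epochs = config$epochs) {
  stopifnot(inherits(model, "ae_model"))
  data <- as.matrix(data)
  check_unit_interval(data, "finetune_ae5")
  if (epochs == 0) return(model)
  fit <- train_net(model$params, data, data, config, epochs = epochs)
  model$params <- fit$params
  model$training_log$finetune <- c(model$training_log$finetune, fit$loss)
  model
}

#' Fit a five-layer autoencoder (pretrain, then fine-tune)
#'
#' Convenience wrapper: [pretrain_ae5()] followed, by default, by
#' [finetune_ae5()].
#'
#' @inheritParams pretrain_ae5
#' @param finetune Logical; fine-tune end to end after the greedy copy.
#' @return An `"ae_model"`.
#' @export
fit_autoencoder <- function(data, arch, config = train_config(),
                            finetune = TRUE) {
  model <- pretrain_ae5(data, arch, config)
  if (finetune) model <- finetune_ae5(model, data, config)
  model
}

#' Encode data to bottleneck codes
#'
#' Applies the first two affine + sigmoid stages of a five-layer
#' autoencoder. Codes lie in `(0, 1)`.
#'
#' @param model An `"ae_model"`.
#' @param x Vector of length `M`, or matrix with samples in rows.
#' @return Code vector of length `D`, or an `N x D` matrix.
#' @export
ae_encode <- function(model, x) {
  stopifnot(inherits(model, "ae_model"))
  one <- is.null(dim(x))
  X <- if (one) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
  # same kernel as the full forward pass, so encode/decode composition is
  # bit-identical to running the assembled network
  z <- cpp_forward_batch(model$params$W[1:2], model$params$b[1:2], X)
  if (one) drop(z) else z
}

#' Decode bottleneck codes back to data space
#'
#' Applies the last two affine + sigmoid stages of a five-layer autoencoder,
#' so `ae_decode(model, ae_encode(model, x))` equals the full forward output.
#'
#' @param model An `"ae_model"`.
#' @param code Vector of length `D`, or matrix with codes in rows.
#' @return Reconstruction of length `M`, or an `N x M` matrix.
#' @export
ae_decode <- function(model, code) {
  stopifnot(inherits(model, "ae_model"))
  one <- is.null(dim(code))
  Z <- if (one) matrix(as.numeric(code), nrow = 1) else as.matrix(code)
  y <- cpp_forward_batch(model$params$W[3:4], model$params$b[3:4], Z)
  if (one) drop(y) else y
}

#' Absolute reconstruction error
#'
#' Sum of absolute deviations between the data and its reconstruction over
#' all `N x M` entries (a sum, not a mean) — the criterion used to compare
#' autoencoder and PCA compression and to pick hidden-layer widths.
#'
#' @param model An `"ae_model"`, or a `"net_params"` autoencoder.
#' @param data Matrix with samples in rows, width matching the model input.
#' @return Nonnegative scalar.
#' @export
reconstruction_error <- function(model, data) {
  params <- if (inherits(model, "ae_model")) model$params else model
  validate_net_params(params)
  data <- as.matrix(data)
  if (ncol(data) != params$sizes[1])
    stop("reconstruction_error: data width ", ncol(data),
         " does not match model input ", params$sizes[1])
  sum(abs(data - net_predict(params, data)))
}

#' @export
print.ae_model <- function(x, ...) {
  cat("Five-layer autoencoder (", x$arch$role, ")\n", sep = "")
  cat("  layers:", paste(x$params$sizes, collapse = " - "), "\n")
  ft <- x$training_log$finetune
  if (length(ft))
    cat("  fine-tuned", length(ft), "epochs; final loss",
        format(ft[length(ft)], digits = 4), "\n")
  else cat("  pretrained only (greedy weight copy)\n")
  invisible(x)
}
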