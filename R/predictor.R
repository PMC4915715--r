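#' Train the latent-space mapping perceptron
#'
#' Fits a multilayer perceptron from spectrum codes (bottleneck activations
#' of the spectrum autoencoder) to sensory codes, by supervised training
#' with the standard update rule.
#'
#' @param spec_codes `N x D_M` matrix of spectrum codes, entries in `(0, 1)`.
#' @param sens_codes `N x D_S` matrix of sensory codes, same row order.
#' @param config A [train_config()].
#' @param hidden Integer vector of hidden-layer widths (default
#'   `c(50, 55, 50)`).
#' @param epochs Sweeps; defaults to `config$epochs`.
#' @param init `"glorot"` (default) or a numeric half-width passed to
#'   [net_params()]. Unlike the autoencoders, the mapper gets no greedy
#'   pretraining; with a flat `0.03` init its three hidden sigmoid layers
#'   pass essentially no input signal and training plateaus, so the
#'   depth-scaled initialization is the default here.
#' @return List with class `"mapper_model"`: `params` (a `"net_params"`
#'   object over `c(D_M, hidden, D_S)`) and `training_log`.
#' @export
train_mapper <- function(spec_codes, sens_codes, config = train_config(),
                         hidden = c(50, 55, 50), epochs = config$epochs,
                         init = "glorot") {
  spec_codes <- as.matrix(spec_codes)
  sens_codes <- as.matrix(sens_codes)
  if (nrow(spec_codes) != nrow(sens_codes))
    stop("train_mapper: row counts differ (", nrow(spec_codes), " vs ",
         nrow(sens_codes), ")")
  params <- net_params(c(ncol(spec_codes), hidden, ncol(sens_codes)), init)
  fit <- train_net(params, spec_codes, sens_codes, config, epochs = epochs)
  structure(list(params = fit$params, training_log = fit$loss),
            class = "mapper_model")
}

#' Assemble the nine-layer spectrum-to-sensory network
#'
#' Pure rewiring: the spectrum autoencoder's encoder half (first two weight
#' layers), the mapper's layers, and the sensory autoencoder's decoder half
#' (last two weight layers) are concatenated into one feed-forward network.
#' At assembly time `predict` on the result is bit-identical to
#' `ae_decode(sens_ae, net_predict(mapper, ae_encode(spec_ae, x)))`.
#'
#' @param spec_ae Spectrum `"ae_model"`.
#' @param mapper A `"mapper_model"`.
#' @param sens_ae Sensory `"ae_model"`.
#' @return List with class `"nine_layer_model"`: `params` (e.g. layer sizes
#'   `212 85 45 50 55 50 30 65 144` with the default architecture) and
#'   `provenance`.
#' @export
assemble_nine_layer <- function(spec_ae, mapper, sens_ae) {
  stopifnot(inherits(spec_ae, "ae_model"), inherits(mapper, "mapper_model"),
            inherits(sens_ae, "ae_model"))
  mp <- mapper$params
  if (spec_ae$arch$code_dim != mp$sizes[1])
    stop("assemble_nine_layer: spectrum-code/mapper joint mismatch (code ",
         spec_ae$arch$code_dim, " vs mapper input ", mp$sizes[1], ")")
  if (mp$sizes[length(mp$sizes)] != sens_ae$arch$code_dim)
    stop("assemble_nine_layer: mapper/sensory-code joint mismatch (mapper ",
         "output ", mp$sizes[length(mp$sizes)], " vs code ",
         sens_ae$arch$code_dim, ")")
  sp <- spec_ae$params
  sn <- sens_ae$params
  params <- structure(
    list(W = c(sp$W[1:2], mp$W, sn$W[3:4]),
         b = c(sp$b[1:2], mp$b, sn$b[3:4]),
         sizes = c(sp$sizes[1:3], mp$sizes[-c(1, length(mp$sizes))],
                   sn$sizes[3:5])),
    class = "net_params")
  validate_net_params(params)
  structure(list(params = params,
                 provenance = list(spec_arch = spec_ae$arch,
                                   sens_arch = sens_ae$arch,
                                   mapper_sizes = mp$sizes)),
            class = "nine_layer_model")
}

#' Fine-tune the assembled nine-layer model end to end
#'
#' Backpropagates through all nine layers on (spectrum, sensory) pairs for a
#' small number of passes (about 5 by default). By default
#' (`config$finetune_lr_reset = FALSE`) the learning rate continues the
#' decay schedule as if fine-tuning were the tail of one long run: every
#' layer of the assembled network has already been trained through three
#' stages of `config$epochs` sweeps (two greedy autoencoder stages plus
#' end-to-end autoencoder fine-tuning, or mapper training), so the offset
#' is `3 * config$epochs` and the final adjustment is gentle. Restarting
#' the schedule at the full `eta0` (`finetune_lr_reset = TRUE`) overwrites
#' the pretrained composition within a few passes and is kept only as an
#' option.
#'
#' @param model A `"nine_layer_model"`.
#' @param spectra `N x M_spec` matrix in `[0, 1]`.
#' @param sensory `N x M_sens` matrix in `[0, 1]`.
#' @param config A [train_config()].
#' @param passes Epochs; defaults to `config$finetune_passes`.
#' @param lr_offset Epoch offset of the learning-rate schedule; `NULL`
#'   (default) resolves to 0 or `3 * config$epochs` per
#'   `config$finetune_lr_reset`.
#' @return The fine-tuned `"nine_layer_model"` with a `training_log` field.
#' @export
finetune_full <- function(model, spectra, sensory, config = train_config(),
                          passes = config$finetune_passes,
                          lr_offset = NULL) {
  stopifnot(inherits(model, "nine_layer_model"))
  if (passes == 0) return(model)
  offset <- if (!is.null(lr_offset)) lr_offset
            else if (isTRUE(config$finetune_lr_reset)) 0
            else 3 * config$epochs
  fit <- train_net(model$params, as.matrix(spectra), as.matrix(sensory),
                   config, epochs = passes, epoch_offset = offset)
  model$params <- fit$params
  model$training_log <- c(model$training_log, fit$loss)
  model
}

#' @export
predict.nine_layer_model <- function(object, newdata, ...) {
  net_predict(object$params, newdata)
}

#' Default layer widths for given data dimensions
#'
#' With the standard windowed-spectrum width (212 bins) and 144 descriptors
#' this returns the reference architecture `212 85 45 50 55 50 30 65 144`
#' (spectrum K = 85, D = 45; sensory K = 65, D = 30; mapper hidden
#' 50-55-50). For other input widths the widths are scaled proportionally
#' (the hidden-width sweeps in [dimension_sweep()] are the principled way to
#' choose them for new data).
#'
#' @param m_spec Number of spectrum bins.
#' @param m_sens Number of sensory descriptors.
#' @return List with `spectrum` and `sensory` [ae_architecture()]s and
#'   `mapper_hidden`.
#' @export
default_architecture <- function(m_spec = 212, m_sens = 144) {
  scale_dims <- function(m, k_ref, d_ref, m_ref) {
    if (m == m_ref) return(c(k_ref, d_ref))
    k <- max(2L, as.integer(round(m * k_ref / m_ref)))
    d <- max(1L, as.integer(round(m * d_ref / m_ref)))
    if (d >= k) d <- max(1L, k - 1L)
    c(k, d)
  }
  sp <- scale_dims(m_spec, 85L, 45L, 212L)
  sn <- scale_dims(m_sens, 65L, 30L, 144L)
  hidden <- if (m_spec == 212 && m_sens == 144) c(50L, 55L, 50L) else {
    h <- max(2L, as.integer(round((sp[2] + sn[2]) / 2)))
    c(h, h + 1L, h)
  }
  list(spectrum = ae_architecture(m_spec, sp[1], sp[2], "spectrum"),
       sensory = ae_architecture(m_sens, sn[1], sn[2], "sensory"),
       mapper_hidden = hidden)
}

#' Fit the odor-impression model
#'
#' The front door of the package: fits the full pipeline on paired,
#' max-normalized matrices — greedy pretraining and fine-tuning of a
#' spectrum autoencoder and a sensory autoencoder, supervised training of
#' the latent-space mapper on the two code sets, assembly of the nine-layer
#' network, and a few end-to-end fine-tuning passes.
#'
#' @param x Spectrum matrix, samples in rows, entries in `[0, 1]`
#'   (see [window_mz()] and [normalize_max()]).
#' @param y Sensory matrix, same rows, entries in `[0, 1]`.
#' @param config A [train_config()]; `config$seed`, when set, makes the fit
#'   reproducible.
#' @param arch Architecture list as from [default_architecture()]; derived
#'   from the data dimensions when `NULL`.
#' @param finetune_ae Logical; fine-tune each autoencoder end to end after
#'   the greedy weight copy (default `TRUE`).
#' @return An object of class `"odor_model"` with components `net` (the
#'   assembled and fine-tuned `"nine_layer_model"`), `spec_ae`, `sens_ae`,
#'   `mapper`, `arch`, `config`, `fitted` (training-set predictions),
#'   `descriptors` (column names of `y`) and `call`.
#' @seealso [predict.odor_model()], [run_cv()] for the cross-validated
#'   protocol, [pls_baseline()] for the linear comparison.
#' @export
#' @examples
#' d <- gen_dataset(synth_config(n_samples = 40, n_mz_bins = 30,
#'                               n_descriptors = 12, seed = 1))
#' cfg <- train_config(epochs = 15, seed = 1)
#' fit <- odor_model(d$spectra, d$sensory, cfg)
#' fit
#' head(predict(fit, d$spectra[1:2, , drop = FALSE]))
odor_model <- function(x, y, config = train_config(), arch = NULL,
                       finetune_ae = TRUE) {
  cl <- match.call()
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y))
    stop("odor_model: x and y must have the same number of rows; ",
         "use align_by_id() to pair them")
  check_unit_interval(x, "odor_model (x)")
  check_unit_interval(y, "odor_model (y)")
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(arch)) arch <- default_architecture(ncol(x), ncol(y))

  spec_ae <- fit_autoencoder(x, arch$spectrum, config, finetune = finetune_ae)
  sens_ae <- fit_autoencoder(y, arch$sensory, config, finetune = finetune_ae)
  mapper <- train_mapper(ae_encode(spec_ae, x), ae_encode(sens_ae, y),
                         config, hidden = arch$mapper_hidden)
  net <- assemble_nine_layer(spec_ae, mapper, sens_ae)
  net <- finetune_full(net, x, y, config)

  fitted <- net_predict(net$params, x)
  colnames(fitted) <- colnames(y)
  structure(list(net = net, spec_ae = spec_ae, sens_ae = sens_ae,
                 mapper = mapper, arch = arch, config = config,
                 fitted = fitted, y = y, descriptors = colnames(y),
                 call = cl),
            class = "odor_model")
}

#' Predict odor-impression profiles for new spectra
#'
#' @param object An `"odor_model"`.
#' @param newdata Spectrum matrix (samples in rows) or a single spectrum
#'   vector, preprocessed like the training data.
#' @param ... Unused.
#' @return Matrix of predicted descriptor applicabilities in `(0, 1)`,
#'   one row per spectrum, columns named after the training descriptors.
#' @export
predict.odor_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(as.numeric(newdata), nrow = 1)
  out <- net_predict(object$net$params, newdata)
  colnames(out) <- object$descriptors
  out
}

#' @export
print.odor_model <- function(x, ...) {
  cat("Nine-layer odor-impression model\n")
  cat("  layers:", paste(x$net$params$sizes, collapse = " - "), "\n")
  cat("  samples:", nrow(x$fitted), " spectra bins:", x$net$params$sizes[1],
      " descriptors:", x$net$params$sizes[length(x$net$params$sizes)], "\n")
  cat("  free parameters:", n_params(x$net$params), "\n")
  invisible(x)
}

#' @export
summary.odor_model <- function(object, ...) {
  res <- object$y - object$fitted
  tl <- object$net$training_log
  out <- list(sizes = object$net$params$sizes,
              n = nrow(object$fitted),
              n_params = n_params(object$net$params),
              train_r = cor(as.vector(object$fitted), as.vector(object$y)),
              train_mae = mean(abs(res)),
              finetune_loss = tl)
  class(out) <- "summary.odor_model"
  out
}

#' @export
print.summary.odor_model <- function(x, ...) {
  cat("Nine-layer odor-impression model\n")
  cat("  layers:", paste(x$sizes, collapse = " - "),
      " (", x$n_params, "free parameters )\n")
  cat("  training samples:", x$n, "\n")
  cat("  training-set pooled Pearson R:", format(x$train_r, digits = 3), "\n")
  cat("  training-set mean |error|:", format(x$train_mae, digits = 3), "\n")
  if (length(x$finetune_loss))
    cat("  fine-tuning loss trace:",
        paste(format(x$finetune_loss, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.odor_model <- function(object, ...) object$net$params

#' @export
fitted.odor_model <- function(object, ...) object$fitted

#' @export
residuals.odor_model <- function(object, ...) object$y - object$fitted

#' Plot training diagnostics of an odor model
#'
#' Draws the per-epoch training-loss traces of the two autoencoders (their
#' fine-tuning stage), the latent-space mapper, and the final end-to-end
#' fine-tuning passes.
#'
#' @param x An `"odor_model"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.odor_model <- function(x, ...) {
  traces <- list(`spectrum AE` = x$spec_ae$training_log$finetune,
                 `sensory AE` = x$sens_ae$training_log$finetune,
                 mapper = x$mapper$training_log,
                 `9-layer fine-tune` = x$net$training_log)
  traces <- traces[vapply(traces, length, 0L) > 0]
  if (!length(traces)) {
    warning("no training traces recorded")
    return(invisible(x))
  }
  ylim <- range(unlist(traces))
  xlim <- c(1, max(vapply(traces, length, 0L)))
  plot(NA, xlim = xlim, ylim = ylim, xlab = "epoch",
       ylab = "mean per-sample loss", main = "Training traces", ...)
  for (i in seq_along(traces))
    lines(seq_along(traces[[i]]), traces[[i]], col = i, lwd = 2)
  legend("topright", legend = names(traces), col = seq_along(traces),
         lwd = 2, bty = "n")
  invisible(x)
}
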