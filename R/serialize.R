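#' Save a fitted model or network parameters to a JSON archive
#'
#' Portable, versioned text schema: layer sizes plus flattened
#' (column-major) weight and bias arrays. Handles a bare `"net_params"`
#' object or a full `"odor_model"` (whose autoencoders, mapper,
#' architecture, config and descriptor names are all stored).
#'
#' @param object A `"net_params"` or `"odor_model"` object.
#' @param path Output path (conventionally `.json`).
#' @export
save_model <- function(object, path) {
  payload <- if (inherits(object, "net_params")) {
    list(schema = "odormap-net", version = "1.0",
         net = pack_params(object))
  } else if (inherits(object, "odor_model")) {
    list(schema = "odormap-model", version = "1.0",
         net = pack_params(object$net$params),
         spec_ae = pack_params(object$spec_ae$params),
         sens_ae = pack_params(object$sens_ae$params),
         mapper = pack_params(object$mapper$params),
         arch = list(
           spectrum = unclass(object$arch$spectrum),
           sensory = unclass(object$arch$sensory),
           mapper_hidden = object$arch$mapper_hidden),
         config = unclass(object$config),
         descriptors = object$descriptors)
  } else stop("save_model: unsupported object of class ",
              paste(class(object), collapse = "/"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

pack_params <- function(params) {
  list(layer_sizes = params$sizes,
       weights = lapply(params$W, as.numeric),
       biases = lapply(params$b, as.numeric))
}

unpack_params <- function(x) {
  sizes <- as.integer(unlist(x$layer_sizes))
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(as.numeric(unlist(x$weights[[l]])),
                     nrow = sizes[l + 1L], ncol = sizes[l])
    b[[l]] <- as.numeric(unlist(x$biases[[l]]))
  }
  validate_net_params(structure(list(W = W, b = b, sizes = sizes),
                                class = "net_params"))
}

#' Load a model saved by [save_model()]
#'
#' @param path Path to the JSON archive.
#' @return A `"net_params"` or `"odor_model"` object, depending on what was
#'   saved. A reloaded `"odor_model"` predicts identically to the original;
#'   its training-set fields (`fitted`, `y`) are not stored.
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path)
  if (identical(x$schema, "odormap-net")) return(unpack_params(x$net))
  if (!identical(x$schema, "odormap-model"))
    stop("load_model: unrecognized schema in ", path)
  arch <- list(
    spectrum = suppressWarnings(ae_architecture(
      x$arch$spectrum$input_dim, x$arch$spectrum$outer_hidden,
      x$arch$spectrum$code_dim, x$arch$spectrum$role)),
    sensory = suppressWarnings(ae_architecture(
      x$arch$sensory$input_dim, x$arch$sensory$outer_hidden,
      x$arch$sensory$code_dim, x$arch$sensory$role)),
    mapper_hidden = as.integer(unlist(x$arch$mapper_hidden)))
  cfg <- do.call(train_config, x$config[setdiff(names(x$config), "seed")])
  cfg$seed <- x$config$seed
  spec_ae <- structure(list(params = unpack_params(x$spec_ae),
                            arch = arch$spectrum,
                            training_log = list()), class = "ae_model")
  sens_ae <- structure(list(params = unpack_params(x$sens_ae),
                            arch = arch$sensory,
                            training_log = list()), class = "ae_model")
  mapper <- structure(list(params = unpack_params(x$mapper),
                           training_log = numeric(0)),
                      class = "mapper_model")
  net <- structure(list(params = unpack_params(x$net),
                        provenance = list(restored_from = path)),
                   class = "nine_layer_model")
  descr <- if (length(x$descriptors)) unlist(x$descriptors) else NULL
  structure(list(net = net, spec_ae = spec_ae, sens_ae = sens_ae,
                 mapper = mapper, arch = arch, config = cfg,
                 fitted = NULL, y = NULL, descriptors = descr,
                 call = NULL),
            class = "odor_model")
}

#' Read a training configuration from YAML or JSON
#'
#' Field names mirror [train_config()] arguments; unknown fields are an
#' error. JSON is detected by the `.json` extension.
#'
#' @param path Path to a YAML or JSON file.
#' @return A [train_config()].
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(train_config)))
  if (length(unknown))
    stop("read_config: unknown field(s): ", paste(unknown, collapse = ", "))
  do.call(train_config, vals)
}
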