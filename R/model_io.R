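MODEL_ARCHIVE_FORMAT <- "metsite-model"
MODEL_ARCHIVE_VERSION <- 1L

# doubles travel as %.17g strings: enough digits to reproduce every IEEE-754
# double bit-identically after the round trip
num_out <- function(x) sprintf("%.17g", as.numeric(x))
num_in <- function(x) as.numeric(unlist(x))

serialize_layers <- function(layers) {
  lapply(layers, function(l) list(
    fan_in = nrow(l$W), fan_out = ncol(l$W),
    activation = l$activation,
    # column-major flat vector; shape restored from fan_in/fan_out
    weights = num_out(l$W),
    bias = num_out(l$b)))
}

deserialize_layers <- function(spec) {
  layers <- lapply(spec, function(l) {
    W <- matrix(num_in(l$weights), as.integer(l$fan_in), as.integer(l$fan_out))
    list(W = W, b = num_in(l$bias), activation = as.character(l$activation))
  })
  validate_network(structure(list(layers = unname(layers)),
                             class = "dense_network"))
}

#' Save / load a trained model archive
#'
#' The archive is a self-describing JSON container holding, per layer, the
#' weight matrix (flattened column-major), bias vector and activation tag,
#' plus -- for a fitted site model -- the class levels, gene panel and the
#' per-gene standardization statistics needed to replay identical
#' preprocessing on new data. Numbers are written at full precision, so a
#' save/load round trip reproduces the network bit-identically.
#'
#' @param model A `dense_network` or a fitted `site_model`.
#' @param path Output path (conventionally `.json`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   reconstructed object.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "dense_network")) {
    payload <- list(format = MODEL_ARCHIVE_FORMAT, version = MODEL_ARCHIVE_VERSION,
                    type = "dense_network", layers = serialize_layers(model$layers))
  } else if (inherits(model, "site_model")) {
    payload <- list(
      format = MODEL_ARCHIVE_FORMAT, version = MODEL_ARCHIVE_VERSION,
      type = "site_model",
      layers = serialize_layers(model$network$layers),
      classes = model$classes,
      panel_genes = model$panel_genes,
      standardize = list(mean = num_out(model$stats$mean),
                         sd = num_out(model$stats$sd),
                         gene = names(model$stats$mean)),
      training = model$training %||% list())
  } else stop("model must be a dense_network or site_model", call. = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stop("corrupt model archive: ", path,
                                               " (", conditionMessage(e), ")",
                                               call. = FALSE))
  if (!identical(payload$format, MODEL_ARCHIVE_FORMAT) ||
      !identical(as.integer(payload$version), MODEL_ARCHIVE_VERSION))
    stop("not a supported model archive (format/version mismatch): ", path,
         call. = FALSE)
  spec <- payload$layers
  if (is.data.frame(spec)) spec <- split(spec, seq_len(nrow(spec)))
  net <- deserialize_layers(spec)
  if (identical(payload$type, "dense_network")) return(net)
  stats <- list(mean = stats::setNames(num_in(payload$standardize$mean),
                                       payload$standardize$gene),
                sd = stats::setNames(num_in(payload$standardize$sd),
                                     payload$standardize$gene))
  structure(list(network = net,
                 classes = as.character(payload$classes),
                 panel_genes = as.character(payload$panel_genes),
                 stats = stats,
                 training = payload$training,
                 history = NULL),
            class = "site_model")
}
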