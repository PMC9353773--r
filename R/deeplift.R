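#' Build a DeepLIFT reference input
#'
#' DeepLIFT explains the difference between a sample's output and the output
#' of a reference input. The default reference is the per-gene mean of the
#' training matrix (the natural baseline for z-scored expression data); an
#' all-zero reference and a fully custom vector are also supported.
#'
#' @param matrix Genes x samples training matrix (defines the gene order and,
#'   for `train_mean`, the values).
#' @param mode One of `"train_mean"`, `"zeros"`, `"custom"`.
#' @param values Numeric vector for `mode = "custom"`; must have one value per
#'   gene (names, if present, must match).
#' @return A `deeplift_reference`: list with `values` (named numeric) and
#'   `mode`.
#' @export
make_reference <- function(matrix, mode = c("train_mean", "zeros", "custom"),
                           values = NULL) {
  mode <- match.arg(mode)
  assert_expression_matrix(matrix)
  genes <- rownames(matrix)
  vals <- switch(mode,
                 train_mean = rowMeans(matrix),
                 zeros = stats::setNames(numeric(nrow(matrix)), genes),
                 custom = {
                   if (is.null(values) || length(values) != nrow(matrix))
                     stop("custom reference must supply one value per gene (",
                          nrow(matrix), ")", call. = FALSE)
                   if (!is.null(names(values)) && !identical(names(values), genes))
                     values <- values[genes]
                   stats::setNames(as.numeric(values), genes)
                 })
  if (anyNA(vals)) stop("reference contains missing values", call. = FALSE)
  structure(list(values = vals, mode = mode), class = "deeplift_reference")
}

reference_vector <- function(reference, fan_in) {
  vals <- if (inherits(reference, "deeplift_reference")) reference$values
  else as.numeric(reference)
  if (length(vals) != fan_in)
    stop("reference width ", length(vals), " does not match network fan_in ",
         fan_in, call. = FALSE)
  vals
}

# Forward both the samples and the reference, and compute per-layer deltas and
# rescale-rule multipliers. Near-zero pre-activation deltas (|d_pre| < 1e-9)
# fall back to the derivative at the reference, which keeps the chain rule
# finite. The final softmax layer gets no multiplier: attribution targets the
# pre-softmax logit.
dl_state <- function(network, inputs, reference) {
  ref <- reference_vector(reference, net_fan_in(network))
  fx <- forward(network, inputs, record_activations = TRUE)
  fr <- forward(network, matrix(ref, nrow = 1), record_activations = TRUE)
  L <- length(network$layers)
  d_pre <- d_post <- mult <- vector("list", L)
  for (l in seq_len(L)) {
    act <- network$layers[[l]]$activation
    dp <- sweep(fx$pre[[l]], 2L, fr$pre[[l]][1, ], "-")
    da <- sweep(fx$post[[l]], 2L, fr$post[[l]][1, ], "-")
    d_pre[[l]] <- dp
    d_post[[l]] <- da
    if (act == "softmax") {
      mult[[l]] <- NULL  # attribution never rescales through softmax
    } else {
      m <- da / dp
      tiny <- abs(dp) < 1e-9
      if (any(tiny)) {
        dref <- act_deriv(fr$pre[[l]], act)[1, ]
        m[tiny] <- matrix(dref, nrow(dp), ncol(dp), byrow = TRUE)[tiny]
      }
      mult[[l]] <- m
    }
  }
  list(d_pre = d_pre, d_post = d_post, mult = mult,
       d_x = sweep(inputs, 2L, ref, "-"), L = L,
       softmax_final = network$layers[[L]]$activation == "softmax")
}

# Backward chain of DeepLIFT multipliers from layer `layer` down to the
# inputs. `v` is a samples x units(layer) matrix of multipliers on the POST
# activation of `layer` (or on the logits when from_logit). Returns the list
# of per-layer post-activation multiplier matrices, index 0 = inputs (stored
# at position l+1 in the returned list).
dl_backward <- function(network, state, layer, v, from_logit = FALSE) {
  v_post <- vector("list", layer + 1L)
  v_post[[layer + 1L]] <- v
  v_pre <- if (from_logit) v else v * state$mult[[layer]]
  for (l in layer:1) {
    v_lower <- v_pre %*% t(network$layers[[l]]$W)
    v_post[[l]] <- v_lower
    if (l > 1) v_pre <- v_lower * state$mult[[l - 1]]
  }
  v_post
}

#' DeepLIFT contribution scores of the inputs to a target neuron
#'
#' Implements the rescale rule for dense relu/sigmoid networks: affine layers
#' propagate multipliers through the weights (linear rule), nonlinearities use
#' `delta(post) / delta(pre)` with a derivative-at-reference fallback for
#' near-zero deltas. Contributions satisfy summation-to-delta: for every
#' sample the contributions of all inputs add up to the target's activation
#' difference from the reference. When the final layer is softmax, the target
#' is the pre-softmax logit of the requested output unit.
#'
#' @param network A `dense_network`.
#' @param inputs Samples x fan_in matrix (or single vector).
#' @param reference A [make_reference()] object or plain numeric vector.
#' @param layer Index of the target layer (default: output layer).
#' @param neuron Index of the target neuron within that layer.
#' @return An `attribution`: list with `contributions` (samples x inputs),
#'   `delta` (per-sample target delta), `layer`, `neuron`, `target_is_logit`,
#'   `reference`.
#' @export
deeplift_attribute <- function(network, inputs, reference,
                               layer = NULL, neuron = 1L) {
  validate_network(network)
  if (is.vector(inputs)) inputs <- matrix(inputs, nrow = 1)
  L <- length(network$layers)
  layer <- layer %||% L
  if (layer < 1 || layer > L) stop("target layer out of range", call. = FALSE)
  units <- ncol(network$layers[[layer]]$W)
  if (neuron < 1 || neuron > units) stop("target neuron out of range", call. = FALSE)
  state <- dl_state(network, inputs, reference)
  from_logit <- (layer == L) && state$softmax_final
  v <- matrix(0, nrow(inputs), units)
  v[, neuron] <- 1
  v_post <- dl_backward(network, state, layer, v, from_logit)
  contrib <- state$d_x * v_post[[1L]]
  colnames(contrib) <- colnames(inputs) %||%
    names(if (inherits(reference, "deeplift_reference")) reference$values else NULL)
  delta <- if (from_logit) state$d_pre[[layer]][, neuron] else
    state$d_post[[layer]][, neuron]
  structure(list(contributions = contrib, delta = delta, layer = layer,
                 neuron = neuron, target_is_logit = from_logit,
                 reference = reference),
            class = "attribution")
}

#' Class-conditional relevance scores of every neuron
#'
#' Starting from the output delta of one class, DeepLIFT multipliers are
#' propagated backward and each neuron's relevance in layer L is the sum of
#' its contributions to all neurons of layer L+1. Relevance is conserved: in
#' every layer the neuron relevances add up to the class-output delta of each
#' sample. For a softmax classifier the class's pre-softmax logit is the
#' starting point.
#'
#' @param network A `dense_network` classifier or a fitted `site_model` (in
#'   which case `inputs` may be a raw genes x samples matrix and the stored
#'   standardization/panel are applied).
#' @param inputs Samples x fan_in matrix (dense_network) or genes x samples
#'   expression matrix (site_model).
#' @param reference [make_reference()] object or numeric vector; ignored for a
#'   `site_model` when `NULL` (the stored training means, i.e. the zero vector
#'   in standardized space, are used).
#' @param class Output unit index, or class name for a `site_model`.
#' @return A `relevance_profile`: list with per-layer samples x units
#'   relevance matrices (`layers`, hidden layers then `output`), their column
#'   means (`mean`), per-sample output `delta` and the `class` label.
#' @export
neuron_relevance <- function(network, inputs, reference = NULL, class = 1L) {
  if (inherits(network, "site_model")) {
    prep <- prepare_site_inputs(network, inputs)
    if (is.character(class)) {
      class <- match(class, network$classes)
      if (is.na(class)) stop("unknown class label", call. = FALSE)
    }
    reference <- reference %||% numeric(length(network$panel_genes))
    label <- network$classes[class]
    network <- network$network
    inputs <- prep
  } else {
    label <- as.character(class)
  }
  validate_network(network)
  if (is.vector(inputs)) inputs <- matrix(inputs, nrow = 1)
  if (nrow(inputs) == 0) stop("no samples to propagate", call. = FALSE)
  L <- length(network$layers)
  units_out <- net_fan_out(network)
  if (class < 1 || class > units_out) stop("class index out of range", call. = FALSE)
  state <- dl_state(network, inputs, reference %||% numeric(net_fan_in(network)))
  from_logit <- state$softmax_final
  v <- matrix(0, nrow(inputs), units_out)
  v[, class] <- 1
  v_post <- dl_backward(network, state, L, v, from_logit)
  delta <- if (from_logit) state$d_pre[[L]][, class] else state$d_post[[L]][, class]
  layers <- vector("list", L)
  for (l in seq_len(L - 1L)) layers[[l]] <- state$d_post[[l]] * v_post[[l + 1L]]
  out_rel <- matrix(0, nrow(inputs), units_out)
  out_rel[, class] <- delta
  layers[[L]] <- out_rel
  names(layers) <- c(paste0("hidden_", seq_len(L - 1L)), "output")
  structure(list(class = label, class_index = class, layers = layers,
                 mean = lapply(layers, colMeans), delta = delta,
                 target_is_logit = from_logit),
            class = "relevance_profile")
}
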