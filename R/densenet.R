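ACTIVATIONS <- c("relu", "linear", "sigmoid", "softmax")
LOSSES <- c("mae", "binary_cross_entropy", "categorical_cross_entropy")

validate_network <- function(network) {
  layers <- network$layers
  if (!length(layers)) stop("network has no layers", call. = FALSE)
  for (l in seq_along(layers)) {
    lay <- layers[[l]]
    if (!lay$activation %in% ACTIVATIONS)
      stop("unknown activation: ", lay$activation, call. = FALSE)
    if (lay$activation == "softmax" && l != length(layers))
      stop("softmax is only allowed on the final layer", call. = FALSE)
    if (length(lay$b) != ncol(lay$W))
      stop("layer ", l, ": bias length does not match fan_out", call. = FALSE)
    if (!all(is.finite(lay$W)) || !all(is.finite(lay$b)))
      stop("layer ", l, ": non-finite weights", call. = FALSE)
    if (l > 1 && nrow(lay$W) != ncol(layers[[l - 1]]$W))
      stop("layer dimensions do not chain at layer ", l, call. = FALSE)
  }
  network
}

net_fan_in <- function(network) nrow(network$layers[[1]]$W)
net_fan_out <- function(network) ncol(network$layers[[length(network$layers)]]$W)

#' Initialise a dense feedforward network
#'
#' Weights are drawn from the Glorot (scaled uniform) scheme,
#' `U(-sqrt(6/(fan_in+fan_out)), +sqrt(6/(fan_in+fan_out)))`; biases start at
#' zero. Initialisation is deterministic for a given seed.
#'
#' @param layer_sizes Integer vector of unit counts, input layer first, e.g.
#'   `c(1000, 500, 100, 500, 1000)` for the autoencoder.
#' @param activations One activation tag per weight layer
#'   (`length(layer_sizes) - 1`), each of `"relu"`, `"linear"`, `"sigmoid"`,
#'   `"softmax"` (final layer only).
#' @param seed Integer seed.
#' @return A `dense_network`.
#' @export
init_network <- function(layer_sizes, activations, seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2 || any(layer_sizes < 1))
    stop("layer_sizes must be >= 2 positive integers", call. = FALSE)
  if (length(activations) != length(layer_sizes) - 1L)
    stop("need exactly one activation per weight layer (",
         length(layer_sizes) - 1L, "), got ", length(activations), call. = FALSE)
  with_seed(seed, {
    layers <- vector("list", length(activations))
    for (l in seq_along(layers)) {
      fan_in <- layer_sizes[l]; fan_out <- layer_sizes[l + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))
      layers[[l]] <- list(
        W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
        b = numeric(fan_out),
        activation = activations[l])
    }
    validate_network(structure(list(layers = layers), class = "dense_network"))
  })
}

#' @export
print.dense_network <- function(x, ...) {
  sizes <- c(net_fan_in(x), vapply(x$layers, function(l) ncol(l$W), 1L))
  acts <- vapply(x$layers, function(l) l$activation, "")
  cat("dense_network:", paste(sizes, collapse = "-"),
      "(", paste(acts, collapse = ", "), ")\n")
  invisible(x)
}

act_apply <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         linear = z,
         sigmoid = 1 / (1 + exp(-z)),
         softmax = {
           z <- z - apply(z, 1L, max)
           e <- exp(z)
           e / rowSums(e)
         })
}

# derivative wrt pre-activation (softmax handled jointly with its loss)
act_deriv <- function(pre, act) {
  switch(act,
         relu = (pre > 0) + 0,
         linear = array(1, dim(pre)),
         sigmoid = {
           s <- 1 / (1 + exp(-pre))
           s * (1 - s)
         },
         softmax = stop("softmax derivative is handled with its loss", call. = FALSE))
}

add_bias <- function(z, b) z + matrix(b, nrow(z), ncol(z), byrow = TRUE)

#' Forward pass through a dense network
#'
#' Deterministic inference pass (dropout is a training-time device only).
#'
#' @param network A `dense_network`.
#' @param inputs Samples x fan_in numeric matrix (or a single input vector).
#' @param record_activations If `TRUE`, also return the pre- and
#'   post-activation values of every layer (needed by the attribution code).
#' @return The output matrix, or (when recording) a list with `output`, `pre`,
#'   `post`.
#' @export
forward <- function(network, inputs, record_activations = FALSE) {
  if (is.vector(inputs)) inputs <- matrix(inputs, nrow = 1)
  if (ncol(inputs) != net_fan_in(network))
    stop("input width ", ncol(inputs), " does not match network fan_in ",
         net_fan_in(network), call. = FALSE)
  L <- length(network$layers)
  pre <- post <- vector("list", L)
  a <- inputs
  for (l in seq_len(L)) {
    lay <- network$layers[[l]]
    z <- add_bias(a %*% lay$W, lay$b)
    a <- act_apply(z, lay$activation)
    if (record_activations) {
      pre[[l]] <- z
      post[[l]] <- a
    }
  }
  if (record_activations) list(output = a, pre = pre, post = post) else a
}

#' Training configuration for dense networks
#'
#' Defaults follow common practice for this architecture family: Adam
#' (lr 1e-3, beta1 0.9, beta2 0.999, eps 1e-8), batch size 32, L2 penalty
#' 1e-4, 10% inverted dropout on hidden layers, early stopping on a 10%
#' validation split with patience 10 and best-weight restoration.
#'
#' @param loss One of `"mae"`, `"binary_cross_entropy"`,
#'   `"categorical_cross_entropy"`.
#' @param epochs Maximum number of epochs (500 is the convention for the
#'   autoencoder, 100 for the classifiers).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param l2_lambda L2 penalty coefficient (gradient term `lambda * w`).
#' @param dropout_rate Hidden-layer dropout probability in `[0, 1)`.
#' @param early_stopping Use a validation split with patience-based stopping.
#' @param validation_fraction Fraction of rows held out for validation.
#' @param patience Epochs without validation improvement before stopping.
#' @param seed Integer seed governing the split, shuffling and dropout masks.
#' @param verbose Print one log line per epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(loss = c("mae", "binary_cross_entropy",
                                  "categorical_cross_entropy"),
                         epochs = 100L, batch_size = 32L, learning_rate = 1e-3,
                         l2_lambda = 1e-4, dropout_rate = 0.10,
                         early_stopping = TRUE, validation_fraction = 0.10,
                         patience = 10L, seed = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, l2_lambda >= 0,
            dropout_rate >= 0, dropout_rate < 1,
            validation_fraction > 0, validation_fraction < 1, patience >= 1)
  structure(list(loss = loss, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, l2_lambda = l2_lambda,
                 dropout_rate = dropout_rate, early_stopping = early_stopping,
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience), seed = seed,
                 verbose = verbose),
            class = "train_config")
}

loss_value <- function(out, Y, loss) {
  switch(loss,
         mae = mean(abs(out - Y)),
         binary_cross_entropy = {
           p <- pmin(pmax(out, 1e-12), 1 - 1e-12)
           -mean(Y * log(p) + (1 - Y) * log(1 - p))
         },
         categorical_cross_entropy = {
           p <- pmax(out, 1e-12)
           -sum(Y * log(p)) / nrow(Y)
         })
}

check_loss_compat <- function(network, loss) {
  final_act <- network$layers[[length(network$layers)]]$activation
  if (loss == "categorical_cross_entropy" && final_act != "softmax")
    stop("categorical_cross_entropy requires a softmax output layer", call. = FALSE)
  if (loss == "binary_cross_entropy" &&
      !(final_act == "sigmoid"))
    stop("binary_cross_entropy requires a sigmoid output layer", call. = FALSE)
  if (loss == "mae" && final_act == "softmax")
    stop("mae with a softmax output is not supported", call. = FALSE)
  invisible(TRUE)
}

# Training-mode forward pass: inverted dropout on hidden layers, cache of
# everything backprop needs. `aout` is the (possibly dropped-out) input fed to
# the next layer; `post` is the raw post-activation.
forward_train <- function(layers, X, dropout_rate) {
  L <- length(layers)
  pre <- post <- masks <- aout <- vector("list", L)
  a <- X
  for (l in seq_len(L)) {
    lay <- layers[[l]]
    z <- add_bias(a %*% lay$W, lay$b)
    h <- act_apply(z, lay$activation)
    pre[[l]] <- z; post[[l]] <- h
    if (dropout_rate > 0 && l < L) {
      m <- matrix((stats::runif(length(h)) >= dropout_rate) / (1 - dropout_rate),
                  nrow(h), ncol(h))
      h <- h * m
      masks[[l]] <- m
    }
    aout[[l]] <- h
    a <- h
  }
  list(X = X, pre = pre, post = post, masks = masks, aout = aout, output = a)
}

backprop <- function(layers, cache, Y, loss, l2_lambda) {
  L <- length(layers)
  out <- cache$output
  delta <- switch(loss,
                  categorical_cross_entropy = (out - Y) / nrow(Y),
                  binary_cross_entropy = (out - Y) / length(Y),
                  mae = sign(out - Y) / length(Y) *
                    act_deriv(cache$pre[[L]], layers[[L]]$activation))
  grads <- vector("list", L)
  for (l in L:1) {
    a_prev <- if (l == 1) cache$X else cache$aout[[l - 1]]
    grads[[l]] <- list(W = crossprod(a_prev, delta) + l2_lambda * layers[[l]]$W,
                       b = colSums(delta))
    if (l > 1) {
      d_a <- delta %*% t(layers[[l]]$W)
      if (!is.null(cache$masks[[l - 1]])) d_a <- d_a * cache$masks[[l - 1]]
      delta <- d_a * act_deriv(cache$pre[[l - 1]], layers[[l - 1]]$activation)
    }
  }
  grads
}

#' Loss and analytic parameter gradients
#'
#' Dropout-free loss (including the L2 penalty `lambda/2 * sum(W^2)`) and its
#' exact gradients for every weight and bias. Exposed so the gradients can be
#' audited against finite differences.
#'
#' @param network A `dense_network`.
#' @param inputs Samples x fan_in matrix.
#' @param targets Target matrix matching the output layer.
#' @param loss Loss tag.
#' @param l2_lambda L2 penalty coefficient.
#' @return List with `loss` (numeric) and `gradients` (per layer, `W` and `b`).
#' @export
loss_and_gradients <- function(network, inputs, targets,
                               loss = c("mae", "binary_cross_entropy",
                                        "categorical_cross_entropy"),
                               l2_lambda = 0) {
  loss <- match.arg(loss)
  check_loss_compat(network, loss)
  if (is.vector(inputs)) inputs <- matrix(inputs, nrow = 1)
  targets <- as.matrix(targets)
  cache <- forward_train(network$layers, inputs, dropout_rate = 0)
  penalty <- if (l2_lambda > 0)
    0.5 * l2_lambda * sum(vapply(network$layers, function(l) sum(l$W^2), 0))
  else 0
  list(loss = loss_value(cache$output, targets, loss) + penalty,
       gradients = backprop(network$layers, cache, targets, loss, l2_lambda))
}

#' Train a dense network
#'
#' Minibatch Adam with an L2 gradient penalty, inverted dropout on hidden
#' layers (training only), and early stopping that restores the weights of the
#' best validation epoch. Fully reproducible for a given `config$seed`.
#'
#' @param network A `dense_network` (e.g. from [init_network()]).
#' @param inputs Samples x fan_in matrix.
#' @param targets Samples x fan_out matrix (for an autoencoder,
#'   `targets = inputs`).
#' @param config A [train_config()].
#' @return List with `network` (trained) and `history` (per-epoch train and
#'   validation loss, `stopped_epoch`, `best_epoch`).
#' @export
train <- function(network, inputs, targets, config = train_config()) {
  validate_network(network)
  check_loss_compat(network, config$loss)
  if (is.vector(inputs)) inputs <- matrix(inputs, nrow = 1)
  targets <- as.matrix(targets)
  if (nrow(inputs) != nrow(targets))
    stop("inputs and targets disagree on sample count", call. = FALSE)
  if (ncol(inputs) != net_fan_in(network) || ncol(targets) != net_fan_out(network))
    stop("input/target width does not match the network", call. = FALSE)

  with_seed(config$seed, {
    n <- nrow(inputs)
    if (config$early_stopping) {
      n_val <- max(1L, round(config$validation_fraction * n))
      if (n_val >= n) stop("too few samples for a validation split", call. = FALSE)
      val_idx <- sample.int(n, n_val)
      tr_idx <- setdiff(seq_len(n), val_idx)
    } else {
      val_idx <- integer(0)
      tr_idx <- seq_len(n)
    }
    layers <- network$layers
    adam <- lapply(layers, function(l) list(mW = 0 * l$W, vW = 0 * l$W,
                                            mb = 0 * l$b, vb = 0 * l$b))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    train_loss <- val_loss <- rep(NA_real_, config$epochs)
    best_val <- Inf; best_layers <- layers; best_epoch <- 0L; wait <- 0L
    stopped <- config$epochs

    for (epoch in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      starts <- seq(1L, length(ord), by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, length(ord))]
        cache <- forward_train(layers, inputs[idx, , drop = FALSE],
                               config$dropout_rate)
        grads <- backprop(layers, cache, targets[idx, , drop = FALSE],
                          config$loss, config$l2_lambda)
        step <- step + 1L
        for (l in seq_along(layers)) {
          g <- grads[[l]]
          st <- adam[[l]]
          st$mW <- b1 * st$mW + (1 - b1) * g$W
          st$vW <- b2 * st$vW + (1 - b2) * g$W^2
          st$mb <- b1 * st$mb + (1 - b1) * g$b
          st$vb <- b2 * st$vb + (1 - b2) * g$b^2
          adam[[l]] <- st
          c1 <- 1 - b1^step; c2 <- 1 - b2^step
          layers[[l]]$W <- layers[[l]]$W -
            config$learning_rate * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
          layers[[l]]$b <- layers[[l]]$b -
            config$learning_rate * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
        }
      }
      net_now <- structure(list(layers = layers), class = "dense_network")
      train_loss[epoch] <- loss_value(
        forward(net_now, inputs[tr_idx, , drop = FALSE]),
        targets[tr_idx, , drop = FALSE], config$loss)
      if (!is.finite(train_loss[epoch]))
        stop("training loss became non-finite at epoch ", epoch,
             "; try a lower learning_rate", call. = FALSE)
      if (config$early_stopping) {
        val_loss[epoch] <- loss_value(
          forward(net_now, inputs[val_idx, , drop = FALSE]),
          targets[val_idx, , drop = FALSE], config$loss)
        if (config$verbose)
          message(sprintf("epoch %d train %.6f val %.6f", epoch,
                          train_loss[epoch], val_loss[epoch]))
        if (val_loss[epoch] < best_val) {
          best_val <- val_loss[epoch]
          best_layers <- layers
          best_epoch <- epoch
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= config$patience) {
            stopped <- epoch
            break
          }
        }
        stopped <- epoch
      } else {
        if (config$verbose)
          message(sprintf("epoch %d train %.6f", epoch, train_loss[epoch]))
        best_epoch <- epoch
        stopped <- epoch
      }
    }
    if (config$early_stopping) layers <- best_layers
    history <- structure(list(train_loss = train_loss[seq_len(stopped)],
                              val_loss = val_loss[seq_len(stopped)],
                              stopped_epoch = stopped,
                              best_epoch = best_epoch),
                         class = "train_history")
    list(network = validate_network(structure(list(layers = layers),
                                              class = "dense_network")),
         history = history)
  })
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("train_history: stopped at epoch %d (best %d), final train loss %.5f\n",
              x$stopped_epoch, x$best_epoch,
              x$train_loss[length(x$train_loss)]))
  invisible(x)
}
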