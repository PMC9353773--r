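`%||%` <- function(a, b) if (is.null(a)) b else a

# Random dense network with non-zero biases (exercises the affine terms).
rand_net <- function(seed, max_layers = 4L, max_units = 64L, n_in = NULL,
                     final_act = NULL, hidden_acts = c("relu", "linear", "sigmoid")) {
  set.seed(seed)
  n_layers <- sample(2:max_layers, 1)
  sizes <- c(n_in %||% sample(3:12, 1), sample(2:max_units, n_layers, replace = TRUE))
  acts <- c(sample(hidden_acts, n_layers - 1, replace = TRUE),
            final_act %||% sample(c("relu", "linear", "sigmoid"), 1))
  net <- init_network(sizes, acts, seed = seed + 1L)
  for (l in seq_along(net$layers))
    net$layers[[l]]$b <- stats::rnorm(length(net$layers[[l]]$b), sd = 0.3)
  net
}

# Central-difference check of loss_and_gradients over every parameter.
max_grad_rel_err <- function(net, X, Y, loss, l2 = 0, h = 1e-6) {
  ana <- loss_and_gradients(net, X, Y, loss, l2)$gradients
  worst <- 0
  f <- function(n) loss_and_gradients(n, X, Y, loss, l2)$loss
  for (l in seq_along(net$layers)) {
    for (field in c("W", "b")) {
      for (i in seq_along(net$layers[[l]][[field]])) {
        np <- net; np$layers[[l]][[field]][i] <- np$layers[[l]][[field]][i] + h
        nm <- net; nm$layers[[l]][[field]][i] <- nm$layers[[l]][[field]][i] - h
        fd <- (f(np) - f(nm)) / (2 * h)
        err <- abs(fd - ana[[l]][[field]][i]) / max(abs(fd), abs(ana[[l]][[field]][i]), 1e-4)
        worst <- max(worst, err)
      }
    }
  }
  worst
}

# Small labelled two-class dataset with `n_sep` perfectly separating genes.
toy_binary <- function(n_genes = 30L, n_sep = 0L, n_pos = 20L, n_neg = 30L,
                       shift = 4, seed = 1L) {
  set.seed(seed)
  m <- n_pos + n_neg
  X <- matrix(rnorm(n_genes * m), n_genes, m,
              dimnames = list(sprintf("G%03d", 1:n_genes), sprintf("S%03d", 1:m)))
  labels <- factor(rep(c("primary", "bone"), c(n_neg, n_pos)),
                   levels = c("primary", "bone"))
  if (n_sep > 0) X[1:n_sep, labels == "bone"] <- X[1:n_sep, labels == "bone"] + shift
  labeled_dataset(X, labels)
}

expr_fixture <- function(n_genes = 5L, n_samples = 4L, seed = 1L) {
  set.seed(seed)
  matrix(round(rnorm(n_genes * n_samples), 4), n_genes, n_samples,
         dimnames = list(sprintf("G%02d", 1:n_genes), sprintf("S%02d", 1:n_samples)))
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
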