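#' Rank genes by DeepLIFT importance to the autoencoder bottleneck
#'
#' A gene's importance is the mean, over samples and over bottleneck neurons,
#' of the absolute DeepLIFT contribution of that gene to the neuron's
#' activation. Genes are returned in descending importance order; ties are
#' broken by gene id so the ranking is deterministic.
#'
#' @param ae A trained autoencoder (`dense_network`).
#' @param data Genes x samples matrix on the scale the autoencoder was trained
#'   on; gene order must match the network input.
#' @param reference [make_reference()] object (defaults to the per-gene mean
#'   of `data`).
#' @param bottleneck_layer Index of the bottleneck layer; defaults to the
#'   middle hidden layer.
#' @return A `gene_ranking` data frame with columns `gene`, `importance`,
#'   sorted descending.
#' @export
rank_genes <- function(ae, data, reference = NULL, bottleneck_layer = NULL) {
  validate_network(ae)
  assert_expression_matrix(data)
  if (nrow(data) != net_fan_in(ae))
    stop("gene count does not match the autoencoder input width", call. = FALSE)
  reference <- reference %||% make_reference(data, "train_mean")
  if (inherits(reference, "deeplift_reference") &&
      !identical(names(reference$values), rownames(data)))
    stop("reference genes do not match the data genes", call. = FALSE)
  L <- length(ae$layers)
  hidden <- seq_len(L - 1L)
  bottleneck_layer <- bottleneck_layer %||% hidden[ceiling(length(hidden) / 2)]
  if (!bottleneck_layer %in% hidden)
    stop("bottleneck_layer must be a hidden layer index", call. = FALSE)
  inputs <- t(data)
  state <- dl_state(ae, inputs, reference)
  n_units <- ncol(ae$layers[[bottleneck_layer]]$W)
  total <- matrix(0, nrow(inputs), ncol(inputs))
  v <- matrix(0, nrow(inputs), n_units)
  for (t in seq_len(n_units)) {
    v[, t] <- 1
    v_post <- dl_backward(ae, state, bottleneck_layer, v, from_logit = FALSE)
    total <- total + abs(state$d_x * v_post[[1L]])
    v[, t] <- 0
  }
  importance <- colMeans(total) / n_units
  ord <- order(-importance, rownames(data))
  structure(data.frame(gene = rownames(data)[ord],
                       importance = unname(importance[ord]),
                       stringsAsFactors = FALSE),
            class = c("gene_ranking", "data.frame"))
}

#' Grow a gene panel ten genes at a time and track cross-validated AUC
#'
#' For `k = step, 2*step, ..., max_k` the expression matrix is restricted to
#' the top-`k` ranked genes and a binary relu network (hidden layers 64-32-8,
#' sigmoid output) is evaluated by stratified k-fold cross-validation.
#' Standardization is fitted on each training fold and SMOTE is applied inside
#' training folds only, so evaluation folds stay untouched. `best_k` is the
#' smallest `k` attaining the maximum mean AUC.
#'
#' @param ranking A [rank_genes()] result.
#' @param data Two-class [labeled_dataset()] (primary vs one metastasis site).
#' @param step Panel increment (10 by convention).
#' @param max_k Largest panel size tried; default `min(200, n_genes)`.
#' @param folds Number of cross-validation folds.
#' @param config [train_config()] for the fold classifiers (loss is forced to
#'   binary cross-entropy).
#' @param hidden Hidden layer sizes of the binary classifier.
#' @param smote Apply SMOTE inside training folds.
#' @param k_neighbors SMOTE neighbour count.
#' @param positive Label treated as the positive class for AUC (defaults to
#'   the non-primary class).
#' @param seed Integer seed for fold assignment and per-fold training.
#' @return A `search_curve`: list with `curve` (data frame `k`, `mean_auc`,
#'   `sd_auc`), `best_k`, `best_auc`.
#' @export
iterative_search <- function(ranking, data, step = 10L, max_k = NULL,
                             folds = 5L, config = train_config("binary_cross_entropy"),
                             hidden = c(64L, 32L, 8L), smote = TRUE,
                             k_neighbors = 5L, positive = NULL, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (nlevels(data$labels) != 2 || any(table(data$labels) == 0))
    stop("iterative_search expects exactly two classes", call. = FALSE)
  genes <- ranking$gene
  max_k <- max_k %||% min(200L, length(genes))
  if (max_k > length(genes)) stop("max_k exceeds the ranking length", call. = FALSE)
  if (is.null(positive)) {
    non_primary <- setdiff(levels(data$labels), "primary")
    positive <- if (length(non_primary)) non_primary[1] else levels(data$labels)[2]
  }
  ks <- seq(step, max_k, by = step)
  fold_of <- stratified_folds(data$labels, folds, stage_seed(seed, 0L))
  mean_auc <- sd_auc <- numeric(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    top <- genes[seq_len(k)]
    aucs <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      if (length(unique(data$labels[!tr])) < 2 ||
          length(unique(data$labels[tr])) < 2)
        stop("a class is absent from fold ", f, call. = FALSE)
      fit <- standardize(data$matrix[top, tr, drop = FALSE])
      train_set <- labeled_dataset(fit$matrix, data$labels[tr])
      if (smote) train_set <- smote_oversample(train_set, k_neighbors,
                                               stage_seed(seed, k * 100L + f))
      cfg <- config
      cfg$loss <- "binary_cross_entropy"
      cfg$seed <- stage_seed(seed, k * 100L + f + 50000L)
      net <- init_network(c(k, hidden, 1L),
                          c(rep("relu", length(hidden)), "sigmoid"),
                          seed = cfg$seed)
      fitted <- train(net, t(train_set$matrix),
                      matrix(as.numeric(train_set$labels == positive)), cfg)
      val <- standardize(data$matrix[top, !tr, drop = FALSE], fit$stats)
      scores <- forward(fitted$network, t(val$matrix))[, 1]
      aucs[f] <- roc_auc(scores, data$labels[!tr], positive = positive)
    }
    mean_auc[i] <- mean(aucs)
    sd_auc[i] <- stats::sd(aucs)
  }
  best <- which.max(mean_auc)  # first maximum = smallest k on ties
  structure(list(curve = data.frame(k = ks, mean_auc = mean_auc, sd_auc = sd_auc),
                 best_k = ks[best], best_auc = mean_auc[best]),
            class = "search_curve")
}

#' @export
print.search_curve <- function(x, ...) {
  cat(sprintf("search_curve: best_k = %d (mean AUC %.3f)\n", x$best_k, x$best_auc))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Select the gene panel at the best panel size
#'
#' @param curve A [iterative_search()] result.
#' @param ranking The [rank_genes()] ranking the curve was built from.
#' @return Character vector: the top `best_k` genes (a prefix of the ranking).
#' @export
select_site_genes <- function(curve, ranking) {
  stopifnot(inherits(curve, "search_curve"))
  ranking$gene[seq_len(curve$best_k)]
}

#' Phase-1 gene selection for one metastasis site
#'
#' Restricts the cohort to primary plus one site, trains a site-specific
#' autoencoder on the expression values as given (normalized, but *not*
#' z-scored: per-gene scale is part of the signal DeepLIFT importance relies
#' on), ranks genes by contribution to the bottleneck, and runs the iterative
#' panel search with the binary classifier (which standardizes per training
#' fold). The autoencoder uses relu hidden layers and, by default, a linear
#' output layer so that values below the reconstruction range's floor are
#' representable.
#'
#' @param data [labeled_dataset()] containing at least `primary` and `site`.
#' @param site Metastasis-site label to contrast against `primary`.
#' @param ae_hidden Autoencoder hidden layer sizes (encoder-bottleneck-decoder).
#' @param ae_config [train_config()] for the autoencoder (loss forced to MAE).
#' @param ae_output Output activation of the autoencoder.
#' @param reference_mode Reference for the attribution (`"train_mean"` or
#'   `"zeros"`); on z-scored data both coincide up to sampling noise.
#' @param seed Integer seed; per-stage seeds are derived from it.
#' @inheritParams iterative_search
#' @param search_config [train_config()] for the panel-search classifiers.
#' @return List with `site`, `ranking`, `curve`, `genes` (selected panel),
#'   `ae`, `ae_history`.
#' @export
site_gene_selection <- function(data, site, ae_hidden = c(500L, 100L, 500L),
                                ae_config = train_config("mae", epochs = 500L),
                                ae_output = "linear",
                                reference_mode = "train_mean",
                                step = 10L, max_k = NULL, folds = 5L,
                                search_config = train_config("binary_cross_entropy"),
                                hidden = c(64L, 32L, 8L), smote = TRUE,
                                k_neighbors = 5L, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!site %in% levels(data$labels) || !"primary" %in% levels(data$labels))
    stop("data must contain both 'primary' and '", site, "' samples", call. = FALSE)
  keep <- data$labels %in% c("primary", site)
  subset <- labeled_dataset(data$matrix[, keep, drop = FALSE],
                            factor(as.character(data$labels[keep]),
                                   levels = c("primary", site)))
  n_genes <- nrow(subset$matrix)
  ae_cfg <- ae_config
  ae_cfg$loss <- "mae"
  ae_cfg$seed <- stage_seed(seed, 1L)
  ae <- init_network(c(n_genes, ae_hidden, n_genes),
                     c(rep("relu", length(ae_hidden)), ae_output),
                     seed = ae_cfg$seed)
  trained <- train(ae, t(subset$matrix), t(subset$matrix), ae_cfg)
  reference <- make_reference(subset$matrix, reference_mode)
  ranking <- rank_genes(trained$network, subset$matrix, reference)
  curve <- iterative_search(ranking, subset, step = step, max_k = max_k,
                            folds = folds, config = search_config,
                            hidden = hidden, smote = smote,
                            k_neighbors = k_neighbors, positive = site,
                            seed = stage_seed(seed, 2L))
  list(site = site, ranking = ranking, curve = curve,
       genes = select_site_genes(curve, ranking),
       ae = trained$network, ae_history = trained$history)
}
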