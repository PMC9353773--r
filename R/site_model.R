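#' Merge per-site gene lists into one deduplicated panel
#'
#' Order-preserving union: the first occurrence of a gene wins, and every gene
#' remembers which site lists it came from.
#'
#' @param site_lists Named list of character vectors (one per site).
#' @return A `gene_panel`: list with `genes` (deduplicated, ordered) and
#'   `provenance` (per gene, the contributing site names).
#' @export
assemble_panel <- function(site_lists) {
  if (!length(site_lists) || any(!lengths(site_lists)))
    stop("every site list must be non-empty", call. = FALSE)
  if (is.null(names(site_lists)))
    names(site_lists) <- paste0("list", seq_along(site_lists))
  genes <- unique(unlist(site_lists, use.names = FALSE))
  provenance <- lapply(stats::setNames(genes, genes), function(g)
    names(site_lists)[vapply(site_lists, function(s) g %in% s, TRUE)])
  structure(list(genes = genes, provenance = provenance), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel: %d genes from %d lists (%d entries before deduplication)\n",
              length(x$genes), length(unique(unlist(x$provenance))),
              sum(lengths(x$provenance))))
  invisible(x)
}

panel_genes <- function(panel) {
  if (inherits(panel, "gene_panel")) panel$genes else as.character(panel)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic normalized by
#' `n_pos * n_neg`; tied scores count 1/2. Invariant under strictly monotone
#' transformations of the scores.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels: logical, or a two-level factor/character.
#' @param positive The label counted as positive (default: second factor
#'   level, or `TRUE` for logical labels).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (is.logical(labels)) {
    pos <- labels
  } else {
    labels <- as.factor(labels)
    lv <- levels(droplevels(labels))
    if (length(lv) != 2) stop("roc_auc needs exactly two classes present", call. = FALSE)
    positive <- positive %||% lv[2]
    pos <- labels == positive
  }
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

prepare_site_inputs <- function(model, matrix) {
  if (!is.matrix(matrix)) stop("expected a genes x samples matrix", call. = FALSE)
  missing <- setdiff(model$panel_genes, rownames(matrix))
  if (length(missing))
    stop("matrix is missing panel genes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  std <- standardize(matrix[model$panel_genes, , drop = FALSE], model$stats)
  t(std$matrix)
}

#' Train the multi-class metastasis-site classifier
#'
#' Restricts the matrix to the panel, fits per-gene standardization, balances
#' the training classes with SMOTE (each minority class oversampled within
#' itself up to the majority count), and trains a relu network with three
#' hidden layers of 100 neurons and a softmax output over the classes, using
#' categorical cross-entropy. The fitted standardization and the panel travel
#' with the model so prediction on new data replays identical preprocessing.
#'
#' @param data [labeled_dataset()]; every level of its label factor must be
#'   present.
#' @param panel A `gene_panel` or character vector of gene ids.
#' @param hidden Hidden layer sizes.
#' @param config [train_config()] (loss forced to categorical cross-entropy).
#' @param smote Balance classes with SMOTE before training.
#' @param k_neighbors SMOTE neighbour count.
#' @return A `site_model`: list with `network`, `classes`, `panel_genes`,
#'   `stats`, `history`, `training`.
#' @export
train_site_model <- function(data, panel, hidden = c(100L, 100L, 100L),
                             config = train_config("categorical_cross_entropy",
                                                   epochs = 100L),
                             smote = TRUE, k_neighbors = 5L) {
  stopifnot(inherits(data, "labeled_dataset"))
  classes <- levels(data$labels)
  absent <- classes[!classes %in% data$labels]
  if (length(absent))
    stop("classes absent from the data: ", paste(absent, collapse = ", "),
         call. = FALSE)
  genes <- panel_genes(panel)
  missing <- setdiff(genes, rownames(data$matrix))
  if (length(missing))
    stop("panel genes missing from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  fit <- standardize(data$matrix[genes, , drop = FALSE])
  work <- labeled_dataset(fit$matrix, data$labels)
  if (smote && length(unique(table(work$labels))) > 1)
    work <- smote_multiclass(work, k_neighbors, stage_seed(config$seed, 7L))
  Y <- stats::model.matrix(~ 0 + work$labels)
  colnames(Y) <- classes
  cfg <- config
  cfg$loss <- "categorical_cross_entropy"
  net <- init_network(c(length(genes), hidden, length(classes)),
                      c(rep("relu", length(hidden)), "softmax"),
                      seed = cfg$seed)
  fitted <- train(net, t(work$matrix), Y, cfg)
  structure(list(network = fitted$network, classes = classes,
                 panel_genes = genes, stats = fit$stats,
                 history = fitted$history,
                 training = list(hidden = hidden, epochs = cfg$epochs,
                                 dropout_rate = cfg$dropout_rate,
                                 l2_lambda = cfg$l2_lambda, seed = cfg$seed,
                                 smote = smote)),
            class = "site_model")
}

#' @export
print.site_model <- function(x, ...) {
  cat(sprintf("site_model: %d-gene panel -> classes [%s]\n",
              length(x$panel_genes), paste(x$classes, collapse = ", ")))
  print(x$network)
  invisible(x)
}

#' Predict metastasis-site probabilities for new samples
#'
#' Applies the stored standardization, restricts to the stored panel (extra
#' genes are ignored; missing panel genes are an error) and runs a forward
#' pass. Probability rows sum to one.
#'
#' @param model A `site_model` (fitted or loaded with [load_model()]).
#' @param matrix Genes x samples expression matrix.
#' @return A `site_prediction`: list with `probabilities` (samples x classes)
#'   and `class` (argmax factor).
#' @export
predict_sites <- function(model, matrix) {
  stopifnot(inherits(model, "site_model"))
  inputs <- prepare_site_inputs(model, matrix)
  probs <- forward(model$network, inputs)
  dimnames(probs) <- list(colnames(matrix), model$classes)
  structure(list(probabilities = probs,
                 class = factor(model$classes[max.col(probs, ties.method = "first")],
                                levels = model$classes)),
            class = "site_prediction")
}

#' Evaluate a site model on labelled data
#'
#' One-vs-rest AUC per class from the probability columns; accuracy,
#' sensitivity, specificity, precision and F1 per class from the argmax
#' predictions; plus the confusion matrix. Metrics that are undefined for a
#' class absent from the labels are reported as `NA`, never fabricated.
#'
#' @param model A `site_model`.
#' @param data [labeled_dataset()] with the same class vocabulary.
#' @return An `eval_report`: list with `auc` (per class), `macro_auc`,
#'   `accuracy`, `metrics` (per-class data frame) and `confusion`.
#' @export
evaluate_sites <- function(model, data) {
  stopifnot(inherits(data, "labeled_dataset"))
  pred <- predict_sites(model, data$matrix)
  truth <- factor(as.character(data$labels), levels = model$classes)
  if (anyNA(truth)) stop("labels contain classes unknown to the model", call. = FALSE)
  classes <- model$classes
  auc <- stats::setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    is_cl <- truth == cl
    if (any(is_cl) && !all(is_cl))
      auc[cl] <- roc_auc(pred$probabilities[, cl], is_cl)
  }
  confusion <- table(truth = truth, predicted = pred$class)
  n <- length(truth)
  metrics <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred$class == cl)
    fn <- sum(truth == cl & pred$class != cl)
    fp <- sum(truth != cl & pred$class == cl)
    tn <- n - tp - fn - fp
    if (tp + fn == 0) {  # class absent: leave its metrics undefined
      return(data.frame(class = cl, accuracy = NA_real_, sensitivity = NA_real_,
                        specificity = NA_real_, precision = NA_real_,
                        f1 = NA_real_))
    }
    sens <- tp / (tp + fn)
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(prec) && (prec + sens) > 0) 2 * prec * sens / (prec + sens)
    else NA_real_
    data.frame(class = cl, accuracy = (tp + tn) / n, sensitivity = sens,
               specificity = spec, precision = prec, f1 = f1)
  }))
  structure(list(auc = auc, macro_auc = mean(auc, na.rm = TRUE),
                 accuracy = mean(pred$class == truth), metrics = metrics,
                 confusion = confusion),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: accuracy %.3f, macro one-vs-rest AUC %.3f\n",
              x$accuracy, x$macro_auc))
  print(round(x$auc, 3))
  print(x$confusion)
  invisible(x)
}
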