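one_sample_p <- function(x, mu0) {
  if (length(x) < 3) stop("need at least 3 samples per score vector", call. = FALSE)
  if (stats::sd(x) == 0) {
    # degenerate: constant scores -- either indistinguishable from the mean
    # (p = 1) or deterministically different from it (p = 0)
    return(if (isTRUE(all.equal(mean(x), mu0))) 1 else 0)
  }
  stats::t.test(x, mu = mu0)$p.value
}

#' Select a class's essential neurons in each layer
#'
#' Each neuron's per-sample relevance scores are compared with the layer-wide
#' mean relevance by a two-sided one-sample t-test; a neuron is essential when
#' its p-value is below `alpha` and its mean relevance lies above the layer
#' mean (so "essential" means significantly above-average relevance).
#' Benjamini-Hochberg adjusted p-values are always reported; selection uses
#' the raw p-values by default.
#'
#' @param profile A [neuron_relevance()] result.
#' @param alpha Significance threshold (0.05 by convention).
#' @param adjust `"none"` (default) selects on raw p, `"BH"` on the adjusted p.
#' @param layers Which profile layers to analyse (default: all hidden layers).
#' @return Data frame with columns `layer`, `neuron`, `mean_relevance`,
#'   `p_value`, `p_adjusted`, `essential`.
#' @export
essential_neurons <- function(profile, alpha = 0.05, adjust = c("none", "BH"),
                              layers = NULL) {
  stopifnot(inherits(profile, "relevance_profile"))
  adjust <- match.arg(adjust)
  layers <- layers %||% grep("^hidden_", names(profile$layers), value = TRUE)
  out <- lapply(layers, function(ln) {
    scores <- profile$layers[[ln]]
    if (nrow(scores) < 3)
      stop("need at least 3 samples for the t-test", call. = FALSE)
    mu0 <- mean(scores)
    p <- apply(scores, 2L, one_sample_p, mu0 = mu0)
    means <- colMeans(scores)
    p_adj <- stats::p.adjust(p, method = "BH")
    used <- if (adjust == "BH") p_adj else p
    data.frame(layer = ln, neuron = seq_len(ncol(scores)),
               mean_relevance = means, p_value = p, p_adjusted = p_adj,
               essential = used < alpha & means > mu0,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Essential input genes of one neuron
#'
#' The neuron's activation is back-attributed to the inputs with DeepLIFT;
#' each gene's per-sample contributions are then tested against the mean
#' contribution over all genes with the same two-sided t-test / upper-tail
#' rule used for neurons.
#'
#' @param network A `dense_network`, or a fitted `site_model` (then `inputs`
#'   is a raw genes x samples matrix and the stored preprocessing is applied).
#' @param inputs Samples x fan_in matrix (dense network) or genes x samples
#'   matrix (site model).
#' @param reference [make_reference()] object or numeric vector (for a
#'   `site_model`, defaults to the training mean, i.e. zeros after
#'   standardization).
#' @param layer,neuron Target neuron coordinates.
#' @param alpha Significance threshold.
#' @param adjust `"none"` or `"BH"` selection, as in [essential_neurons()].
#' @return Data frame with columns `gene`, `mean_contribution`, `p_value`,
#'   `p_adjusted`, `essential`.
#' @export
essential_genes <- function(network, inputs, reference = NULL, layer, neuron,
                            alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  gene_ids <- NULL
  if (inherits(network, "site_model")) {
    inputs <- prepare_site_inputs(network, inputs)
    reference <- reference %||% numeric(length(network$panel_genes))
    gene_ids <- network$panel_genes
    network <- network$network
  }
  att <- deeplift_attribute(network, inputs, reference, layer = layer,
                            neuron = neuron)
  C <- att$contributions
  if (nrow(C) < 3) stop("need at least 3 samples for the t-test", call. = FALSE)
  gene_ids <- gene_ids %||% colnames(C) %||% paste0("input_", seq_len(ncol(C)))
  mu0 <- mean(C)
  p <- apply(C, 2L, one_sample_p, mu0 = mu0)
  means <- colMeans(C)
  p_adj <- stats::p.adjust(p, method = "BH")
  used <- if (adjust == "BH") p_adj else p
  data.frame(gene = gene_ids, mean_contribution = unname(means),
             p_value = unname(p), p_adjusted = unname(p_adj),
             essential = unname(used < alpha & means > mu0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Over-representation analysis with Fisher's exact (hypergeometric) test
#'
#' For every gene set, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the gene list and the set, given the
#' background universe. Sets are intersected with the background first.
#' Benjamini-Hochberg adjustment is applied across sets.
#'
#' @param gene_list Character vector of genes (must be a subset of
#'   `background`).
#' @param gene_sets A `gene_set_collection` from [read_gmt()] or a named list
#'   of gene id vectors.
#' @param background Character vector: the gene universe.
#' @return Data frame sorted by p-value with columns `set`, `overlap`,
#'   `set_size`, `list_size`, `background_size`, `p_value`, `p_adjusted`.
#' @export
ora_fisher <- function(gene_list, gene_sets, background) {
  background <- unique(background)
  if (!length(background)) stop("background gene universe is empty", call. = FALSE)
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, background)
  if (length(outside))
    stop("gene list contains genes outside the background: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  sets <- if (inherits(gene_sets, "gene_set_collection")) gene_sets$sets else gene_sets
  if (!length(sets)) stop("no gene sets supplied", call. = FALSE)
  N <- length(background)
  n <- length(gene_list)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), background)
    K <- length(s)
    k <- length(intersect(gene_list, s))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, list_size = n,
               background_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$set), , drop = FALSE]
}

#' Full neuron-level interpretation of a fitted site model
#'
#' For every class: propagate class-conditional relevance, select essential
#' neurons per hidden layer, back-attribute each essential neuron to its
#' essential input genes, and (when gene sets are given) run
#' over-representation analysis of each neuron's gene list against the panel
#' background.
#'
#' @param model A fitted `site_model`.
#' @param data [labeled_dataset()] whose samples drive the relevance scores;
#'   by default only samples predicted as the class under study are used,
#'   falling back to all samples when a class is never predicted.
#' @param gene_sets Optional `gene_set_collection` for enrichment.
#' @param alpha Significance threshold for neurons and genes.
#' @param max_neurons_per_layer Cap on back-attributed neurons per layer
#'   (strongest mean relevance first), to bound runtime.
#' @return An `essential_report`: per class, the neuron table, per-neuron gene
#'   lists and enrichment tables.
#' @export
interpret_model <- function(model, data, gene_sets = NULL, alpha = 0.05,
                            max_neurons_per_layer = Inf) {
  stopifnot(inherits(model, "site_model"), inherits(data, "labeled_dataset"))
  pred <- predict_sites(model, data$matrix)
  report <- list()
  for (ci in seq_along(model$classes)) {
    cl <- model$classes[ci]
    use <- which(pred$class == cl)
    if (length(use) < 3) use <- seq_along(pred$class)
    mat <- data$matrix[, use, drop = FALSE]
    profile <- neuron_relevance(model, mat, class = cl)
    neurons <- essential_neurons(profile, alpha = alpha)
    sel <- neurons[neurons$essential, , drop = FALSE]
    genes <- list()
    enrichment <- list()
    for (ln in unique(sel$layer)) {
      layer_idx <- match(ln, names(profile$layers))
      rows <- sel[sel$layer == ln, , drop = FALSE]
      rows <- rows[order(-rows$mean_relevance), , drop = FALSE]
      if (is.finite(max_neurons_per_layer))
        rows <- utils::head(rows, max_neurons_per_layer)
      for (i in seq_len(nrow(rows))) {
        key <- sprintf("%s_neuron%d", ln, rows$neuron[i])
        gt <- essential_genes(model, mat, layer = layer_idx,
                              neuron = rows$neuron[i], alpha = alpha)
        genes[[key]] <- gt$gene[gt$essential]
        if (!is.null(gene_sets) && length(genes[[key]]))
          enrichment[[key]] <- ora_fisher(genes[[key]], gene_sets,
                                          background = model$panel_genes)
      }
    }
    report[[cl]] <- list(class = cl, n_samples = length(use),
                         neurons = neurons, genes = genes,
                         enrichment = enrichment)
  }
  structure(report, class = "essential_report")
}
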