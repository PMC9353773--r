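#' Quantile-normalize an expression matrix across samples
#'
#' Forces every sample (column) onto the common distribution of per-rank
#' means: column values are sorted, the mean across samples is taken at every
#' rank, and each value is replaced by the mean at its rank. Ties within a
#' column receive the mean of the rank-means they span. Idempotent on
#' tie-free data.
#'
#' @param matrix Genes x samples numeric matrix (at least two samples).
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(matrix) {
  assert_expression_matrix(matrix)
  if (ncol(matrix) < 2)
    stop("quantile normalization needs at least two samples", call. = FALSE)
  mu <- rowMeans(apply(matrix, 2L, sort))
  out <- matrix
  for (j in seq_len(ncol(matrix))) {
    x <- matrix[, j]
    v <- mu[rank(x, ties.method = "first")]
    # tied input values share the mean of the rank-means their ranks span
    out[, j] <- stats::ave(v, match(x, x), FUN = mean)
  }
  out
}

#' Collapse probe-level rows to one row per gene
#'
#' For genes measured by several probes, the probe with the highest mean value
#' across samples is retained (ties broken by the lexicographically smallest
#' probe id). Probes absent from the mapping are dropped. Gene order follows
#' the first appearance of each gene in probe (row) order.
#'
#' @param probes Probes x samples numeric matrix (probe ids as row names).
#' @param probe_map Data frame with columns `probe_id`, `gene_id` (e.g. from
#'   [read_probe_map()]).
#' @return Genes x samples matrix.
#' @export
collapse_probes <- function(probes, probe_map) {
  assert_expression_matrix(probes, "probe matrix")
  if (is.null(probe_map) || nrow(probe_map) == 0)
    stop("probe map is empty", call. = FALSE)
  gene_of <- stats::setNames(as.character(probe_map$gene_id),
                             as.character(probe_map$probe_id))
  keep <- rownames(probes) %in% names(gene_of)
  if (!any(keep)) stop("no probe in the matrix is covered by the map", call. = FALSE)
  probes <- probes[keep, , drop = FALSE]
  genes_in_order <- unique(unname(gene_of[rownames(probes)]))
  means <- rowMeans(probes)
  pick <- vapply(genes_in_order, function(g) {
    cand <- rownames(probes)[gene_of[rownames(probes)] == g]
    cand <- cand[order(-means[cand], cand)]
    cand[1]
  }, "")
  out <- probes[pick, , drop = FALSE]
  rownames(out) <- genes_in_order
  out
}

#' SMOTE oversampling of the minority class
#'
#' Balances a two-class dataset by synthesising minority samples: a random
#' minority sample `x_i` is moved a uniform fraction of the way toward one of
#' its `k_neighbors` nearest minority neighbours (Euclidean distance),
#' `x_new = x_i + u * (x_nn - x_i)`, `u ~ U(0, 1)`. Original samples are kept
#' unchanged; synthetic samples get ids `<class>_synth<i>` and are flagged in
#' the dataset's `synthetic` field.
#'
#' @param data A two-class [labeled_dataset()].
#' @param k_neighbors Number of nearest minority neighbours to interpolate
#'   toward (must be smaller than the minority class size).
#' @param seed Integer seed.
#' @return A balanced `labeled_dataset`.
#' @export
smote_oversample <- function(data, k_neighbors = 5L, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"))
  counts <- table(data$labels)
  if (length(counts) != 2)
    stop("SMOTE here expects exactly two classes, got ",
         length(counts), call. = FALSE)
  if (counts[1] == counts[2]) return(data)
  minority <- names(counts)[which.min(counts)]
  n_min <- min(counts)
  if (n_min <= k_neighbors)
    stop("minority class has ", n_min, " samples; k_neighbors (", k_neighbors,
         ") must be smaller -- use a smaller k", call. = FALSE)
  n_new <- max(counts) - n_min
  X <- t(data$matrix[, data$labels == minority, drop = FALSE])  # samples x genes
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n_min),
                              function(i) order(D[i, ])[seq_len(k_neighbors)]))
  synth <- with_seed(seed, {
    base <- sample.int(n_min, n_new, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    X[base, , drop = FALSE] + u * (X[pick, , drop = FALSE] - X[base, , drop = FALSE])
  })
  rownames(synth) <- sprintf("%s_synth%d", minority, seq_len(n_new))
  new_matrix <- cbind(data$matrix, t(synth))
  new_labels <- factor(c(as.character(data$labels), rep(minority, n_new)),
                       levels = levels(data$labels))
  structure(list(matrix = new_matrix, labels = new_labels,
                 synthetic = c(data$synthetic, rep(TRUE, n_new))),
            class = "labeled_dataset")
}

# Balance every class of a multi-class dataset up to the majority count by
# applying the same interpolation within each minority class.
smote_multiclass <- function(data, k_neighbors = 5L, seed = 1L) {
  counts <- table(data$labels)
  majority <- names(counts)[which.max(counts)]
  out <- data
  for (i in seq_along(counts)) {
    cl <- names(counts)[i]
    n_new <- max(counts) - counts[i]
    if (cl == majority || n_new == 0) next
    pair_idx <- which(data$labels %in% c(cl, majority))
    pair <- structure(list(matrix = data$matrix[, pair_idx, drop = FALSE],
                           labels = factor(as.character(data$labels[pair_idx]),
                                           levels = c(majority, cl)),
                           synthetic = data$synthetic[pair_idx]),
                      class = "labeled_dataset")
    balanced <- smote_oversample(pair, k_neighbors, stage_seed(seed, i))
    new_cols <- balanced$matrix[, ncol(balanced$matrix) - n_new + seq_len(n_new),
                                drop = FALSE]
    out <- structure(list(
      matrix = cbind(out$matrix, new_cols),
      labels = factor(c(as.character(out$labels), rep(cl, n_new)),
                      levels = levels(out$labels)),
      synthetic = c(out$synthetic, rep(TRUE, n_new))),
      class = "labeled_dataset")
  }
  out
}

#' Per-gene standardization (z-scores)
#'
#' Without `stats`, fits per-gene mean and standard deviation and applies
#' them; with `stats` (e.g. from the training data), applies the provided
#' parameters to new data. Zero-variance genes get their sd replaced by 1 (so
#' the standardized row is all zeros) and are reported via a message.
#'
#' @param matrix Genes x samples numeric matrix.
#' @param stats Optional list with named numeric vectors `mean` and `sd`.
#' @return List with `matrix` (standardized) and `stats` (the parameters
#'   applied).
#' @export
standardize <- function(matrix, stats = NULL) {
  assert_expression_matrix(matrix)
  if (is.null(stats)) {
    mu <- rowMeans(matrix)
    sd <- apply(matrix, 1L, stats::sd)
    flat <- !is.finite(sd) | sd == 0
    if (any(flat)) {
      message("standardize: ", sum(flat),
              " zero-variance gene(s) kept with sd = 1: ",
              paste(utils::head(rownames(matrix)[flat], 5), collapse = ", "),
              if (sum(flat) > 5) ", ..." else "")
      sd[flat] <- 1
    }
    stats <- list(mean = mu, sd = sd)
  } else {
    if (!setequal(names(stats$mean), rownames(matrix)))
      stop("standardization stats do not cover the same genes as the matrix",
           call. = FALSE)
    stats <- list(mean = stats$mean[rownames(matrix)],
                  sd = stats$sd[rownames(matrix)])
  }
  list(matrix = (matrix - stats$mean) / stats$sd, stats = stats)
}
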