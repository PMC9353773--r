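#' Configuration for the synthetic multi-site cohort generator
#'
#' Defaults emulate the structure of the microarray cohorts the method is
#' aimed at: log-scale intensities with Gaussian noise, a large primary group
#' and smaller metastasised groups (class imbalance), a small disjoint set of
#' planted signature genes per site, and many uninformative genes. The default
#' fixture is 1000 genes, 20 planted genes per site at an effect of 2 noise
#' standard deviations, 200 primary and 60 samples per site.
#'
#' @param n_genes Total number of genes.
#' @param class_counts Named integer vector of per-class sample counts; the
#'   names define the class vocabulary (one of them should be `"primary"`).
#' @param planted_per_site Planted signature genes per non-primary class.
#' @param effect_size Mean shift of planted genes in that class, in units of
#'   the noise standard deviation.
#' @param rho Within-block equicorrelation of baseline expression, in `[0, 1)`.
#' @param block_size Genes per correlation block (only used when `rho > 0`).
#' @param noise_sd Baseline noise standard deviation.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000L,
                       class_counts = c(primary = 200L, bone = 60L, brain = 60L,
                                        lung = 60L, liver = 60L),
                       planted_per_site = 20L, effect_size = 2,
                       rho = 0, block_size = 10L, noise_sd = 1, seed = 1L) {
  stopifnot(n_genes >= 1, all(class_counts >= 1), planted_per_site >= 0,
            effect_size >= 0, rho >= 0, rho < 1, block_size >= 1, noise_sd > 0)
  if (is.null(names(class_counts)) || any(!nzchar(names(class_counts))))
    stop("class_counts must be named by class", call. = FALSE)
  sites <- setdiff(names(class_counts), "primary")
  if (planted_per_site * length(sites) > n_genes)
    stop("planted genes (", planted_per_site * length(sites),
         ") exceed n_genes (", n_genes, ")", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), class_counts = class_counts,
                 planted_per_site = as.integer(planted_per_site),
                 effect_size = effect_size, rho = rho,
                 block_size = as.integer(block_size), noise_sd = noise_sd,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a multi-site expression cohort with known ground truth
#'
#' Baseline expression is Gaussian per gene (optionally equicorrelated within
#' gene blocks); each non-primary class has a disjoint planted gene set whose
#' values are shifted by `effect_size * noise_sd` in that class's samples.
#' Deterministic for a given seed.
#'
#' @param config A [sim_config()].
#' @return List with `data` (a [labeled_dataset()]) and `truth` (list with
#'   `planted` per site and the true `labels`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_genes <- config$n_genes
    counts <- config$class_counts
    classes <- names(counts)
    m <- sum(counts)
    gene_ids <- sprintf("G%05d", seq_len(n_genes))
    sample_ids <- sprintf("S%05d", seq_len(m))
    labels <- factor(rep(classes, counts),
                     levels = if (all(classes %in% SITE_CLASSES))
                       intersect(SITE_CLASSES, classes) else classes)
    if (config$rho > 0) {
      block <- rep(seq_len(ceiling(n_genes / config$block_size)),
                   each = config$block_size)[seq_len(n_genes)]
      z <- matrix(stats::rnorm(max(block) * m), max(block), m)
      X <- sqrt(config$rho) * z[block, , drop = FALSE] +
        sqrt(1 - config$rho) * matrix(stats::rnorm(n_genes * m), n_genes, m)
      X <- X * config$noise_sd
    } else {
      X <- matrix(stats::rnorm(n_genes * m, sd = config$noise_sd), n_genes, m)
    }
    dimnames(X) <- list(gene_ids, sample_ids)
    sites <- setdiff(classes, "primary")
    pool <- sample(gene_ids)
    planted <- list()
    for (i in seq_along(sites)) {
      take <- pool[seq_len(config$planted_per_site) +
                     (i - 1L) * config$planted_per_site]
      planted[[sites[i]]] <- sort(take)
      X[take, labels == sites[i]] <-
        X[take, labels == sites[i]] + config$effect_size * config$noise_sd
    }
    names(labels) <- sample_ids
    list(data = labeled_dataset(X, labels),
         truth = list(planted = planted, labels = labels))
  })
}

#' Expand a gene-level matrix to probe level
#'
#' Each gene becomes one or more probes: probe value = gene value + a fixed
#' per-probe offset + independent noise. With one probe per gene and zero
#' offset/noise, [collapse_probes()] recovers the original matrix exactly.
#'
#' @param matrix Genes x samples matrix (or a [labeled_dataset()], whose
#'   matrix is used).
#' @param probes_per_gene Integer vector of possible probe counts per gene.
#' @param probs Sampling probabilities for `probes_per_gene` (default
#'   uniform).
#' @param offset_sd Standard deviation of the per-probe constant offset.
#' @param probe_noise_sd Standard deviation of per-cell probe noise.
#' @param seed Integer seed.
#' @return List with `values` (probes x samples matrix) and `map` (data frame
#'   `probe_id`, `gene_id`).
#' @export
simulate_probe_level <- function(matrix, probes_per_gene = 1:3, probs = NULL,
                                 offset_sd = 0.5, probe_noise_sd = 0.1,
                                 seed = 1L) {
  if (inherits(matrix, "labeled_dataset")) matrix <- matrix$matrix
  assert_expression_matrix(matrix)
  with_seed(seed, {
    n_per <- if (length(probes_per_gene) == 1L)
      rep(probes_per_gene, nrow(matrix))
    else sample(probes_per_gene, nrow(matrix), replace = TRUE, prob = probs)
    probe_gene <- rep(rownames(matrix), n_per)
    within <- unlist(lapply(n_per, seq_len))
    probe_ids <- sprintf("%s_p%d", probe_gene, within)
    offsets <- if (offset_sd > 0) stats::rnorm(length(probe_ids), sd = offset_sd)
    else numeric(length(probe_ids))
    values <- matrix[probe_gene, , drop = FALSE] + offsets
    if (probe_noise_sd > 0)
      values <- values + matrix(stats::rnorm(length(values), sd = probe_noise_sd),
                                nrow(values), ncol(values))
    rownames(values) <- probe_ids
    list(values = values,
         map = data.frame(probe_id = probe_ids, gene_id = probe_gene,
                          stringsAsFactors = FALSE))
  })
}
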