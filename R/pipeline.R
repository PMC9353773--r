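#' Assemble a pipeline configuration
#'
#' One object drives the full run: simulate (or load) a cohort, preprocess,
#' select genes per site, merge the panel, train and evaluate the multi-class
#' model, and optionally interpret it. A single global seed expands into
#' per-stage seeds via [stage_seed()].
#'
#' @param seed Global integer seed.
#' @param sim List of [sim_config()] arguments for a synthetic cohort, or
#'   `NULL` to read `matrix`/`labels` from disk.
#' @param matrix,labels,probe_map Input file paths (used when `sim` is NULL;
#'   `probe_map` triggers probe collapse and is optional either way).
#' @param quantile_normalization Quantile-normalize the matrix across samples.
#' @param smote_scope `"train"` (SMOTE inside training partitions only, the
#'   default), `"all"` (oversample the full dataset up front, replicating the
#'   original protocol), or `"off"`.
#' @param sites Site labels to run phase 1 on; default: every non-primary
#'   class present.
#' @param selection Phase-1 parameters: `step`, `max_k`, `folds`, `ae_hidden`,
#'   `ae_epochs`, `epochs` (search classifier), `k_neighbors`.
#' @param model Phase-2 parameters: `hidden`, `epochs`, `k_neighbors`.
#' @param evaluation `test_fraction` of each class held out for the final
#'   evaluation.
#' @param interpret `gmt` (path or `NULL`), `alpha`, `max_neurons_per_layer`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, sim = list(), matrix = NULL,
                            labels = NULL, probe_map = NULL,
                            quantile_normalization = TRUE,
                            smote_scope = c("train", "all", "off"),
                            sites = NULL,
                            selection = list(), model = list(),
                            evaluation = list(), interpret = list()) {
  smote_scope <- match.arg(smote_scope)
  sel <- utils::modifyList(list(step = 10L, max_k = 100L, folds = 5L,
                                ae_hidden = c(500L, 100L, 500L),
                                ae_epochs = 500L, epochs = 100L,
                                k_neighbors = 5L),
                           selection)
  mod <- utils::modifyList(list(hidden = c(100L, 100L, 100L), epochs = 100L,
                                k_neighbors = 5L), model)
  ev <- utils::modifyList(list(test_fraction = 0.25), evaluation)
  itp <- utils::modifyList(list(gmt = NULL, alpha = 0.05,
                                max_neurons_per_layer = 5L), interpret)
  structure(list(seed = seed, sim = sim, matrix = matrix, labels = labels,
                 probe_map = probe_map,
                 quantile_normalization = quantile_normalization,
                 smote_scope = smote_scope, sites = sites, selection = sel,
                 model = mod, evaluation = ev, interpret = itp),
            class = "pipeline_config")
}

read_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    x <- jsonlite::read_json(x, simplifyVector = TRUE)
  }
  stopifnot(is.list(x))
  do.call(pipeline_config, x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the end-to-end pipeline
#'
#' Executes simulate/load -> preprocess -> per-site gene selection -> panel ->
#' multi-class training -> evaluation -> interpretation, writing every
#' artifact under `out_dir` plus a `manifest.json` with the seeds, parameters
#' and md5 checksums of the outputs. Re-running with the same configuration
#' and seed reproduces every output byte for byte. With `resume = TRUE`,
#' stages whose outputs already exist are skipped and their artifacts reused.
#'
#' @param config A [pipeline_config()], a plain list of its arguments, or a
#'   path to a JSON file of them.
#' @param out_dir Output directory (created if needed).
#' @param resume Reuse existing stage outputs.
#' @return (Invisibly) a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, ...)
  seed <- config$seed
  log_stage <- function(stage, ...) message(sprintf("[%s] %s", stage, sprintf(...)))

  # -- stage 1: obtain and preprocess the cohort ---------------------------
  matrix_file <- path("matrix.tsv"); labels_file <- path("labels.tsv")
  if (resume && file.exists(matrix_file) && file.exists(labels_file)) {
    log_stage("input", "reusing %s", matrix_file)
    X <- read_expression(matrix_file)
    lab <- read_labels(labels_file)
    truth <- if (file.exists(path("truth.json")))
      jsonlite::read_json(path("truth.json"), simplifyVector = TRUE) else NULL
  } else if (length(config$sim) || is.null(config$matrix)) {
    sim <- do.call(sim_config, utils::modifyList(list(seed = stage_seed(seed, 1L)),
                                                 config$sim %||% list()))
    cohort <- simulate_cohort(sim)
    X <- cohort$data$matrix
    lab <- stats::setNames(as.character(cohort$data$labels), colnames(X))
    truth <- cohort$truth
    jsonlite::write_json(list(planted = truth$planted,
                              labels = as.list(stats::setNames(as.character(truth$labels),
                                                               names(truth$labels)))),
                         path("truth.json"), auto_unbox = TRUE)
    log_stage("simulate", "%d genes x %d samples", nrow(X), ncol(X))
  } else {
    for (f in c(config$matrix, config$labels))
      if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
    X <- read_expression(config$matrix)
    lab <- read_labels(config$labels)
    truth <- NULL
    if (!is.null(config$probe_map)) {
      pm <- read_probe_map(config$probe_map)
      X <- collapse_probes(X, pm)
      log_stage("preprocess", "collapsed probes to %d genes", nrow(X))
    }
  }
  if (config$quantile_normalization) X <- quantile_normalize(X)
  data <- labeled_dataset(X, lab)
  if (config$smote_scope == "all") {
    data <- smote_multiclass(data, seed = stage_seed(seed, 2L))
    log_stage("preprocess", "SMOTE applied to the full dataset (%d samples)",
              ncol(data$matrix))
  }
  smote_in_train <- config$smote_scope == "train"
  write_expression(data$matrix, matrix_file)
  write_labels(stats::setNames(as.character(data$labels), colnames(data$matrix)),
               labels_file)

  # -- stage 2: per-site gene selection ------------------------------------
  sites <- config$sites %||% setdiff(levels(data$labels), "primary")
  site_genes <- list()
  selections <- list()
  for (i in seq_along(sites)) {
    site <- sites[i]
    genes_file <- path(sprintf("genes_%s.txt", site))
    if (resume && file.exists(genes_file)) {
      site_genes[[site]] <- readLines(genes_file)
      log_stage("select-genes", "reusing %s", genes_file)
      next
    }
    sel_cfg <- config$selection
    res <- site_gene_selection(
      data, site,
      ae_hidden = sel_cfg$ae_hidden,
      ae_config = train_config("mae", epochs = sel_cfg$ae_epochs),
      step = sel_cfg$step, max_k = sel_cfg$max_k, folds = sel_cfg$folds,
      search_config = train_config("binary_cross_entropy",
                                   epochs = sel_cfg$epochs),
      smote = smote_in_train, k_neighbors = sel_cfg$k_neighbors,
      seed = stage_seed(seed, 10L + i))
    write_tsv(res$ranking, path(sprintf("ranking_%s.tsv", site)))
    write_tsv(res$curve$curve, path(sprintf("curve_%s.tsv", site)))
    writeLines(res$genes, genes_file)
    site_genes[[site]] <- res$genes
    selections[[site]] <- res
    log_stage("select-genes", "%s: best_k = %d (AUC %.3f)", site,
              res$curve$best_k, res$curve$best_auc)
  }

  # -- stage 3: panel + multi-class model ----------------------------------
  panel <- assemble_panel(site_genes)
  writeLines(panel$genes, path("panel.txt"))
  write_tsv(data.frame(gene = panel$genes,
                       sites = vapply(panel$provenance, paste, "", collapse = ",")),
            path("panel_provenance.tsv"))
  model_file <- path("model.json")
  split <- stratified_split(data$labels, config$evaluation$test_fraction,
                            seed = stage_seed(seed, 30L))
  if (resume && file.exists(model_file)) {
    model <- load_model(model_file)
    log_stage("train", "reusing %s", model_file)
  } else {
    train_data <- labeled_dataset(data$matrix[, split$train, drop = FALSE],
                                  data$labels[split$train])
    model <- train_site_model(train_data, panel, hidden = config$model$hidden,
                              config = train_config("categorical_cross_entropy",
                                                    epochs = config$model$epochs,
                                                    seed = stage_seed(seed, 31L)),
                              smote = smote_in_train,
                              k_neighbors = config$model$k_neighbors)
    save_model(model, model_file)
    log_stage("train", "panel of %d genes, classes [%s]",
              length(panel$genes), paste(model$classes, collapse = ", "))
  }

  # -- stage 4: predictions + evaluation -----------------------------------
  pred <- predict_sites(model, data$matrix)
  pred_df <- data.frame(sample_id = colnames(data$matrix),
                        pred$probabilities,
                        predicted = as.character(pred$class),
                        check.names = FALSE)
  write_tsv(pred_df, path("predictions.tsv"))
  test_data <- labeled_dataset(data$matrix[, split$test, drop = FALSE],
                               data$labels[split$test])
  report <- evaluate_sites(model, test_data)
  jsonlite::write_json(list(auc = as.list(report$auc),
                            macro_auc = report$macro_auc,
                            accuracy = report$accuracy,
                            n_test = ncol(test_data$matrix)),
                       path("evaluation.json"), auto_unbox = TRUE, digits = NA)
  write_tsv(report$metrics, path("metrics.tsv"))
  write_tsv(as.data.frame.matrix(report$confusion), path("confusion.tsv"))
  log_stage("evaluate", "held-out accuracy %.3f, macro AUC %.3f",
            report$accuracy, report$macro_auc)

  # -- stage 5: interpretation ---------------------------------------------
  interp <- NULL
  if (!is.null(config$interpret$gmt)) {
    gmt <- read_gmt(config$interpret$gmt)
    interp <- interpret_model(model, data, gmt, alpha = config$interpret$alpha,
                              max_neurons_per_layer = config$interpret$max_neurons_per_layer)
    dir.create(path("interpret"), showWarnings = FALSE)
    for (cl in names(interp)) {
      write_tsv(interp[[cl]]$neurons,
                path("interpret", sprintf("neurons_%s.tsv", cl)))
      for (key in names(interp[[cl]]$genes))
        writeLines(interp[[cl]]$genes[[key]],
                   path("interpret", sprintf("genes_%s_%s.txt", cl, key)))
      for (key in names(interp[[cl]]$enrichment))
        write_tsv(interp[[cl]]$enrichment[[key]],
                  path("interpret", sprintf("enrichment_%s_%s.tsv", cl, key)))
    }
    log_stage("interpret", "%d classes interpreted", length(interp))
  }

  # -- manifest -------------------------------------------------------------
  outputs <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.json"))
  manifest <- list(
    package = as.character(utils::packageVersion("metsite")),
    r_version = R.version.string,
    seed = seed,
    smote_scope = config$smote_scope,
    checksums = as.list(tools::md5sum(file.path(out_dir, outputs))))
  names(manifest$checksums) <- outputs
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE)
  invisible(list(data = data, panel = panel, model = model, report = report,
                 predictions = pred, selections = selections,
                 interpret = interp, manifest = manifest, out_dir = out_dir))
}
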