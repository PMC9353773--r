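#' Canonical class vocabulary
#'
#' Sample classes used throughout: a primary tumour or one metastasised to
#' bone, brain, lung or liver.
#'
#' @format Character vector of length 5.
#' @export
SITE_CLASSES <- c("primary", "bone", "brain", "lung", "liver")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive a per-stage seed from a base seed
#'
#' One global seed expands deterministically into per-stage seeds so that any
#' pipeline stage can be re-run in isolation with the stream it saw in the
#' full run. The derived seed always fits a 32-bit integer.
#'
#' @param seed Base integer seed.
#' @param index Stage counter (any non-negative integer).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 131 + as.numeric(index) * 7919) %% 2147483647)
}

assert_expression_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must carry gene row names and sample column names", call. = FALSE)
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g))
    stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "), call. = FALSE)
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "), call. = FALSE)
  if (anyNA(x)) stop(what, " contains missing values", call. = FALSE)
  invisible(x)
}

#' Bundle an expression matrix with per-sample class labels
#'
#' @param matrix Numeric genes x samples matrix with unique row (gene) and
#'   column (sample) names.
#' @param labels Per-sample classes: a factor or character vector, either in
#'   column order or named by sample id. Factor levels are preserved (declared
#'   but absent classes stay part of the vocabulary); character labels drawn
#'   from [SITE_CLASSES] get that canonical level order.
#' @param synthetic Optional logical vector flagging oversampled (synthetic)
#'   samples; defaults to all-`FALSE`.
#' @return A `labeled_dataset`: list with elements `matrix`, `labels`,
#'   `synthetic`.
#' @export
labeled_dataset <- function(matrix, labels, synthetic = NULL) {
  assert_expression_matrix(matrix)
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(matrix), names(labels))
    if (length(missing))
      stop("labels missing for samples: ", paste(missing, collapse = ", "), call. = FALSE)
    labels <- labels[colnames(matrix)]
  }
  if (length(labels) != ncol(matrix))
    stop("need exactly one label per sample", call. = FALSE)
  lab_chr <- as.character(labels)
  lev <- if (is.factor(labels)) levels(labels)
  else if (all(lab_chr %in% SITE_CLASSES)) intersect(SITE_CLASSES, lab_chr)
  else sort(unique(lab_chr))
  labels <- factor(lab_chr, levels = lev)
  synthetic <- synthetic %||% rep(FALSE, ncol(matrix))
  structure(list(matrix = matrix, labels = labels, synthetic = synthetic),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d genes x %d samples\n", nrow(x$matrix), ncol(x$matrix)))
  print(table(x$labels))
  if (any(x$synthetic)) cat(sum(x$synthetic), "synthetic (oversampled) samples\n")
  invisible(x)
}

#' Stratified train/test split of class labels
#'
#' @param labels Factor of class labels.
#' @param test_fraction Fraction of each class assigned to the test set.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction = 0.25, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  with_seed(seed, {
    test <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_test <- max(1L, round(test_fraction * length(idx)))
      if (n_test >= length(idx))
        stop("class '", cl, "' too small for a ", test_fraction, " test split", call. = FALSE)
      test <- c(test, sample(idx, n_test))
    }
    list(train = setdiff(seq_along(labels), test), test = sort(test))
  })
}

# Stratified fold assignment: every fold contains every class (error if a
# class has fewer samples than folds -- the search contract forbids folds
# missing a class).
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    assign <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < folds)
        stop("class '", cl, "' has fewer samples (", length(idx),
             ") than folds (", folds, ")", call. = FALSE)
      assign[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    assign
  })
}
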