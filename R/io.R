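#' Read an expression matrix from delimited text
#'
#' Expects one header row and one identifier column (the first). The delimiter
#' is taken from the file extension (`.csv` = comma, anything else = tab)
#' unless given explicitly. The canonical in-memory orientation is genes x
#' samples; files holding samples as rows are transposed on read.
#'
#' @param path Path to a TSV/CSV file.
#' @param orientation `"genes_rows"` (default) if file rows are genes,
#'   `"samples_rows"` if file rows are samples.
#' @param sep Field separator; `NULL` (default) auto-detects.
#' @return Numeric genes x samples matrix with gene row names and sample
#'   column names.
#' @export
read_expression <- function(path, orientation = c("genes_rows", "samples_rows"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sep %||% (if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected an id column plus at least one data column", call. = FALSE)
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate identifiers in ", basename(path), ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  col_ids <- colnames(df)[-1]
  dupc <- unique(col_ids[duplicated(col_ids)])
  if (length(dupc))
    stop("duplicate column identifiers in ", basename(path), ": ",
         paste(dupc, collapse = ", "), call. = FALSE)
  values <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                   dimnames = list(ids, col_ids))
  for (j in seq_along(col_ids)) {
    chr <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(chr))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s' of %s",
                   chr[bad[1]], ids[bad[1]], col_ids[j], basename(path)),
           call. = FALSE)
    values[, j] <- num
  }
  if (orientation == "samples_rows") values <- t(values)
  assert_expression_matrix(values, basename(path))
  values
}

#' Write an expression matrix as tab-separated text
#'
#' @param matrix Genes x samples numeric matrix.
#' @param path Output path.
#' @param id_column Header of the identifier column.
#' @export
write_expression <- function(matrix, path, id_column = "gene_id") {
  assert_expression_matrix(matrix)
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a two-column sample label file
#'
#' Format: header row, then `sample_id TAB class` per line.
#'
#' @param path Path to a TSV file.
#' @return Named character vector of classes, names = sample ids.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("label file needs two columns (sample_id, class)", call. = FALSE)
  dup <- unique(df[[1]][duplicated(df[[1]])])
  if (length(dup))
    stop("duplicate sample ids in label file: ", paste(dup, collapse = ", "), call. = FALSE)
  stats::setNames(df[[2]], df[[1]])
}

#' @rdname read_labels
#' @param labels Named character/factor vector (names = sample ids).
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(sample_id = names(labels), class = as.character(labels),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' Two-column TSV (`probe_id`, `gene_id`) with a header row. Many probes may
#' map to one gene; probes without a mapping are dropped at collapse time.
#'
#' @param path Path to a TSV file.
#' @return Data frame with columns `probe_id`, `gene_id`.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("probe map needs two columns (probe_id, gene_id)", call. = FALSE)
  dup <- unique(df[[1]][duplicated(df[[1]])])
  if (length(dup))
    stop("duplicate probe ids in map: ", paste(dup, collapse = ", "), call. = FALSE)
  data.frame(probe_id = df[[1]], gene_id = df[[2]], stringsAsFactors = FALSE)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `name TAB description TAB gene TAB gene ...`.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of gene id
#'   vectors, file order preserved) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 fields (name, description, genes...)",
           call. = FALSE)
    nm <- fields[1]
    if (nm %in% names(sets))
      stop("duplicate gene-set name in GMT: ", nm, call. = FALSE)
    sets[[nm]] <- unique(fields[-(1:2)])
    descriptions[nm] <- fields[2]
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d distinct genes\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}
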