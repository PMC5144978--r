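#' Construct an expression dataset
#'
#' The atomic input of every pipeline stage: a genes x samples matrix of
#' log-scale expression values together with per-sample annotations.
#'
#' @param name Study identifier (single string).
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique rownames (gene symbols) and unique colnames (sample identifiers).
#'   No missing values are allowed; ingest drops incomplete rows before
#'   construction.
#' @param annotations Data frame with one row per sample.  Must contain a
#'   `sample_id` column matching `colnames(values)`; typical further columns
#'   are `histology`, `grade`, `stage` and `original_subtype_label`.  If
#'   `NULL` a minimal annotation table holding only `sample_id` is created.
#'
#' @return An object of class `expr_dataset`: a list with elements `name`,
#'   `values` and `annotations` (annotations reordered to match the sample
#'   order of `values`).
#' @export
expression_dataset <- function(name, values, annotations = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in `values`")
  if (anyNA(values))
    stop("missing values are not allowed in an expr_dataset")
  if (is.null(annotations)) {
    annotations <- data.frame(sample_id = colnames(values),
                              stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(annotations))
    stop("`annotations` must contain a sample_id column")
  if (!setequal(annotations$sample_id, colnames(values)))
    stop("annotation sample_id set must equal the matrix sample set")
  annotations <- annotations[match(colnames(values), annotations$sample_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  structure(list(name = name, values = values, annotations = annotations),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("expr_dataset '%s': %d genes x %d samples\n",
              x$name, nrow(x$values), ncol(x$values)))
  extra <- setdiff(names(x$annotations), "sample_id")
  if (length(extra))
    cat("  annotations:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname expression_dataset
#' @param x Object to test or query.
#' @export
is_expr_dataset <- function(x) inherits(x, "expr_dataset")

#' @rdname expression_dataset
#' @export
genes <- function(x) rownames(x$values)

#' @rdname expression_dataset
#' @export
samples <- function(x) colnames(x$values)

#' Subset an expression dataset by gene and/or sample identifiers
#'
#' @param dataset An `expr_dataset`.
#' @param genes,samples Character vectors of identifiers to keep (in the
#'   given order); `NULL` keeps the current axis untouched.
#' @return A new `expr_dataset`.
#' @export
subset_dataset <- function(dataset, genes = NULL, samples = NULL) {
  stopifnot(is_expr_dataset(dataset))
  vals <- dataset$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(vals))
    if (length(missing))
      stop("genes not present in dataset '", dataset$name, "': ",
           paste(utils::head(missing, 5L), collapse = ", "))
    vals <- vals[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(vals))
    if (length(missing))
      stop("samples not present in dataset '", dataset$name, "': ",
           paste(utils::head(missing, 5L), collapse = ", "))
    vals <- vals[, samples, drop = FALSE]
  }
  ann <- dataset$annotations[dataset$annotations$sample_id %in% colnames(vals), ,
                             drop = FALSE]
  expression_dataset(dataset$name, vals, ann)
}

#' Write an expression matrix to tab-separated text
#'
#' Inverse of [load_expression_matrix()]: first row holds sample identifiers,
#' first column gene identifiers.  Values are printed at full precision
#' (17 significant digits) so a load/write/load round trip is exact.
#'
#' @param dataset An `expr_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(dataset, path) {
  stopifnot(is_expr_dataset(dataset))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(dataset$values)), collapse = "\t"), con)
  body <- apply(format(dataset$values, digits = 17, trim = TRUE,
                       scientific = FALSE), 1L, paste, collapse = "\t")
  writeLines(paste(rownames(dataset$values), body, sep = "\t"), con)
  invisible(path)
}

#' Write a sample-annotation table to tab-separated text
#'
#' @param dataset An `expr_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(dataset, path) {
  stopifnot(is_expr_dataset(dataset))
  utils::write.table(dataset$annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
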