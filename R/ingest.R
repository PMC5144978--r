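#' Load an expression matrix from tab-separated text
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; remaining cells are numeric or empty.  Two cleaning policies
#' are applied and reported: gene rows containing any missing value are
#' dropped, and duplicated gene identifiers are collapsed by keeping the row
#' with the highest variance (the standard microarray probe-collapse rule).
#'
#' @param path Path to a TSV file.
#' @param name Study identifier attached to the dataset.
#' @return An [expression_dataset()] with an `ingest_report` attribute: a list
#'   with `n_dropped_missing`, `n_collapsed_duplicates` and the input
#'   dimensions.
#' @export
load_expression_matrix <- function(path, name) {
  if (!file.exists(path)) stop("cannot read expression matrix: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 3L) stop("expression matrix needs at least 2 samples")
  if (nrow(raw) < 2L) stop("expression matrix needs at least 2 genes")
  gene_ids <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells[cells == ""] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells),
                                 dimnames = list(NULL, colnames(cells))))
  bad <- !is.na(cells) & is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 gene_ids[idx[1L]], colnames(cells)[idx[2L]]))
  }

  incomplete <- apply(num, 1L, anyNA)
  n_dropped <- sum(incomplete)
  num <- num[!incomplete, , drop = FALSE]
  gene_ids <- gene_ids[!incomplete]
  if (nrow(num) < 2L) stop("fewer than 2 complete gene rows after ingest")

  n_collapsed <- 0L
  if (anyDuplicated(gene_ids)) {
    vars <- apply(num, 1L, stats::var)
    ord <- order(vars, decreasing = TRUE)
    keep <- ord[!duplicated(gene_ids[ord])]
    n_collapsed <- nrow(num) - length(keep)
    keep <- sort(keep)  # preserve file order among kept rows
    num <- num[keep, , drop = FALSE]
    gene_ids <- gene_ids[keep]
  }
  rownames(num) <- gene_ids

  ds <- expression_dataset(name, num)
  attr(ds, "ingest_report") <- list(
    name = name,
    n_genes_in = nrow(raw), n_samples = ncol(num),
    n_dropped_missing = n_dropped,
    n_collapsed_duplicates = n_collapsed)
  ds
}

#' Load a sample-annotation table and attach it to a dataset
#'
#' The TSV must contain columns `sample_id`, `histology` and `grade`;
#' `stage` and `original_subtype_label` are optional.  Categorical fields are
#' normalized to lower case, with an optional alias table mapping local
#' vocabulary onto the canonical one (e.g. `c(lmp = "borderline")`).
#'
#' @param dataset An `expr_dataset`.
#' @param path Path to the annotation TSV.
#' @param aliases Named character vector: names are observed categories
#'   (lower-cased), values their canonical replacement.
#' @return The dataset with annotations replaced.
#' @export
load_annotations <- function(dataset, path, aliases = NULL) {
  stopifnot(is_expr_dataset(dataset))
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  req <- c("sample_id", "histology", "grade")
  miss <- setdiff(req, names(ann))
  if (length(miss))
    stop("annotation table lacks required columns: ",
         paste(miss, collapse = ", "))
  for (col in setdiff(names(ann), "sample_id")) {
    v <- tolower(trimws(ann[[col]]))
    v[v == ""] <- NA_character_
    if (!is.null(aliases)) {
      hit <- match(v, tolower(names(aliases)))
      v[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
    }
    ann[[col]] <- v
  }
  expression_dataset(dataset$name, dataset$values, ann)
}

#' Filter samples by histology and grade
#'
#' Retains exactly the samples whose histology and grade fall in the given
#' sets.  Samples with a missing value in either field are excluded unless
#' `keep_missing = TRUE`.  Per-reason exclusion counts are attached as the
#' `filter_report` attribute.
#'
#' @param dataset An `expr_dataset` whose annotations carry `histology` and
#'   `grade` columns.
#' @param keep_histologies,keep_grades Character vectors of categories to
#'   retain (matched after lower-casing).
#' @param keep_missing Keep samples with missing histology/grade?
#' @return The filtered `expr_dataset`; filtering all samples out is an error.
#' @export
apply_inclusion_filter <- function(dataset, keep_histologies, keep_grades,
                                   keep_missing = FALSE) {
  stopifnot(is_expr_dataset(dataset))
  ann <- dataset$annotations
  if (!all(c("histology", "grade") %in% names(ann)))
    stop("annotations must carry histology and grade")
  hist <- tolower(ann$histology)
  grade <- tolower(ann$grade)
  miss <- is.na(hist) | is.na(grade)
  ok_hist <- !is.na(hist) & hist %in% tolower(keep_histologies)
  ok_grade <- !is.na(grade) & grade %in% tolower(keep_grades)
  keep <- (ok_hist & ok_grade) | (keep_missing & miss)
  report <- list(
    n_in = nrow(ann),
    n_excluded_histology = sum(!ok_hist & !miss),
    n_excluded_grade = sum(ok_hist & !ok_grade & !miss),
    n_excluded_missing = if (keep_missing) 0L else sum(miss),
    n_kept = sum(keep))
  if (!any(keep))
    stop("inclusion filter excluded every sample of '", dataset$name, "'")
  out <- subset_dataset(dataset, samples = ann$sample_id[keep])
  attr(out, "filter_report") <- report
  out
}

#' Restrict several datasets to their shared gene universe
#'
#' Every dataset is restricted to the lexicographically sorted intersection
#' of all gene sets, so gene order is identical across studies afterwards
#' (a precondition for comparing signature vectors).
#'
#' @param datasets List of `expr_dataset` objects (at least two).
#' @return List of restricted datasets, with the intersection size attached
#'   as attribute `gene_universe_size` and the genes as `gene_universe`.
#' @export
intersect_gene_universe <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 2L,
            all(vapply(datasets, is_expr_dataset, logical(1L))))
  universe <- Reduce(intersect, lapply(datasets, genes))
  if (!length(universe)) stop("empty gene intersection across datasets")
  universe <- sort(universe)
  out <- lapply(datasets, subset_dataset, genes = universe)
  names(out) <- vapply(out, function(d) d$name, character(1L))
  attr(out, "gene_universe") <- universe
  attr(out, "gene_universe_size") <- length(universe)
  out
}
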