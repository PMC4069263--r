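# Expression container and TSV input/output.

#' Construct a validated expression matrix
#'
#' Bundles a genes x samples matrix of log2 expression scores with per-sample
#' metadata. Gene ids must be unique, every column must have a metadata row,
#' and all values must be finite.
#'
#' @param values numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @param metadata data.frame with columns `sample_id`, `cohort` (one of
#'   "CF", "RF", "SF"), `time_h` (positive hours), `replicate`.
#' @return an object of class `expression_matrix`: list with `values` and
#'   `metadata` (rows ordered as the matrix columns).
#' @export
expression_matrix <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup)) {
    stop("duplicate gene ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  need <- c("sample_id", "cohort", "time_h", "replicate")
  miss_col <- setdiff(need, names(metadata))
  if (length(miss_col)) {
    stop("metadata is missing columns: ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  }
  missing_meta <- setdiff(colnames(values), metadata$sample_id)
  if (length(missing_meta)) {
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  if (!all(metadata$cohort %in% c("CF", "RF", "SF"))) {
    stop("cohort must be one of CF, RF, SF", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    bad <- rownames(values)[apply(!is.finite(values), 1, any)]
    stop("non-finite values in genes: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  metadata <- metadata[match(colnames(values), metadata$sample_id),
                       need, drop = FALSE]
  rownames(metadata) <- NULL
  metadata$time_h <- as.numeric(metadata$time_h)
  if (any(metadata$time_h <= 0)) stop("time_h must be positive", call. = FALSE)
  structure(list(values = values, metadata = metadata),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sort(unique(x$metadata$cohort)), collapse = "/")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its sample metadata from TSV
#'
#' The matrix file has a `gene_id` first column and one column per sample;
#' the metadata file has columns `sample_id`, `cohort`, `time_h`,
#' `replicate`. Validation errors name the offending gene or sample ids.
#'
#' @param matrix_path,metadata_path paths to tab-separated files.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(matrix_path, metadata_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id") {
    stop("first column of ", matrix_path, " must be gene_id", call. = FALSE)
  }
  ids <- as.character(tab$gene_id)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    stop("non-numeric expression cells in ", matrix_path, call. = FALSE)
  }
  rownames(vals) <- ids
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  expression_matrix(vals, meta)
}

#' Write an expression matrix (and optional truth table) to TSV
#'
#' @param x an [expression_matrix()].
#' @param matrix_path,metadata_path output paths.
#' @param truth optional truth data.frame; written next to the matrix.
#' @param truth_path path for the truth table when `truth` is given.
#' @return invisibly, the input `x`.
#' @export
write_expression <- function(x, matrix_path, metadata_path,
                             truth = NULL, truth_path = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  tab <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(truth)) {
    if (is.null(truth_path)) stop("truth_path required when truth is given",
                                  call. = FALSE)
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' Quantile-normalize the columns of an expression matrix
#'
#' After normalization every sample shares the identical empirical
#' distribution (each column's sorted vector equals the row-wise mean of the
#' sorted input columns); ties receive the mean of the quantile values they
#' span. A single-column matrix is returned unchanged with a warning.
#'
#' @param x an [expression_matrix()] or bare numeric matrix.
#' @return object of the same type with normalized values.
#' @export
quantile_normalize <- function(x) {
  m <- if (inherits(x, "expression_matrix")) x$values else x
  if (ncol(m) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged")
    return(x)
  }
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  if (inherits(x, "expression_matrix")) {
    x$values <- qn
    x
  } else {
    qn
  }
}
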