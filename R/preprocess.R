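# Expression-matrix container and the data-preparation rules: low-expression
# filtering on raw FPKM, log2(FPKM + 1) transform, and sample alignment
# against a clinical table with completeness requirements.

na_tokens <- c("", "NA", "NaN", "[Not Available]")

#' Expression matrix with a scale tag
#'
#' A thin wrapper around a numeric features x samples matrix that records
#' whether values are raw FPKM or log2(FPKM + 1), so that scale-dependent
#' operations (the low-expression filter, the log transform) can refuse
#' inputs on the wrong scale.
#'
#' @param values Numeric matrix, rows = features, columns = samples, with
#'   unique row and column names.
#' @param scale_tag `"raw"` (FPKM, nonnegative) or `"log2p1"`.
#' @return A matrix of class `expr_matrix` with attribute `scale_tag`.
#' @export
expr_matrix <- function(values, scale_tag = c("raw", "log2p1")) {
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (scale_tag == "raw" && any(values < 0))
    stop("raw FPKM values must be nonnegative")
  structure(values, scale_tag = scale_tag,
            class = c("expr_matrix", class(values)))
}

expr_scale <- function(x) attr(x, "scale_tag")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples, scale = %s\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}

# subset while keeping class and scale tag
expr_subset <- function(x, i = NULL, j = NULL) {
  tag <- expr_scale(x)
  m <- unclass(x)
  if (!is.null(i)) m <- m[i, , drop = FALSE]
  if (!is.null(j)) m <- m[, j, drop = FALSE]
  expr_matrix(m, tag)
}

#' Remove features with low total FPKM
#'
#' Deletes every feature whose FPKM sum across all samples (both subtypes
#' combined) is strictly below `threshold`; a sum exactly equal to the
#' threshold is retained.  Defined on the raw FPKM scale only.
#'
#' @param matrix An [expr_matrix()] with `scale_tag = "raw"`.
#' @param threshold Minimum retained row sum (default 4).
#' @return The filtered `expr_matrix`, feature order preserved.
#' @export
filter_low_expression <- function(matrix, threshold = 4) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (expr_scale(matrix) != "raw")
    stop("low-expression filter is defined on raw FPKM values only")
  keep <- rowSums(matrix) >= threshold
  expr_subset(matrix, i = which(keep))
}

#' Transform raw FPKM to log2(FPKM + 1)
#'
#' @param matrix An [expr_matrix()] with `scale_tag = "raw"`.
#' @return An `expr_matrix` on the `log2p1` scale.
#' @export
log_transform <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (expr_scale(matrix) != "raw")
    stop("input is already log-transformed")
  if (any(matrix < 0))
    stop("negative FPKM values")
  expr_matrix(log2(unclass(matrix) + 1), "log2p1")
}

is_missing_token <- function(x) {
  if (is.character(x) || is.factor(x)) {
    is.na(x) | trimws(as.character(x)) %in% na_tokens
  } else {
    !is.finite(x)
  }
}

#' Align an expression matrix with a clinical table
#'
#' Keeps the samples present in both the expression matrix and the clinical
#' table that have complete values in every `require`d clinical field
#' (missing means `NA`, `NaN`, the empty string or the token
#' `"[Not Available]"`).  The returned matrix columns and clinical rows are
#' in identical order (order of appearance in the matrix).
#'
#' @param matrix An [expr_matrix()].
#' @param clinical Data frame with a `sample_id` column.
#' @param require Character vector of clinical fields that must be complete
#'   (default `c("os_time", "os_event", "subtype")`).
#' @param min_subtype_warn Warn when an observed subtype level has fewer
#'   samples than this after alignment (default 10).
#' @return A list with elements `expr` and `clinical`.
#' @export
align_samples <- function(matrix, clinical,
                          require = c("os_time", "os_event", "subtype"),
                          min_subtype_warn = 10) {
  stopifnot(inherits(matrix, "expr_matrix"), is.data.frame(clinical))
  if (!"sample_id" %in% names(clinical))
    stop("clinical table needs a sample_id column")
  if (anyDuplicated(clinical$sample_id))
    stop("duplicate sample ids in clinical table")
  missing_cols <- setdiff(require, names(clinical))
  if (length(missing_cols))
    stop("required clinical fields absent: ",
         paste(missing_cols, collapse = ", "))
  complete <- rep(TRUE, nrow(clinical))
  for (f in require)
    complete <- complete & !is_missing_token(clinical[[f]])
  cl <- clinical[complete, , drop = FALSE]
  ids <- intersect(colnames(matrix), cl$sample_id)
  if (!length(ids))
    stop("no samples shared between expression matrix and complete clinical rows")
  ids <- colnames(matrix)[colnames(matrix) %in% ids]  # matrix order
  cl <- cl[match(ids, cl$sample_id), , drop = FALSE]
  rownames(cl) <- NULL
  if ("subtype" %in% names(cl)) {
    tab <- table(cl$subtype)
    small <- tab[tab < min_subtype_warn]
    if (length(small))
      warning(sprintf("subtype level(s) with fewer than %d samples: %s",
                      min_subtype_warn,
                      paste(sprintf("%s (n=%d)", names(small), small),
                            collapse = ", ")))
  }
  list(expr = expr_subset(matrix, j = ids), clinical = cl)
}

# ---- TSV input/output -------------------------------------------------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Write an expression matrix as TSV
#'
#' First column `feature_id`, then one column per sample.  The scale tag is
#' not stored in the file; supply it again when reading.
#'
#' @param matrix An [expr_matrix()].
#' @param path Output path.
#' @export
write_expression <- function(matrix, path) {
  stopifnot(inherits(matrix, "expr_matrix"))
  write_matrix_tsv(unclass(matrix), path)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV with first column `feature_id` and a header row of sample
#'   ids.
#' @param scale_tag Scale of the stored values (`"raw"` or `"log2p1"`).
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, scale_tag = c("raw", "log2p1")) {
  scale_tag <- match.arg(scale_tag)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expr_matrix(m, scale_tag)
}

#' Read a clinical table from TSV
#'
#' Expects at least `sample_id`, `os_time`, `os_event` and `subtype`
#' columns; recognized missing-value tokens (`NA`, `NaN`, empty string,
#' `[Not Available]`) become `NA` in the numeric columns, and are caught in
#' all required columns by [align_samples()].
#'
#' @param path TSV path.
#' @return Data frame with `os_time` numeric and `os_event` integer.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if ("os_time" %in% names(df))
    df$os_time <- suppressWarnings(as.numeric(
      replace(df$os_time, trimws(df$os_time) %in% na_tokens, NA)))
  if ("os_event" %in% names(df))
    df$os_event <- suppressWarnings(as.integer(
      replace(df$os_event, trimws(df$os_event) %in% na_tokens, NA)))
  df
}
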