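#' Validate a gene-by-cell count matrix
#'
#' Checks the count-matrix contract: a numeric matrix of finite,
#' non-negative, integral entries with unique gene and cell identifiers in
#' its dimnames (identifiers are generated when absent).
#'
#' @param cm Matrix-like object (dense matrix or Matrix sparse matrix).
#' @return The validated base matrix.
#' @export
validate_counts <- function(cm) {
  if (inherits(cm, "Matrix")) cm <- as.matrix(cm)
  if (!is.matrix(cm)) cm <- as.matrix(cm)
  if (!is.numeric(cm)) stop("counts must be numeric")
  if (any(!is.finite(cm))) stop("counts contain non-finite entries")
  if (any(cm < 0)) stop("malformed input: negative count entry")
  if (any(cm != round(cm))) stop("malformed input: non-integer count entry")
  if (is.null(rownames(cm)))
    rownames(cm) <- sprintf("gene%05d", seq_len(nrow(cm)))
  if (is.null(colnames(cm)))
    colnames(cm) <- sprintf("cell%05d", seq_len(ncol(cm)))
  if (anyDuplicated(rownames(cm))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(cm))) stop("duplicate cell ids")
  cm
}

#' Construct and validate a cell design
#'
#' @param batch Per-cell batch label (>= 2 levels; every level must contain
#'   at least 2 cells).
#' @param group Per-cell group / cell-type label.
#' @param cell_id Optional cell identifiers.
#' @return A data frame with columns `cell_id`, `batch`, `group` (factors).
#' @export
cell_design <- function(batch, group, cell_id = NULL) {
  if (length(batch) != length(group))
    stop("'batch' and 'group' must have the same length")
  batch <- factor(batch); group <- factor(group)
  if (nlevels(batch) < 2L) stop("need at least 2 batch levels")
  if (any(table(batch) < 2L)) stop("every batch must contain >= 2 cells")
  if (anyNA(batch) || anyNA(group)) stop("batch/group labels must be complete")
  if (is.null(cell_id)) cell_id <- sprintf("cell%05d", seq_along(batch))
  data.frame(cell_id = as.character(cell_id), batch = batch, group = group,
             stringsAsFactors = FALSE)
}

#' Read a count matrix
#'
#' Reads either a dense TSV (header row of cell ids, first column
#' `gene_id`) or a MatrixMarket coordinate file (1-based indices;
#' accompanied by one-column gene and cell id files).
#'
#' @param path Path to the TSV or `.mtx` file.
#' @param format `"auto"` (by extension), `"tsv"` or `"mtx"`.
#' @param genes_file,cells_file Id files for the MatrixMarket format;
#'   default `<path>.genes` / `<path>.cells` next to the matrix.
#' @return A validated dense count matrix with gene/cell dimnames.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx"),
                        genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!nrow(df) || names(df)[1] != "gene_id")
      stop("dense TSV must have a 'gene_id' first column")
    cm <- as.matrix(df[, -1, drop = FALSE])
    rownames(cm) <- df$gene_id
    storage.mode(cm) <- "double"
    return(validate_counts(cm))
  }
  if (is.null(genes_file)) genes_file <- paste0(path, ".genes")
  if (is.null(cells_file)) cells_file <- paste0(path, ".cells")
  if (!file.exists(genes_file) || !file.exists(cells_file))
    stop("MatrixMarket input requires gene and cell id files")
  m <- Matrix::readMM(path)
  genes <- readLines(genes_file)
  cells <- readLines(cells_file)
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop("id files do not match the matrix dimensions")
  cm <- as.matrix(m)
  dimnames(cm) <- list(genes, cells)
  validate_counts(cm)
}

#' Write a count matrix
#'
#' @param cm Count matrix.
#' @param path Output path; `.mtx` writes MatrixMarket coordinate format
#'   plus `<path>.genes` / `<path>.cells` id files, anything else a dense
#'   TSV.
#' @return The path, invisibly.
#' @export
write_counts <- function(cm, path) {
  cm <- validate_counts(cm)
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(cm, sparse = TRUE), path)
    writeLines(rownames(cm), paste0(path, ".genes"))
    writeLines(colnames(cm), paste0(path, ".cells"))
  } else {
    df <- data.frame(gene_id = rownames(cm), cm, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a cell metadata table
#'
#' TSV with columns `cell_id`, `batch`, `group`.
#'
#' @param path Path to the metadata TSV.
#' @return A validated cell design data frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("cell_id", "batch", "group"), names(df))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  cell_design(df$batch, df$group, cell_id = df$cell_id)
}

#' Filter low-count genes
#'
#' Retains genes whose total count across cells is at least `min_total`
#' (default 20, the usual preprocessing threshold for these data), keeping
#' the original gene order.
#'
#' @param cm Count matrix.
#' @param min_total Minimum total count, >= 0.
#' @return The filtered matrix; a warning is raised if no gene survives.
#' @export
filter_genes <- function(cm, min_total = 20) {
  cm <- validate_counts(cm)
  if (min_total < 0) stop("'min_total' must be non-negative")
  keep <- rowSums(cm) >= min_total
  if (!any(keep)) warning("no gene passes the count filter")
  cm[keep, , drop = FALSE]
}

#' Counts per million
#'
#' Scales every cell (column) to sum to 1e6.
#'
#' @param cm Count matrix; every cell must have positive library size.
#' @return Real matrix of CPM values.
#' @export
cpm <- function(cm) {
  cm <- validate_counts(cm)
  ls <- colSums(cm)
  if (any(ls == 0))
    stop("zero library size in cell(s): ",
         paste(colnames(cm)[ls == 0], collapse = ", "))
  sweep(cm, 2, ls / 1e6, "/")
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors against the reference cell (the cell
#' whose upper quartile is closest to the mean upper quartile), rescaled to
#' geometric mean 1, as computed by edgeR's `calcNormFactors`. The offset
#' field is the log effective library size, the standard additive offset
#' for log-link count models.
#'
#' @param cm Count matrix with at least 2 cells.
#' @param logratio_trim,abs_trim Trim fractions for the log-ratios (M) and
#'   absolute intensities (A); the published defaults.
#' @return A list of class `"scmmst_norm"` with `lib_size`, `tmm_factor`
#'   (geometric mean 1) and `offset = log(lib_size * tmm_factor)`.
#' @export
tmm_factors <- function(cm, logratio_trim = 0.3, abs_trim = 0.05) {
  cm <- validate_counts(cm)
  if (ncol(cm) < 2L) stop("TMM needs at least 2 cells")
  f <- suppressWarnings(edgeR::calcNormFactors(
    cm, method = "TMM", logratioTrim = logratio_trim,
    sumTrim = abs_trim))
  if (any(!is.finite(f) | f <= 0)) {
    warning("non-estimable TMM factor(s) set to 1")
    f[!is.finite(f) | f <= 0] <- 1
  }
  f <- f / exp(mean(log(f)))
  ls <- colSums(cm)
  structure(list(lib_size = ls, tmm_factor = stats::setNames(f, colnames(cm)),
                 offset = log(ls * f)),
            class = "scmmst_norm")
}

#' @export
print.scmmst_norm <- function(x, ...) {
  cat("TMM normalization factors for", length(x$tmm_factor), "cells\n")
  print(summary(x$tmm_factor))
  invisible(x)
}
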