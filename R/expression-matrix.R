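#' Validate a cell-by-gene expression matrix
#'
#' The pipeline's substrate is a sparse (or dense) numeric matrix with cells
#' in rows and genes in columns, carrying unique cell barcodes as row names
#' and unique gene symbols as column names. Counts must be non-negative.
#'
#' @param counts matrix or \code{Matrix::dgCMatrix}, cells x genes.
#' @return the matrix, coerced to \code{dgCMatrix}, invisibly validated.
#' @export
as_expression_matrix <- function(counts) {
  if (is.matrix(counts)) counts <- methods::as(counts, "CsparseMatrix")
  if (!methods::is(counts, "sparseMatrix"))
    stop_invalid("`counts` must be a matrix or sparse Matrix")
  counts <- methods::as(counts, "CsparseMatrix")
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts))))
    stop_invalid("`counts` needs cell barcodes as rownames and gene symbols as colnames")
  if (anyDuplicated(rownames(counts)))
    stop_invalid("duplicate cell barcodes in `counts`")
  if (anyDuplicated(colnames(counts)))
    stop_invalid("duplicate gene symbols in `counts`")
  if (any(counts@x < 0))
    stop_invalid("`counts` must be non-negative")
  counts
}

#' Write a dataset (counts, labels, ground truth) to a directory
#'
#' Writes a Matrix Market coordinate file (1-based indices, cells in rows,
#' genes in columns), \code{genes.tsv} (gene_id, gene_symbol),
#' \code{barcodes.tsv}, and, when given, \code{labels.tsv} (barcode,
#' cell_type) plus the ground-truth tables \code{truth_regulons.tsv}
#' (tf, target) and \code{truth_types.tsv} (cell_type, tf).
#'
#' @param expr cells x genes count matrix (see [as_expression_matrix()]).
#' @param dir_path output directory, created if missing.
#' @param labels optional per-cell type labels, length \code{nrow(expr)}.
#' @param gt optional \code{ground_truth_network} from [generate_network()].
#' @return \code{dir_path}, invisibly.
#' @export
write_dataset <- function(expr, dir_path, labels = NULL, gt = NULL) {
  expr <- as_expression_matrix(expr)
  if (nrow(expr) == 0L || ncol(expr) == 0L)
    stop_io("refusing to write an empty matrix to ", dir_path)
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(expr, file.path(dir_path, "matrix.mtx"))
  write.table(data.frame(gene_id = colnames(expr), gene_symbol = colnames(expr)),
              file.path(dir_path, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(expr), file.path(dir_path, "barcodes.tsv"))
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(expr))
    write.table(data.frame(barcode = rownames(expr), cell_type = as.character(labels)),
                file.path(dir_path, "labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(gt)) {
    reg <- do.call(rbind, lapply(names(gt$targets), function(tf)
      data.frame(tf = tf, target = gt$targets[[tf]])))
    write.table(reg, file.path(dir_path, "truth_regulons.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    typ <- do.call(rbind, lapply(names(gt$type_activity), function(ct)
      data.frame(cell_type = ct, tf = gt$type_activity[[ct]])))
    write.table(typ, file.path(dir_path, "truth_types.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir_path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir_path directory containing \code{matrix.mtx}, \code{genes.tsv}
#'   and \code{barcodes.tsv}; label and truth tables are read when present.
#' @return list with \code{counts} (cells x genes \code{dgCMatrix}),
#'   \code{labels} (or NULL) and \code{gt} (a
#'   \code{ground_truth_network}, or NULL).
#' @export
read_dataset <- function(dir_path) {
  need <- c("matrix.mtx", "genes.tsv", "barcodes.tsv")
  for (f in need) {
    if (!file.exists(file.path(dir_path, f)))
      stop_io("missing file '", f, "' in ", dir_path)
  }
  counts <- methods::as(Matrix::readMM(file.path(dir_path, "matrix.mtx")), "CsparseMatrix")
  genes <- read.delim(file.path(dir_path, "genes.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir_path, "barcodes.tsv"))
  if (nrow(genes) != ncol(counts) || length(barcodes) != nrow(counts))
    stop_io("identifier files do not match matrix dimensions in ", dir_path)
  dimnames(counts) <- list(barcodes, genes[[2L]])

  labels <- NULL
  lf <- file.path(dir_path, "labels.tsv")
  if (file.exists(lf)) {
    lab <- read.delim(lf, stringsAsFactors = FALSE)
    labels <- lab$cell_type[match(barcodes, lab$barcode)]
  }

  gt <- NULL
  rf <- file.path(dir_path, "truth_regulons.tsv")
  tf <- file.path(dir_path, "truth_types.tsv")
  if (file.exists(rf) && file.exists(tf)) {
    reg <- read.delim(rf, stringsAsFactors = FALSE)
    typ <- read.delim(tf, stringsAsFactors = FALSE)
    targets <- split(reg$target, reg$tf)
    type_activity <- split(typ$tf, typ$cell_type)
    tfs <- sort(unique(reg$tf))
    background <- setdiff(colnames(counts), c(tfs, unlist(targets)))
    gt <- new_ground_truth_network(tfs, targets[tfs], type_activity, background)
  }
  list(counts = as_expression_matrix(counts), labels = labels, gt = gt)
}
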