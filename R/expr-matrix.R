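#' Expression matrix container
#'
#' Bundles a sparse gene x cell count matrix with per-cell and per-gene
#' metadata. Cell metadata carries at least `cell_id`, and for atlas data
#' `individual`, `area`, `region` and `gw` (gestational week); gene metadata
#' carries `gene_id` and a logical `mito` flag marking mitochondrial genes.
#'
#' @param counts sparse or dense numeric matrix, genes in rows, cells in
#'   columns. Coerced to `dgCMatrix`.
#' @param cells data.frame of per-cell metadata with a `cell_id` column
#'   matching `colnames(counts)`.
#' @param genes data.frame of per-gene metadata with a `gene_id` column
#'   matching `rownames(counts)` and a logical `mito` column.
#' @return An object of class `expr_matrix`: a list with elements `counts`,
#'   `cells`, `genes`.
#' @export
expr_matrix <- function(counts, cells, genes) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and cell colnames")
  stopifnot(is.data.frame(cells), is.data.frame(genes))
  if (!"cell_id" %in% names(cells)) stop("cells needs a cell_id column")
  if (!"gene_id" %in% names(genes)) stop("genes needs a gene_id column")
  if (!identical(as.character(cells$cell_id), colnames(counts)))
    stop("cells$cell_id must match colnames(counts) in order")
  if (!identical(as.character(genes$gene_id), rownames(counts)))
    stop("genes$gene_id must match rownames(counts) in order")
  if (!"mito" %in% names(genes)) genes$mito <- FALSE
  structure(list(counts = counts, cells = cells, genes = genes),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' @method print expr_matrix
#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  mito genes: %d; cell metadata: %s\n",
              sum(x$genes$mito), paste(names(x$cells), collapse = ", ")))
  invisible(x)
}

#' Subset an expression matrix
#'
#' `i` selects genes, `j` selects cells (indices, names or logical), keeping
#' counts and both metadata tables aligned.
#' @param x an `expr_matrix`.
#' @param i,j gene / cell subscripts.
#' @param ... ignored.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, rownames(x$counts))
  if (is.character(j)) j <- match(j, colnames(x$counts))
  expr_matrix(x$counts[i, j, drop = FALSE],
              droplevels(x$cells[j, , drop = FALSE]),
              droplevels(x$genes[i, , drop = FALSE]))
}

#' Write an atlas to disk as Matrix Market + TSV metadata
#'
#' Emits `counts.mtx` (genes x cells), `cells.tsv` and `genes.tsv` into
#' `dir`, the package's plain-text on-disk interchange format.
#' @param x an `expr_matrix`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(x, dir) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "counts.mtx"))
  utils::write.table(x$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an atlas written by [write_atlas()]
#' @param dir directory containing `counts.mtx`, `cells.tsv`, `genes.tsv`.
#' @return an `expr_matrix`.
#' @export
read_atlas <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "counts.mtx"))
  cells <- utils::read.delim(file.path(dir, "cells.tsv"))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"))
  dimnames(counts) <- list(as.character(genes$gene_id),
                           as.character(cells$cell_id))
  expr_matrix(counts, cells, genes)
}
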