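#' Expression matrix container
#'
#' Lightweight S3 container for a single-cell expression matrix with cell and
#' gene annotations. Values are stored genes x cells (the Bioconductor
#' orientation). The `space` tag records whether values are on the raw RPKM
#' scale or natural-log normalized; operations that only make sense in one
#' space check it.
#'
#' @param values numeric matrix, genes in rows, cells in columns, nonnegative.
#'   Must carry rownames (gene ids) and colnames (cell ids).
#' @param cell_meta data.frame with one row per cell; must contain `cell_id`
#'   matching `colnames(values)`. Typical columns: `donor`, `sample`,
#'   `lineage`, `cluster`.
#' @param gene_meta data.frame with one row per gene; must contain `gene_id`
#'   matching `rownames(values)`. Genomic columns (`chrom`, `start`, `end`)
#'   are optional but required by the CNV stage.
#' @param space one of "rpkm" or "lognorm".
#' @return object of class `caf_matrix`.
#' @export
caf_matrix <- function(values, cell_meta, gene_meta, space = c("rpkm", "lognorm")) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix (genes x cells)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and cell colnames")
  }
  if (anyNA(values) || any(values < 0)) stop("values must be nonnegative and non-missing")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate cell ids")
  if (!"cell_id" %in% names(cell_meta)) stop("cell_meta must have a cell_id column")
  if (!"gene_id" %in% names(gene_meta)) stop("gene_meta must have a gene_id column")
  if (!setequal(cell_meta$cell_id, colnames(values)) ||
      nrow(cell_meta) != ncol(values)) {
    stop("cell_meta does not match matrix cells")
  }
  if (!setequal(gene_meta$gene_id, rownames(values)) ||
      nrow(gene_meta) != nrow(values)) {
    stop("gene_meta does not match matrix genes")
  }
  cell_meta <- cell_meta[match(colnames(values), cell_meta$cell_id), , drop = FALSE]
  gene_meta <- gene_meta[match(rownames(values), gene_meta$gene_id), , drop = FALSE]
  rownames(cell_meta) <- cell_meta$cell_id
  rownames(gene_meta) <- gene_meta$gene_id
  structure(
    list(values = values, cell_meta = cell_meta, gene_meta = gene_meta, space = space),
    class = "caf_matrix"
  )
}

#' @export
dim.caf_matrix <- function(x) dim(x$values)

#' @export
print.caf_matrix <- function(x, ...) {
  cat(sprintf(
    "caf_matrix: %d genes x %d cells [%s space]\n",
    nrow(x$values), ncol(x$values), x$space
  ))
  extra <- setdiff(names(x$cell_meta), "cell_id")
  if (length(extra)) cat("cell_meta:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Subset a caf_matrix by cell ids
#' @param mat a `caf_matrix`.
#' @param cells character vector of cell ids to keep.
#' @return a `caf_matrix` restricted to `cells`, in the given order.
#' @export
subset_cells <- function(mat, cells) {
  missing <- setdiff(cells, colnames(mat$values))
  if (length(missing)) {
    stop("unknown cell ids: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  caf_matrix(
    mat$values[, cells, drop = FALSE],
    mat$cell_meta[match(cells, mat$cell_meta$cell_id), , drop = FALSE],
    mat$gene_meta,
    space = mat$space
  )
}

#' Write an expression fixture to disk
#'
#' Writes the matrix plus metadata as plain-text files: either a sparse
#' MatrixMarket triple (`matrix.mtx`, `genes.tsv`, `cells.tsv`) or a dense
#' TSV (`matrix.tsv`, genes x cells with a header row of cell ids), together
#' with `cell_meta.tsv` and a BED-like `genes.bed` (0-based half-open:
#' chrom, start, end, gene_id).
#'
#' @param mat a `caf_matrix`.
#' @param dir output directory (created if absent).
#' @param format "mtx" or "tsv".
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(mat, dir, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(mat$values, sparse = TRUE),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(mat$values), file.path(dir, "genes.tsv"))
    writeLines(colnames(mat$values), file.path(dir, "cells.tsv"))
  } else {
    df <- data.frame(gene_id = rownames(mat$values), mat$values,
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, "matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(mat$cell_meta, file.path(dir, "cell_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gm <- mat$gene_meta
  bed <- data.frame(
    chrom = if ("chrom" %in% names(gm)) gm$chrom else ".",
    start = if ("start" %in% names(gm)) gm$start else 0L,
    end = if ("end" %in% names(gm)) gm$end else 0L,
    gene_id = gm$gene_id
  )
  utils::write.table(bed, file.path(dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(mat$space, file.path(dir, "space.txt"))
  invisible(dir)
}

#' Read an expression fixture from disk
#'
#' Counterpart of [write_fixture()]; autodetects the MTX vs dense-TSV layout.
#' Round-trips are lossless for values and metadata. Every gene in the matrix
#' must appear in `genes.bed`.
#'
#' @param dir fixture directory.
#' @return a `caf_matrix`.
#' @export
read_fixture <- function(dir) {
  if (!dir.exists(dir)) stop("fixture directory not found: ", dir)
  if (file.exists(file.path(dir, "matrix.mtx"))) {
    m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
    genes <- readLines(file.path(dir, "genes.tsv"))
    cells <- readLines(file.path(dir, "cells.tsv"))
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop("matrix.mtx dimensions do not match genes.tsv/cells.tsv in ", dir)
    }
    dimnames(m) <- list(genes, cells)
  } else if (file.exists(file.path(dir, "matrix.tsv"))) {
    df <- utils::read.delim(file.path(dir, "matrix.tsv"), check.names = FALSE)
    if (names(df)[1] != "gene_id") {
      stop("matrix.tsv: first column must be gene_id (", dir, ")")
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene_id
  } else {
    stop("no matrix.mtx or matrix.tsv in ", dir)
  }
  cell_meta <- utils::read.delim(file.path(dir, "cell_meta.tsv"),
                                 colClasses = "character")
  bed <- utils::read.delim(file.path(dir, "genes.bed"), header = FALSE,
                           col.names = c("chrom", "start", "end", "gene_id"),
                           colClasses = c("character", "integer", "integer", "character"))
  missing <- setdiff(rownames(m), bed$gene_id)
  if (length(missing)) {
    stop("genes.bed (", file.path(dir, "genes.bed"), "): missing entries for ",
         length(missing), " matrix genes, e.g. ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  gene_meta <- data.frame(
    gene_id = bed$gene_id, chrom = bed$chrom, start = bed$start, end = bed$end,
    stringsAsFactors = FALSE
  )
  gene_meta <- gene_meta[match(rownames(m), gene_meta$gene_id), , drop = FALSE]
  space <- if (file.exists(file.path(dir, "space.txt"))) {
    readLines(file.path(dir, "space.txt"))[1]
  } else "rpkm"
  caf_matrix(m, cell_meta, gene_meta, space = space)
}
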