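#' Filter low-quality cells from an RPKM matrix
#'
#' Keeps cells with at least `min_genes` detected genes (value strictly
#' positive) and a total RPKM between `min_total` and `max_total`, bounds
#' inclusive. Defaults are the Smart-seq2 atlas thresholds: 400 genes and a
#' per-cell total between 150,000 and 8,000,000 RPKM. The report covers every
#' input cell; a cell violating several rules is recorded under the first
#' failing rule in the order low_genes, low_total, high_total.
#'
#' @param mat a `caf_matrix` in rpkm space.
#' @param min_genes minimum detected genes per cell.
#' @param min_total,max_total inclusive bounds on per-cell total RPKM.
#' @return list with `matrix` (filtered, genes unchanged) and `report`
#'   (data.frame: cell_id, genes_detected, total_rpkm, pass, reason).
#' @export
filter_cells <- function(mat, min_genes = 400L, min_total = 150000,
                         max_total = 8e6) {
  stopifnot(inherits(mat, "caf_matrix"))
  if (mat$space != "rpkm") {
    stop("filter_cells expects an rpkm-space matrix; got '", mat$space, "'")
  }
  genes_detected <- Matrix::colSums(mat$values > 0)
  total <- Matrix::colSums(mat$values)
  reason <- rep("pass", ncol(mat$values))
  reason[total > max_total] <- "high_total"
  reason[total < min_total] <- "low_total"
  reason[genes_detected < min_genes] <- "low_genes"
  pass <- reason == "pass"
  report <- data.frame(
    cell_id = colnames(mat$values),
    genes_detected = as.integer(genes_detected),
    total_rpkm = as.numeric(total),
    pass = pass, reason = reason,
    stringsAsFactors = FALSE
  )
  list(matrix = subset_cells(mat, colnames(mat$values)[pass]), report = report)
}

#' Log-normalize an RPKM matrix
#'
#' Per-cell scaling to a common library size followed by natural-log
#' transform: `v -> ln(1 + v / total_cell * scale_factor)`. Zeros stay zero
#' and within-cell order is preserved. After the transform
#' `sum(exp(x) - 1) == scale_factor` for every cell.
#'
#' @param mat a `caf_matrix` in rpkm space, already quality-filtered.
#' @param scale_factor target per-cell library size (default 1e4).
#' @return a `caf_matrix` in lognorm space.
#' @export
lognormalize <- function(mat, scale_factor = 1e4) {
  stopifnot(inherits(mat, "caf_matrix"))
  if (mat$space != "rpkm") {
    stop("lognormalize expects an rpkm-space matrix; got '", mat$space, "'")
  }
  total <- Matrix::colSums(mat$values)
  if (any(total == 0)) {
    stop("cell(s) with zero total expression: ",
         paste(utils::head(colnames(mat$values)[total == 0], 5), collapse = ", "),
         " (run filter_cells first)")
  }
  v <- log1p(sweep(mat$values, 2, total, "/") * scale_factor)
  caf_matrix(v, mat$cell_meta, mat$gene_meta, space = "lognorm")
}
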