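#' Order genes along the genome
#'
#' Total order by (chromosome rank, start), with a stable tie-break on the
#' gene id so runs are deterministic. Chromosomes named `chr<k>` sort
#' numerically; anything else (chrX, chrY, scaffolds) follows alphabetically.
#' Genes without coordinates are excluded with a warning and listed in the
#' result so reports can name them.
#'
#' @param gene_meta data.frame with gene_id, chrom, start.
#' @return list with `gene_id` (ordered), `chrom` (parallel), `blocks`
#'   (run-length list of per-chromosome index ranges) and `dropped`
#'   (coordinate-less gene ids).
#' @export
order_genes_genomically <- function(gene_meta) {
  stopifnot(all(c("gene_id", "chrom", "start") %in% names(gene_meta)))
  has_coord <- !is.na(gene_meta$chrom) & !is.na(gene_meta$start) &
    gene_meta$chrom != "" & gene_meta$chrom != "."
  dropped <- gene_meta$gene_id[!has_coord]
  if (length(dropped)) {
    warning(length(dropped), " gene(s) without coordinates excluded from the ",
            "genomic ordering, e.g. ", paste(utils::head(dropped, 3), collapse = ", "))
  }
  gm <- gene_meta[has_coord, , drop = FALSE]
  num <- suppressWarnings(as.integer(sub("^chr", "", gm$chrom)))
  chrom_rank <- ifelse(is.na(num), .Machine$integer.max, num)
  o <- order(chrom_rank, gm$chrom, gm$start, gm$gene_id)
  gm <- gm[o, , drop = FALSE]
  r <- rle(gm$chrom)
  ends <- cumsum(r$lengths)
  blocks <- Map(function(ch, s, e) list(chrom = ch, from = s, to = e),
                r$values, ends - r$lengths + 1L, ends)
  list(gene_id = gm$gene_id, chrom = gm$chrom, blocks = unname(blocks),
       dropped = dropped)
}

#' Infer per-cell CNV profiles relative to a stromal reference
#'
#' inferCNV-style estimate on log-normalized expression: drop genes detected
#' in fewer than `min_cells_per_gene` cells, order the rest genomically,
#' subtract the reference-cell mean per gene, clip residuals to
#' `[-clip, +clip]`, smooth with a centered moving average of `window` genes
#' that never crosses a chromosome boundary, re-subtract the reference-cell
#' mean per position, and recenter each cell at its median. The reference
#' mean profile is therefore ~0 everywhere and reference cells carry only
#' smoothed noise.
#'
#' @param mat a `caf_matrix` in lognorm space.
#' @param reference_cells cell ids of the healthy stromal reference.
#' @param min_cells_per_gene minimum cells expressing a gene (default 3).
#' @param window moving-average width in genes (default 101); shrunk with a
#'   warning when a chromosome block is smaller.
#' @param clip residual clipping bound (default 1.0 on natural-log scale).
#' @return object of class `cnv_profiles`: list with `profiles` (positions x
#'   cells), `gene_map` (gene_id, chrom per position), `reference_cells`.
#' @export
infer_cnv_profiles <- function(mat, reference_cells, min_cells_per_gene = 3L,
                               window = 101L, clip = 1.0) {
  stopifnot(inherits(mat, "caf_matrix"))
  if (mat$space != "lognorm") {
    stop("infer_cnv_profiles expects a log-normalized matrix")
  }
  if (!length(reference_cells)) stop("empty reference cell set")
  missing <- setdiff(reference_cells, colnames(mat$values))
  if (length(missing)) stop("reference cells not in matrix: ",
                            paste(utils::head(missing, 3), collapse = ", "))
  expressed <- Matrix::rowSums(mat$values > 0)
  keep <- expressed >= min_cells_per_gene
  if (!any(keep)) stop("no gene passes min_cells_per_gene")
  v <- mat$values[keep, , drop = FALSE]
  ord <- order_genes_genomically(mat$gene_meta[keep, , drop = FALSE])
  v <- v[ord$gene_id, , drop = FALSE]

  ref_mean <- rowMeans(v[, reference_cells, drop = FALSE])
  rel <- pmin(pmax(v - ref_mean, -clip), clip)

  smoothed <- rel
  shrunk <- FALSE
  for (b in ord$blocks) {
    idx <- b$from:b$to
    if (length(idx) < window) shrunk <- TRUE
    smoothed[idx, ] <- smooth_columns(rel[idx, , drop = FALSE], window)
  }
  if (shrunk) {
    warning("moving-average window shrunk to chromosome-block size for ",
            "block(s) smaller than ", window, " genes")
  }
  smoothed <- smoothed - rowMeans(smoothed[, reference_cells, drop = FALSE])
  smoothed <- sweep(smoothed, 2, matrixStats::colMedians(smoothed))

  structure(list(
    profiles = smoothed,
    gene_map = data.frame(gene_id = ord$gene_id, chrom = ord$chrom,
                          stringsAsFactors = FALSE),
    reference_cells = reference_cells, window = window, clip = clip
  ), class = "cnv_profiles")
}

#' @export
print.cnv_profiles <- function(x, ...) {
  cat(sprintf("cnv_profiles: %d positions x %d cells (%d reference cells)\n",
              nrow(x$profiles), ncol(x$profiles), length(x$reference_cells)))
  invisible(x)
}

#' Per-cell CNV signal score (sum of squares)
#'
#' Mean of squared CNV estimates across the genomic window positions. The
#' mean (not the raw sum) makes the statistic invariant to the number of
#' genes retained, which is the only convention under which the published
#' cutoffs (0.017 keratinocyte, 0.026 melanocyte) are on the right scale;
#' `raw_sum = TRUE` gives the plain sum.
#'
#' @param profiles a `cnv_profiles` object or a numeric profile
#'   vector/matrix (positions x cells).
#' @param raw_sum if TRUE return the un-normalized sum of squares.
#' @return named numeric vector of per-cell scores, all `>= 0`.
#' @export
cnv_score <- function(profiles, raw_sum = FALSE) {
  p <- if (inherits(profiles, "cnv_profiles")) profiles$profiles else profiles
  if (is.null(dim(p))) p <- matrix(p, ncol = 1)
  if (nrow(p) == 0L) stop("empty CNV profile")
  if (any(!is.finite(p))) stop("CNV profile contains non-finite values")
  s <- colSums(p^2)
  if (!raw_sum) s <- s / nrow(p)
  s
}

#' Per-sample malignant reference profile
#'
#' For each sample, the mean CNV profile of the cells in the top
#' `top_fraction` of the sample's SoS distribution — a data-driven stand-in
#' for a confirmed-malignant consensus profile. Samples with fewer than
#' `1/top_fraction` cells fall back to the single top cell, with a warning.
#'
#' @param profiles a `cnv_profiles` object.
#' @param sample_groups named character vector: cell id -> sample.
#' @param top_fraction fraction of top-SoS cells to average (default 0.10).
#' @return matrix positions x samples.
#' @export
malignant_reference_profile <- function(profiles, sample_groups,
                                        top_fraction = 0.10) {
  stopifnot(inherits(profiles, "cnv_profiles"), top_fraction > 0, top_fraction <= 1)
  cells <- colnames(profiles$profiles)
  if (!all(cells %in% names(sample_groups))) {
    stop("sample_groups must cover every profiled cell")
  }
  sos <- cnv_score(profiles)
  samples <- unique(sample_groups[cells])
  out <- vapply(samples, function(s) {
    ids <- cells[sample_groups[cells] == s]
    k <- max(1L, floor(length(ids) * top_fraction))
    if (length(ids) < ceiling(1 / top_fraction)) {
      warning("sample ", s, " has ", length(ids),
              " cells; using its single top-SoS cell as reference")
      k <- 1L
    }
    top <- ids[order(sos[ids], decreasing = TRUE)[seq_len(k)]]
    rowMeans(profiles$profiles[, top, drop = FALSE])
  }, numeric(nrow(profiles$profiles)))
  colnames(out) <- samples
  out
}

#' Pearson correlation of each cell to its sample's malignant reference
#'
#' Cells with a constant (zero-variance) profile get r = 0, so degenerate
#' cells can never be called CNV+.
#'
#' @param profiles a `cnv_profiles` object.
#' @param reference matrix positions x samples from
#'   [malignant_reference_profile()].
#' @param sample_groups named character vector: cell id -> sample.
#' @return named numeric vector of correlations in `[-1, 1]`.
#' @export
cnv_correlation <- function(profiles, reference, sample_groups) {
  stopifnot(inherits(profiles, "cnv_profiles"))
  cells <- colnames(profiles$profiles)
  r <- vapply(cells, function(cid) {
    s <- sample_groups[[cid]]
    if (!s %in% colnames(reference)) stop("no reference profile for sample ", s)
    x <- profiles$profiles[, cid]
    y <- reference[, s]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }, numeric(1))
  r
}

#' Classify cells as CNV+, CNV- or undefined
#'
#' Quadrant rule on (Pearson r to the malignant reference, SoS): CNV+ iff
#' both exceed the lineage cutoffs, CNV- iff both fall below, undefined when
#' exactly one criterion is met. Cutoffs: keratinocyte r >= 0.45 and
#' SoS >= 0.017; melanocyte r >= 0.40 and SoS >= 0.026.
#'
#' @param r numeric vector of correlations.
#' @param sos numeric vector of SoS scores (same length/order).
#' @param lineage "keratinocyte" or "melanocyte" (scalar or per cell).
#' @return data.frame: cell_id (from names of r if present), r, sos, lineage,
#'   call in {CNV_plus, CNV_minus, undefined}.
#' @export
classify_malignancy <- function(r, sos, lineage) {
  cutoffs <- list(keratinocyte = c(r = 0.45, sos = 0.017),
                  melanocyte = c(r = 0.40, sos = 0.026))
  if (length(lineage) == 1L) lineage <- rep(lineage, length(r))
  if (length(r) != length(sos) || length(lineage) != length(r)) {
    stop("r, sos and lineage lengths differ")
  }
  bad <- setdiff(unique(lineage), names(cutoffs))
  if (length(bad)) stop("unknown lineage(s): ", paste(bad, collapse = ", "))
  r[!is.finite(r)] <- 0
  r_cut <- vapply(lineage, function(l) cutoffs[[l]]["r"], numeric(1))
  s_cut <- vapply(lineage, function(l) cutoffs[[l]]["sos"], numeric(1))
  hi_r <- r >= r_cut
  hi_s <- sos >= s_cut
  call <- ifelse(hi_r & hi_s, "CNV_plus",
                 ifelse(!hi_r & !hi_s, "CNV_minus", "undefined"))
  data.frame(
    cell_id = names(r) %||% paste0("cell", seq_along(r)),
    r = unname(r), sos = unname(sos), lineage = lineage, call = call,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Full malignancy-calling pipeline
#'
#' Convenience wrapper: profiles, SoS, per-sample malignant reference,
#' correlation, quadrant classification.
#'
#' @param mat a log-normalized `caf_matrix` whose `cell_meta` has a `sample`
#'   column.
#' @param reference_cells healthy stromal cell ids.
#' @param lineage lineage for the cutoffs (scalar or per scored cell).
#' @param ... passed to [infer_cnv_profiles()].
#' @param top_fraction passed to [malignant_reference_profile()].
#' @return list with `calls` (classification data.frame) and `profiles`.
#' @export
call_malignancy <- function(mat, reference_cells, lineage = "keratinocyte",
                            top_fraction = 0.10, ...) {
  profiles <- infer_cnv_profiles(mat, reference_cells, ...)
  groups <- stats::setNames(mat$cell_meta$sample, mat$cell_meta$cell_id)
  ref <- malignant_reference_profile(profiles, groups, top_fraction)
  r <- cnv_correlation(profiles, ref, groups)
  sos <- cnv_score(profiles)
  list(calls = classify_malignancy(r, sos[names(r)], lineage),
       profiles = profiles)
}

#' Flag cells with high PTCH1/PTCH2 expression
#'
#' CNV inference from expression only sees large chromosomal events, so
#' basal-cell-carcinoma keratinocytes are additionally flagged when PTCH1 or
#' PTCH2 log expression exceeds the healthy-cluster mean by more than `k_sd`
#' standard deviations for that gene.
#'
#' @param mat a log-normalized `caf_matrix`.
#' @param candidate_cells cell ids to flag.
#' @param healthy_cells cell ids defining the healthy baseline.
#' @param genes the pathway genes to test (default PTCH1, PTCH2); at least
#'   one must be present in the matrix.
#' @param k_sd flagging threshold in healthy SDs (default 2).
#' @return named logical vector over `candidate_cells`.
#' @export
flag_ptch_high <- function(mat, candidate_cells, healthy_cells,
                           genes = c("PTCH1", "PTCH2"), k_sd = 2.0) {
  stopifnot(inherits(mat, "caf_matrix"))
  present <- intersect(genes, rownames(mat$values))
  if (!length(present)) {
    stop("none of ", paste(genes, collapse = "/"), " present in the matrix")
  }
  flags <- rep(FALSE, length(candidate_cells))
  names(flags) <- candidate_cells
  for (g in present) {
    h <- mat$values[g, healthy_cells]
    thr <- mean(h) + k_sd * stats::sd(h)
    flags <- flags | (mat$values[g, candidate_cells] > thr)
  }
  flags
}
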