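#' Rank-sum differential expression (cluster vs rest)
#'
#' Wilcoxon rank-sum marker test in the style of Seurat's FindAllMarkers on
#' log-normalized data. Genes detected in fewer than `min_pct` of both groups
#' or with |log2 fold change| below `min_abs_log2fc` are not tested; the
#' log2 fold change uses mean expm1 expression with a pseudocount of 1.
#' Benjamini-Hochberg correction spans the tested genes; returned entries
#' satisfy `p_adj <= adj_p_max` and are sorted by p_adj, then |log2FC|
#' descending.
#'
#' @param mat a log-normalized `caf_matrix`.
#' @param labels cluster label per cell (defaults to `cell_meta$cluster`).
#' @param cluster the cluster to contrast against all other cells.
#' @param min_pct minimum detection fraction in at least one group (0.10).
#' @param min_abs_log2fc minimum |log2FC| to test (0.25).
#' @param adj_p_max BH-adjusted p cutoff for returned entries (0.01).
#' @param only_pos keep only up-regulated markers (default FALSE, the named
#'   tool's default).
#' @param exact_limit exact rank-sum enumeration when both groups are at most
#'   this large (default 10), normal approximation otherwise.
#' @return data.frame of class `signature_set`: cluster, gene,
#'   log2_fold_change, p_raw, p_adj, pct_in, pct_out.
#' @export
rank_sum_de <- function(mat, labels = NULL, cluster, min_pct = 0.10,
                        min_abs_log2fc = 0.25, adj_p_max = 0.01,
                        only_pos = FALSE, exact_limit = 10L) {
  stopifnot(inherits(mat, "caf_matrix"))
  if (is.null(labels)) labels <- mat$cell_meta$cluster
  if (length(labels) != ncol(mat$values)) stop("labels length != cell count")
  if (!cluster %in% labels) stop("unknown cluster label: ", cluster)
  in_cl <- labels == cluster
  if (sum(in_cl) < 3L || sum(!in_cl) < 3L) {
    stop("need at least 3 cells in the cluster and in the complement")
  }
  v_in <- mat$values[, in_cl, drop = FALSE]
  v_out <- mat$values[, !in_cl, drop = FALSE]
  pct_in <- rowMeans(v_in > 0)
  pct_out <- rowMeans(v_out > 0)
  mean_in <- rowMeans(expm1(v_in))
  mean_out <- rowMeans(expm1(v_out))
  lfc <- log2((mean_in + 1) / (mean_out + 1))
  constant <- matrixStats::rowVars(mat$values) == 0
  testable <- (pmax(pct_in, pct_out) >= min_pct) &
    (abs(lfc) >= min_abs_log2fc) & !constant
  genes <- rownames(mat$values)[testable]
  if (!length(genes)) {
    return(empty_signature(cluster))
  }
  p_raw <- vapply(genes, function(g) {
    rank_sum_test(v_in[g, ], v_out[g, ], exact_limit = exact_limit)$p
  }, numeric(1))
  p_adj <- bh_adjust(p_raw)
  out <- data.frame(
    cluster = cluster, gene = genes,
    log2_fold_change = lfc[genes],
    p_raw = unname(p_raw), p_adj = unname(p_adj),
    pct_in = pct_in[genes], pct_out = pct_out[genes],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[out$p_adj <= adj_p_max, , drop = FALSE]
  if (only_pos) out <- out[out$log2_fold_change > 0, , drop = FALSE]
  out <- out[order(out$p_adj, -abs(out$log2_fold_change), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signature_set", "data.frame")
  out
}

empty_signature <- function(cluster) {
  out <- data.frame(cluster = character(0), gene = character(0),
                    log2_fold_change = numeric(0), p_raw = numeric(0),
                    p_adj = numeric(0), pct_in = numeric(0), pct_out = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("signature_set", "data.frame")
  out
}

#' Signatures for every cluster
#'
#' Runs [rank_sum_de()] for each cluster label and returns a named list.
#'
#' @inheritParams rank_sum_de
#' @param ... passed to [rank_sum_de()].
#' @return named list of `signature_set` data.frames.
#' @export
all_cluster_signatures <- function(mat, labels = NULL, ...) {
  if (is.null(labels)) labels <- mat$cell_meta$cluster
  cls <- sort(unique(labels))
  stats::setNames(lapply(cls, function(cl) rank_sum_de(mat, labels, cl, ...)), cls)
}

#' Bin-matched gene-program module score
#'
#' AddModuleScore-style program score: all genes are binned into `n_bins` by
#' their average expression across cells; for each program gene, `n_ctrl`
#' control genes are sampled with replacement from its bin; the per-cell
#' score is the mean expression of the program genes minus the mean over the
#' pooled control draws. Program genes absent from the matrix, or with zero
#' expression in every cell, are dropped (and listed in the result), matching
#' the published exclusion of never-expressed chemokine/cytokine genes.
#'
#' @param mat a log-normalized `caf_matrix`.
#' @param gene_set character vector of program genes.
#' @param n_bins expression bins (default 24).
#' @param n_ctrl control genes sampled per program gene (default 100).
#' @param seed integer; required so control sampling is reproducible.
#' @return object of class `module_score`: list with `score` (named per-cell
#'   numeric), `genes_used`, `genes_dropped`, `n_bins`, `n_ctrl`, `seed`.
#' @export
module_score <- function(mat, gene_set, n_bins = 24L, n_ctrl = 100L, seed) {
  stopifnot(inherits(mat, "caf_matrix"))
  if (missing(seed)) stop("seed is required for reproducible control sampling")
  present <- intersect(gene_set, rownames(mat$values))
  nonzero <- present[Matrix::rowSums(mat$values[present, , drop = FALSE] > 0) > 0]
  dropped <- setdiff(gene_set, nonzero)
  if (!length(nonzero)) {
    stop("effective gene set empty after dropping absent/never-expressed genes: ",
         paste(utils::head(dropped, 10), collapse = ", "))
  }
  avg <- rowMeans(mat$values)
  n_bins_eff <- min(n_bins, nrow(mat$values))
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins_eff / length(avg))
  bin_members <- split(rownames(mat$values), bin)

  set.seed(seed)
  ctrl <- unlist(lapply(nonzero, function(g) {
    sample(bin_members[[as.character(bin[[g]])]], n_ctrl, replace = TRUE)
  }), use.names = FALSE)
  score <- colMeans(mat$values[nonzero, , drop = FALSE]) -
    colMeans(mat$values[ctrl, , drop = FALSE])
  structure(list(score = score, genes_used = nonzero, genes_dropped = dropped,
                 n_bins = n_bins, n_ctrl = n_ctrl, seed = seed),
            class = "module_score")
}

#' @export
print.module_score <- function(x, ...) {
  cat(sprintf("module_score: %d cells, %d program genes (%d dropped), %d bins x %d controls, seed %d\n",
              length(x$score), length(x$genes_used), length(x$genes_dropped),
              x$n_bins, x$n_ctrl, x$seed))
  invisible(x)
}

#' Compare module scores between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test on per-cell scores; exact enumeration
#' when both groups have at most `exact_limit` cells.
#'
#' @param scores a `module_score` object or named numeric vector.
#' @param group_a_cells,group_b_cells disjoint cell id vectors.
#' @param exact_limit see [rank_sum_test()].
#' @return list with `statistic` (centered U; sign-flips under label swap)
#'   and `p` (two-sided).
#' @export
compare_module_scores <- function(scores, group_a_cells, group_b_cells,
                                  exact_limit = 10L) {
  s <- if (inherits(scores, "module_score")) scores$score else scores
  if (length(intersect(group_a_cells, group_b_cells))) {
    stop("cell groups overlap")
  }
  missing <- setdiff(c(group_a_cells, group_b_cells), names(s))
  if (length(missing)) stop("cells without scores: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  res <- rank_sum_test(s[group_a_cells], s[group_b_cells],
                       exact_limit = exact_limit)
  list(statistic = res$statistic_centered, p = res$p, exact = res$exact)
}
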