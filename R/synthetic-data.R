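#' Simulation configuration for a synthetic Smart-seq2 atlas
#'
#' Describes a multi-donor plate-based scRNA-seq experiment with
#' cluster-specific marker programs, contiguous genomic gain/loss segments in
#' a designated malignant cluster, and planted ligand-receptor circuits
#' between clusters. Expression follows a per-gene log-normal baseline; all
#' planted effects act multiplicatively in linear space (additively in
#' natural-log space), so fold changes are exactly recoverable. Dropout is
#' independent per-cell-per-gene Bernoulli zeroing (Smart-seq2 sparsity is
#' moderate, default rate 0.3).
#'
#' Default scale emulates the atlas study design: 15 donors, four clusters of
#' 96 cells per donor (5760 cells), and a gene count chosen so that at the
#' default dropout rate the median genes detected per cell is near the
#' reported 3242.
#'
#' @param n_donors number of donors; each donor is one sample.
#' @param clusters list of cluster specs, each a list with `name`,
#'   `n_cells_per_donor` (scalar, or length-`n_donors` vector for donor skew)
#'   and optional `markers` (named numeric: gene id -> natural-log shift).
#' @param n_genes total genes.
#' @param n_chromosomes genes are split evenly over this many chromosomes.
#' @param cnv_segments data.frame(chrom, start_gene, length, fold): contiguous
#'   segments (1-based gene index within chromosome) multiplied into malignant
#'   cells' expression. Segments must lie in bounds and not overlap.
#' @param malignant_cluster cluster name whose cells carry the CNV segments
#'   (NULL for none).
#' @param malignant_donors donors whose `malignant_cluster` cells are actually
#'   malignant (default NULL: all donors). Lets a fixture plant CNVs in a
#'   single sample.
#' @param lr_circuits data.frame(source, target, ligand, receptor, delta):
#'   ligand gene up-shifted by `delta` (log space) in the source cluster,
#'   receptor in the target cluster.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of per-gene
#'   mean expression (RPKM-like scale).
#' @param noise_sd per-cell-per-gene Gaussian noise sd in log space.
#' @param dropout_rate Bernoulli zeroing probability.
#' @param seed integer; fixes all randomness end-to-end.
#' @return validated object of class `sim_config`.
#' @export
sim_config <- function(n_donors = 15L,
                       clusters = default_clusters(),
                       n_genes = 4600L,
                       n_chromosomes = 23L,
                       cnv_segments = NULL,
                       malignant_cluster = NULL,
                       malignant_donors = NULL,
                       lr_circuits = NULL,
                       baseline_meanlog = log(100),
                       baseline_sdlog = 1,
                       noise_sd = 0.4,
                       dropout_rate = 0.3,
                       seed = 1L) {
  stopifnot(n_donors >= 1, n_genes >= n_chromosomes, n_chromosomes >= 1)
  if (!length(clusters)) stop("need at least one cluster")
  cl_names <- vapply(clusters, function(cl) cl$name, character(1))
  if (anyDuplicated(cl_names)) stop("duplicate cluster names")
  for (cl in clusters) {
    n <- cl$n_cells_per_donor
    if (!(length(n) %in% c(1L, n_donors)) || any(n < 0) || sum(n) < 1) {
      stop("cluster ", cl$name, ": n_cells_per_donor must be a scalar or ",
           "length-n_donors vector with at least one cell in total")
    }
    if (!is.null(cl$markers) && (is.null(names(cl$markers)) || anyNA(cl$markers) ||
                                 any(!is.finite(cl$markers)))) {
      stop("cluster ", cl$name, ": markers must be a named finite numeric vector")
    }
  }
  genes_per_chrom <- diff(round(seq(0, n_genes, length.out = n_chromosomes + 1)))
  if (!is.null(cnv_segments)) {
    need <- c("chrom", "start_gene", "length", "fold")
    if (!all(need %in% names(cnv_segments))) {
      stop("cnv_segments needs columns: ", paste(need, collapse = ", "))
    }
    if (any(cnv_segments$fold <= 0)) stop("cnv_segments: fold must be positive")
    chrom_names <- paste0("chr", seq_len(n_chromosomes))
    for (ch in unique(cnv_segments$chrom)) {
      if (!ch %in% chrom_names) stop("cnv_segments: unknown chromosome ", ch)
      seg <- cnv_segments[cnv_segments$chrom == ch, , drop = FALSE]
      len <- genes_per_chrom[match(ch, chrom_names)]
      if (any(seg$start_gene < 1) || any(seg$start_gene + seg$length - 1 > len)) {
        stop("cnv_segments: segment out of bounds on ", ch)
      }
      seg <- seg[order(seg$start_gene), , drop = FALSE]
      if (nrow(seg) > 1 &&
          any(seg$start_gene[-1] <= (seg$start_gene + seg$length - 1)[-nrow(seg)])) {
        stop("cnv_segments: overlapping segments on ", ch)
      }
    }
    if (is.null(malignant_cluster)) {
      stop("cnv_segments given but no malignant_cluster named")
    }
  }
  if (!is.null(malignant_cluster) && !malignant_cluster %in% cl_names) {
    stop("malignant_cluster ", malignant_cluster, " is not a configured cluster")
  }
  if (!is.null(malignant_donors)) {
    donor_ids <- sprintf("D%02d", seq_len(n_donors))
    if (!all(malignant_donors %in% donor_ids)) {
      stop("malignant_donors must be among ", paste(donor_ids, collapse = ", "))
    }
  }
  if (!is.null(lr_circuits)) {
    need <- c("source", "target", "ligand", "receptor", "delta")
    if (!all(need %in% names(lr_circuits))) {
      stop("lr_circuits needs columns: ", paste(need, collapse = ", "))
    }
    bad <- setdiff(unique(c(lr_circuits$source, lr_circuits$target)), cl_names)
    if (length(bad)) stop("lr_circuits: unknown cluster name(s): ",
                          paste(bad, collapse = ", "))
    if (any(!is.finite(lr_circuits$delta))) stop("lr_circuits: delta must be finite")
  }
  stopifnot(is.finite(noise_sd), noise_sd >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(
    n_donors = as.integer(n_donors), clusters = clusters,
    n_genes = as.integer(n_genes), n_chromosomes = as.integer(n_chromosomes),
    genes_per_chrom = as.integer(genes_per_chrom),
    cnv_segments = cnv_segments, malignant_cluster = malignant_cluster,
    malignant_donors = malignant_donors, lr_circuits = lr_circuits,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    noise_sd = noise_sd, dropout_rate = dropout_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default cluster layout (atlas-scale: 4 clusters x 96 cells x 15 donors)
#' @return list of cluster specs for [sim_config()].
#' @export
default_clusters <- function() {
  list(
    list(name = "Tumor", n_cells_per_donor = 96L),
    list(name = "Fibroblast", n_cells_per_donor = 96L),
    list(name = "iCAF", n_cells_per_donor = 96L),
    list(name = "mCAF", n_cells_per_donor = 96L)
  )
}

#' Generate a synthetic multi-donor expression atlas
#'
#' Draws an RPKM-scale genes x cells matrix under the model described in
#' [sim_config()], together with full ground truth (cell assignments,
#' malignancy flags, planted markers, circuits and CNV segments). The same
#' config and seed always reproduce the matrix bit-for-bit.
#'
#' @param config a `sim_config`.
#' @return list with `matrix` (a `caf_matrix` in rpkm space) and `truth`
#'   (list of cells, markers, lr_circuits, cnv_segments data.frames).
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
  chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), config$genes_per_chrom)
  # position index restarts on each chromosome; 10 kb spacing, 1 kb genes
  pos_in_chrom <- sequence(config$genes_per_chrom)
  gene_meta <- data.frame(
    gene_id = gene_ids, chrom = chrom,
    start = (pos_in_chrom - 1L) * 10000L, end = (pos_in_chrom - 1L) * 10000L + 1000L,
    stringsAsFactors = FALSE
  )

  cells <- do.call(rbind, lapply(config$clusters, function(cl) {
    n <- cl$n_cells_per_donor
    if (length(n) == 1L) n <- rep(n, config$n_donors)
    do.call(rbind, lapply(seq_len(config$n_donors), function(d) {
      if (n[d] == 0L) return(NULL)
      data.frame(cluster = cl$name, donor = sprintf("D%02d", d),
                 n = seq_len(n[d]), stringsAsFactors = FALSE)
    }))
  }))
  n_cells <- nrow(cells)
  cell_meta <- data.frame(
    cell_id = sprintf("C%05d", seq_len(n_cells)),
    donor = cells$donor, sample = cells$donor,
    lineage = ifelse(cells$cluster == (config$malignant_cluster %||% ""),
                     "keratinocyte", "stromal"),
    cluster = cells$cluster, stringsAsFactors = FALSE
  )

  gene_meanlog <- stats::rnorm(config$n_genes, config$baseline_meanlog,
                               config$baseline_sdlog)
  logexpr <- matrix(gene_meanlog, nrow = config$n_genes, ncol = n_cells) +
    matrix(stats::rnorm(config$n_genes * n_cells, 0, config$noise_sd),
           nrow = config$n_genes)

  marker_rows <- list()
  for (cl in config$clusters) {
    if (is.null(cl$markers) || !length(cl$markers)) next
    bad <- setdiff(names(cl$markers), gene_ids)
    if (length(bad)) stop("cluster ", cl$name, ": marker gene(s) not in gene set: ",
                          paste(utils::head(bad, 3), collapse = ", "))
    idx <- match(names(cl$markers), gene_ids)
    cols <- which(cell_meta$cluster == cl$name)
    logexpr[idx, cols] <- logexpr[idx, cols] + cl$markers
    marker_rows[[cl$name]] <- data.frame(
      cluster = cl$name, gene = names(cl$markers), delta = unname(cl$markers),
      stringsAsFactors = FALSE
    )
  }

  if (!is.null(config$lr_circuits)) {
    for (i in seq_len(nrow(config$lr_circuits))) {
      ci <- config$lr_circuits[i, ]
      li <- match(ci$ligand, gene_ids); ri <- match(ci$receptor, gene_ids)
      if (is.na(li) || is.na(ri)) {
        stop("lr_circuits: ligand/receptor gene not in gene set (row ", i, ")")
      }
      logexpr[li, cell_meta$cluster == ci$source] <-
        logexpr[li, cell_meta$cluster == ci$source] + ci$delta
      logexpr[ri, cell_meta$cluster == ci$target] <-
        logexpr[ri, cell_meta$cluster == ci$target] + ci$delta
    }
  }

  is_malignant <- rep(FALSE, n_cells)
  if (!is.null(config$cnv_segments)) {
    is_malignant <- cell_meta$cluster == config$malignant_cluster
    if (!is.null(config$malignant_donors)) {
      is_malignant <- is_malignant & cell_meta$donor %in% config$malignant_donors
    }
    chrom_offset <- c(0L, cumsum(config$genes_per_chrom))
    chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
    for (i in seq_len(nrow(config$cnv_segments))) {
      seg <- config$cnv_segments[i, ]
      off <- chrom_offset[match(seg$chrom, chrom_names)]
      idx <- off + seq(seg$start_gene, seg$start_gene + seg$length - 1L)
      logexpr[idx, is_malignant] <- logexpr[idx, is_malignant] + log(seg$fold)
    }
  }

  values <- exp(logexpr)
  if (config$dropout_rate > 0) {
    keep <- stats::runif(length(values)) >= config$dropout_rate
    values <- values * keep
  }
  dimnames(values) <- list(gene_ids, cell_meta$cell_id)

  truth <- list(
    cells = data.frame(cell_id = cell_meta$cell_id, donor = cell_meta$donor,
                       cluster = cell_meta$cluster, is_malignant = is_malignant,
                       stringsAsFactors = FALSE),
    markers = if (length(marker_rows)) do.call(rbind, marker_rows) else NULL,
    lr_circuits = config$lr_circuits,
    cnv_segments = config$cnv_segments
  )
  list(matrix = caf_matrix(values, cell_meta, gene_meta, space = "rpkm"),
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic ROI quantification table
#'
#' Emulates in situ CAF quantification: for each sample, `n_rois_per_sample`
#' regions of interest with log-normal areas and Poisson phenotype counts at
#' the class-specific planted density. CD3 counts inside tumor nests follow a
#' log-linear exclusion model against the observed per-ROI mCAF density:
#' `log10(cd3 density) = alpha + exclusion_beta * log10(mCAF density + 1) + eps`
#' — the same pseudocounted transform [exclusion_regression()] fits, so the
#' planted slope is exactly identifiable and zero-count ROIs are
#' well-defined. CD3-in-nest counts are stored as expected (possibly
#' fractional) counts so the slope is exactly recoverable at zero noise;
#' phenotype counts are integer Poisson draws.
#'
#' @param n_samples_per_class named integer vector (tumor class -> samples),
#'   or a single integer applied to the default six skin-tumor classes.
#' @param class_rates named list: tumor class -> named numeric vector of mean
#'   densities (cells/mm^2) per phenotype. All rates must be positive.
#' @param exclusion_beta planted log-log slope of CD3-in-nest density on mCAF
#'   density (0 disables exclusion).
#' @param noise_sd sd of the Gaussian noise on log10 CD3 density.
#' @param cd3_alpha intercept: log10 CD3 density at mCAF density 1 cell/mm^2.
#' @param area_meanlog,area_sdlog log-normal ROI area parameters (mm^2).
#' @param n_rois_per_sample ROIs per sample, at least 5.
#' @param seed integer seed.
#' @return list with `roi` (the ROI data.frame) and `truth` (planted
#'   parameters).
#' @export
generate_roi_table <- function(n_samples_per_class = default_class_sizes(),
                               class_rates = default_class_rates(),
                               exclusion_beta = -0.5,
                               noise_sd = 0.15,
                               cd3_alpha = 2.5,
                               area_meanlog = log(0.5),
                               area_sdlog = 0.35,
                               n_rois_per_sample = 5L,
                               seed = 1L) {
  if (length(n_samples_per_class) == 1L && is.null(names(n_samples_per_class))) {
    n_samples_per_class <- stats::setNames(
      rep(as.integer(n_samples_per_class), length(class_rates)), names(class_rates))
  }
  if (n_rois_per_sample < 5L) stop("need at least 5 ROIs per sample")
  if (!all(names(n_samples_per_class) %in% names(class_rates))) {
    stop("every class needs rates in class_rates")
  }
  if (any(unlist(class_rates) <= 0)) stop("all planted rates must be positive")
  set.seed(seed)
  phenos <- unique(unlist(lapply(class_rates, names)))
  rows <- list()
  k <- 0L
  for (cls in names(n_samples_per_class)) {
    rates <- class_rates[[cls]]
    for (s in seq_len(n_samples_per_class[[cls]])) {
      k <- k + 1L
      sid <- sprintf("S%03d", k)
      for (r in seq_len(n_rois_per_sample)) {
        area <- stats::rlnorm(1, area_meanlog, area_sdlog)
        if (area <= 0) stop("nonpositive ROI area drawn")  # unreachable for lognormal
        counts <- stats::setNames(
          stats::rpois(length(phenos), rates[phenos] * area), phenos)
        mcaf_dens <- counts[["mCAF"]] / area
        nest_area <- area * stats::runif(1, 0.2, 0.5)
        cd3_dens <- 10^(cd3_alpha + exclusion_beta * log10(mcaf_dens + 1) +
                        if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, tumor_class = cls, roi_id = sprintf("%s_R%02d", sid, r),
          area_mm2 = area, as.list(counts),
          cd3_in_nest_count = cd3_dens * nest_area, nest_area_mm2 = nest_area,
          stringsAsFactors = FALSE, check.names = FALSE
        )
      }
    }
  }
  roi <- do.call(rbind, rows)
  list(roi = roi,
       truth = list(class_rates = class_rates, exclusion_beta = exclusion_beta,
                    cd3_alpha = cd3_alpha, noise_sd = noise_sd))
}

#' Default per-class sample sizes for the spatial simulation
#'
#' Mirrors the section counts of the in situ cohort: nodular BCC n=8,
#' infiltrative BCC n=9, well/poorly differentiated SCC n=8/10, low/high
#' grade melanoma n=8/9.
#' @return named integer vector.
#' @export
default_class_sizes <- function() {
  c("nodular BCC" = 8L, "infiltrative BCC" = 9L,
    "well-diff SCC" = 8L, "poorly-diff SCC" = 10L,
    "low-grade melanoma" = 8L, "high-grade melanoma" = 9L)
}

#' Default planted densities (cells/mm^2) per tumor class
#'
#' Aggressive classes (infiltrative BCC, poorly differentiated SCC,
#' high-grade melanoma) carry roughly two-fold higher iCAF/mCAF densities
#' than their indolent counterparts.
#' @return named list of named numeric vectors.
#' @export
default_class_rates <- function() {
  lo <- c(totalCAF = 150, iCAF = 30, mCAF = 40)
  hi <- c(totalCAF = 300, iCAF = 60, mCAF = 80)
  list("nodular BCC" = lo, "infiltrative BCC" = hi,
       "well-diff SCC" = lo, "poorly-diff SCC" = hi,
       "low-grade melanoma" = lo, "high-grade melanoma" = hi)
}

#' Build a synthetic ligand-receptor database
#'
#' Samples disjoint ligand and receptor gene sets from a gene universe and
#' wires random pairs, optionally forcing a set of planted pairs to be
#' present. Labelled synthetic: it stands in for curated ligand-receptor
#' catalogues, which cannot be bundled.
#'
#' @param gene_ids character vector to draw ligand/receptor genes from.
#' @param n_ligands,n_receptors universe sizes. Defaults give a pair density
#'   (pairs / (ligands x receptors) ~ 0.7%) matching curated catalogues of
#'   the Ramilowski scale (~2500 pairs over ~700 ligands x ~600 receptors).
#' @param n_pairs number of random pairs to wire.
#' @param planted_pairs optional data.frame(ligand, receptor) always included;
#'   genes are added to the universes if needed.
#' @param seed integer seed.
#' @return data.frame(ligand, receptor, source) ready for [load_lr_database()].
#' @export
synthetic_lr_database <- function(gene_ids, n_ligands = 300L, n_receptors = 300L,
                                  n_pairs = 600L, planted_pairs = NULL, seed = 1L) {
  if (n_ligands + n_receptors > length(gene_ids)) stop("gene universe too small")
  set.seed(seed)
  picks <- sample(gene_ids, n_ligands + n_receptors)
  ligands <- picks[seq_len(n_ligands)]
  receptors <- picks[n_ligands + seq_len(n_receptors)]
  if (!is.null(planted_pairs)) {
    ligands <- unique(c(ligands, planted_pairs$ligand))
    receptors <- unique(c(receptors, planted_pairs$receptor))
  }
  pairs <- unique(data.frame(
    ligand = sample(ligands, n_pairs, replace = TRUE),
    receptor = sample(receptors, n_pairs, replace = TRUE),
    stringsAsFactors = FALSE
  ))
  pairs$source <- "synthetic"
  if (!is.null(planted_pairs)) {
    planted <- data.frame(ligand = planted_pairs$ligand,
                          receptor = planted_pairs$receptor,
                          source = "planted", stringsAsFactors = FALSE)
    pairs <- unique(rbind(planted, pairs))
  }
  rownames(pairs) <- NULL
  pairs
}
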