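# Small programmatic fixtures shared across test files.

# Hand-sized caf_matrix with explicit values (genes x cells).
tiny_matrix <- function(values, space = "rpkm", clusters = NULL, donors = NULL) {
  if (is.null(rownames(values))) rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("C%03d", seq_len(ncol(values)))
  n <- ncol(values)
  cell_meta <- data.frame(
    cell_id = colnames(values),
    donor = donors %||% rep("D01", n),
    sample = donors %||% rep("D01", n),
    lineage = "stromal",
    cluster = clusters %||% rep("A", n),
    stringsAsFactors = FALSE
  )
  gene_meta <- data.frame(
    gene_id = rownames(values),
    chrom = "chr1",
    start = (seq_len(nrow(values)) - 1L) * 1000L,
    end = (seq_len(nrow(values)) - 1L) * 1000L + 500L,
    stringsAsFactors = FALSE
  )
  caf_matrix(values, cell_meta, gene_meta, space = space)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-cluster atlas with CNV segments over 30% of a 2000-gene genome,
# used by CNV recovery tests.
cnv_test_config <- function(seed, n_per_donor = 90L) {
  segments <- data.frame(
    chrom = paste0("chr", 1:4), start_gene = 1L,
    length = c(200L, 200L, 100L, 100L), fold = c(1.5, 0.5, 1.5, 0.5)
  )
  sim_config(
    n_donors = 3L,
    clusters = list(list(name = "Tumor", n_cells_per_donor = n_per_donor),
                    list(name = "Fibroblast", n_cells_per_donor = n_per_donor)),
    n_genes = 2000L, n_chromosomes = 10L,
    cnv_segments = segments, malignant_cluster = "Tumor", seed = seed
  )
}

# 10-cell QC fixture with 3 planted violations: one too few genes, one too
# low a total, one too high. Manual rule application says exactly 7 survive.
qc_fixture <- function() {
  v <- matrix(0, 500L, 10)
  for (i in 1:10) {
    v[1:450, i] <- 200000 / 450  # 450 genes, total 200,000
  }
  v[421:450, 1] <- 0                      # cell 1: 420 >= 400 genes, still passes
  v[401:450, 2] <- 0; v[1:400, 2] <- 500  # cell 2: 400 genes, total 200,000
  v[, 3] <- 0; v[1:399, 3] <- 600         # cell 3: 399 genes -> low_genes
  v[, 4] <- v[, 4] * (100000 / 200000)    # cell 4: total 100,000 -> low_total
  v[, 5] <- v[, 5] * (9e6 / 200000)       # cell 5: total 9,000,000 -> high_total
  tiny_matrix(v)
}

# Log-normalized-space matrix with controllable per-gene means; for module
# score tests (values clipped at 0 to respect nonnegativity).
lognorm_test_matrix <- function(n_genes, n_cells, seed, gene_means = NULL,
                                sd = 0.3) {
  set.seed(seed)
  mu <- gene_means %||% stats::runif(n_genes, 0, 3)
  v <- pmax(matrix(mu, n_genes, n_cells) +
              matrix(stats::rnorm(n_genes * n_cells, 0, sd), n_genes), 0)
  tiny_matrix(v, space = "lognorm")
}
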