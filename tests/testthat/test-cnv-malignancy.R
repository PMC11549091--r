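test_that("genomic ordering sorts by chromosome then start, stable on ties", {
  gm <- data.frame(
    gene_id = c("B", "A", "C", "D", "E"),
    chrom = c("chr1", "chr1", "chr2", "chr1", "chr10"),
    start = c(100L, 50L, 10L, 100L, 5L)
  )
  ord <- order_genes_genomically(gm)
  expect_equal(ord$gene_id, c("A", "B", "D", "C", "E"))  # tie B/D by gene id
  expect_equal(vapply(ord$blocks, `[[`, character(1), "chrom"),
               c("chr1", "chr2", "chr10"))  # numeric chromosome rank
  gm$chrom[5] <- NA
  expect_warning(ord2 <- order_genes_genomically(gm), "without coordinates")
  expect_equal(ord2$dropped, "E")
  # all genes on one chromosome -> a single smoothing block
  gm1 <- data.frame(gene_id = letters[1:4], chrom = "chr3", start = 4:1 * 10L)
  expect_length(order_genes_genomically(gm1)$blocks, 1)
})

test_that("identical cells give all-zero CNV profiles (self-reference null)", {
  v <- matrix(rep(stats::rexp(60, 1 / 200), 8), 60, 8)
  mat <- lognormalize(tiny_matrix(v))
  prof <- infer_cnv_profiles(mat, reference_cells = sprintf("C%03d", 1:4),
                             min_cells_per_gene = 3L, window = 11L)
  expect_lt(max(abs(prof$profiles)), 1e-6)
})

test_that("lowly detected genes are dropped per min_cells_per_gene", {
  set.seed(1)
  v <- matrix(stats::rexp(400, 1 / 300), 40, 10)
  v[5, ] <- 0; v[5, 1:2] <- 100   # expressed in exactly 2 cells
  v[6, ] <- 0; v[6, 1:3] <- 100   # expressed in exactly 3 cells
  mat <- lognormalize(tiny_matrix(v))
  prof <- infer_cnv_profiles(mat, reference_cells = sprintf("C%03d", 1:5), window = 5L)
  expect_false("G005" %in% prof$gene_map$gene_id)
  expect_true("G006" %in% prof$gene_map$gene_id)
})

test_that("a planted gain lifts the CNV estimate inside the segment", {
  seg <- data.frame(chrom = "chr1", start_gene = 1L, length = 200L, fold = 1.5)
  cfg <- sim_config(
    n_donors = 2L,
    clusters = list(list(name = "Mal", n_cells_per_donor = 100L),
                    list(name = "Ref", n_cells_per_donor = 100L)),
    n_genes = 1000L, n_chromosomes = 5L, cnv_segments = seg,
    malignant_cluster = "Mal", seed = 21L
  )
  atlas <- generate_atlas(cfg)
  # 1000 genes put per-cell totals below the RPKM QC floor; QC is not under
  # test here, so normalize directly
  norm <- lognormalize(atlas$matrix)
  ref_cells <- norm$cell_meta$cell_id[norm$cell_meta$cluster == "Ref"]
  mal_cells <- norm$cell_meta$cell_id[norm$cell_meta$cluster == "Mal"]
  prof <- infer_cnv_profiles(norm, ref_cells)
  seg_pos <- which(prof$gene_map$chrom == "chr1")
  flank_pos <- which(prof$gene_map$chrom == "chr2")
  inside <- mean(prof$profiles[seg_pos, mal_cells])
  flank <- mean(prof$profiles[flank_pos, mal_cells])
  expect_gt(inside, 0)
  expect_gt(inside, flank + 0.05)
  # reference mean profile ~ 0 at every position
  expect_lt(max(abs(rowMeans(prof$profiles[, ref_cells]))), 0.05)
})

test_that("cnv_score equals the brute-force statistic exactly", {
  expect_equal(unname(cnv_score(rep(0, 10))), 0)
  expect_equal(unname(cnv_score(rep(0.3, 7))), 0.3^2, tolerance = 1e-12)
  set.seed(4)
  p <- matrix(stats::rnorm(50), 10, 5)
  brute <- apply(p, 2, function(x) sum(x^2) / length(x))
  expect_equal(unname(cnv_score(p)), unname(brute), tolerance = 1e-12)
  expect_equal(unname(cnv_score(p, raw_sum = TRUE)),
               unname(apply(p, 2, function(x) sum(x^2))), tolerance = 1e-12)
  expect_error(cnv_score(numeric(0)), "empty")
})

test_that("malignant reference profiles are per-sample with no cross-talk", {
  v <- matrix(stats::rexp(800, 1 / 100), 40, 20)
  mat <- lognormalize(tiny_matrix(v, donors = rep(c("S1", "S2"), each = 10)))
  prof <- infer_cnv_profiles(mat, reference_cells = sprintf("C%03d", 1:5), window = 7L)
  groups <- stats::setNames(mat$cell_meta$sample, mat$cell_meta$cell_id)
  ref <- malignant_reference_profile(prof, groups, top_fraction = 0.2)
  expect_equal(sort(colnames(ref)), c("S1", "S2"))
  sos <- cnv_score(prof)
  for (s in c("S1", "S2")) {
    ids <- names(groups)[groups == s]
    k <- floor(length(ids) * 0.2)
    top <- ids[order(sos[ids], decreasing = TRUE)[1:k]]
    expect_equal(ref[, s], rowMeans(prof$profiles[, top]), tolerance = 1e-12)
  }
  # tiny sample falls back to the single top cell, with a warning
  groups2 <- groups; groups2[1:3] <- "S3"; groups2[4:20] <- "S1"
  expect_warning(ref2 <- malignant_reference_profile(prof, groups2, 0.1),
                 "single top")
  expect_true("S3" %in% colnames(ref2))
})

test_that("quadrant classification follows the lineage cutoffs", {
  # keratinocyte cutoffs r 0.45 / SoS 0.017
  calls <- classify_malignancy(
    r = c(0.50, 0, 0.50, 0.44, 0.45),
    sos = c(0.020, 0, 0.010, 0.020, 0.017),
    lineage = "keratinocyte"
  )
  expect_equal(calls$call,
               c("CNV_plus", "CNV_minus", "undefined", "undefined", "CNV_plus"))
  # melanocyte cutoffs r 0.40 / SoS 0.026
  mel <- classify_malignancy(c(0.42, 0.42), c(0.020, 0.027), "melanocyte")
  expect_equal(mel$call, c("undefined", "CNV_plus"))
  # degenerate profiles (r := 0) can never be CNV_plus
  expect_equal(classify_malignancy(NaN, 0.5, "keratinocyte")$call, "undefined")
  expect_error(classify_malignancy(0.5, 0.02, "dendritic"), "lineage")
})

test_that("malignancy calls are invariant to global RPKM rescaling", {
  cfg <- cnv_test_config(seed = 31L, n_per_donor = 25L)
  atlas <- generate_atlas(cfg)
  run <- function(mat) {
    norm <- lognormalize(filter_cells(mat)$matrix)
    ref <- norm$cell_meta$cell_id[norm$cell_meta$cluster == "Fibroblast"]
    call_malignancy(norm, ref, lineage = "keratinocyte")$calls
  }
  calls1 <- run(atlas$matrix)
  scaled <- atlas$matrix
  scaled$values <- scaled$values * 3.7
  calls2 <- run(scaled)
  expect_equal(calls1, calls2, tolerance = 1e-12)
})

test_that("PTCH1/2 flagging applies the healthy mean + k*SD rule", {
  set.seed(9)
  v <- matrix(stats::rexp(600, 1 / 50), 20, 30)
  rownames(v) <- c("PTCH1", "PTCH2", sprintf("G%03d", 3:20))
  mat <- tiny_matrix(v, space = "rpkm")
  mat <- lognormalize(mat)
  healthy <- sprintf("C%03d", 1:20)
  cand <- sprintf("C%03d", 21:30)
  h1 <- mat$values["PTCH1", healthy]
  # plant: candidate 1 exactly at the healthy mean, candidate 2 at +3 SD
  mat$values["PTCH1", cand[1]] <- mean(h1)
  mat$values["PTCH2", cand[1]] <- mean(mat$values["PTCH2", healthy])
  mat$values["PTCH2", cand[2]] <- mean(mat$values["PTCH2", healthy]) +
    3 * stats::sd(mat$values["PTCH2", healthy])
  flags <- flag_ptch_high(mat, cand, healthy)
  expect_false(flags[[cand[1]]])
  expect_true(flags[[cand[2]]])
  # flagged fraction in the healthy cluster matches direct recomputation
  flags_h <- flag_ptch_high(mat, healthy, healthy)
  thr1 <- mean(h1) + 2 * stats::sd(h1)
  h2 <- mat$values["PTCH2", healthy]
  thr2 <- mean(h2) + 2 * stats::sd(h2)
  expect_equal(unname(flags_h), unname(h1 > thr1 | h2 > thr2))
  expect_error(flag_ptch_high(mat, cand, healthy, genes = c("GLI1", "GLI2")),
               "present")
})

test_that("null specificity: no planted CNVs, few CNV+ calls", {
  cfg <- sim_config(
    n_donors = 3L,
    clusters = list(list(name = "Tumor", n_cells_per_donor = 90L),
                    list(name = "Fibroblast", n_cells_per_donor = 90L)),
    n_genes = 2000L, n_chromosomes = 10L, seed = 41L
  )
  atlas <- generate_atlas(cfg)
  norm <- lognormalize(filter_cells(atlas$matrix)$matrix)
  ref <- norm$cell_meta$cell_id[norm$cell_meta$cluster == "Fibroblast"]
  calls <- call_malignancy(norm, ref, lineage = "keratinocyte")$calls
  expect_gte(nrow(calls), 500)
  expect_lte(mean(calls$call == "CNV_plus"), 0.05)
})

test_that("empty or invalid reference sets are rejected", {
  v <- matrix(stats::rexp(100, 1 / 100), 10, 10)
  mat <- lognormalize(tiny_matrix(v))
  expect_error(infer_cnv_profiles(mat, character(0)), "empty reference")
  expect_error(infer_cnv_profiles(mat, "nope"), "not in matrix")
  expect_error(infer_cnv_profiles(tiny_matrix(v), sprintf("C%03d", 1:3)),
               "log-normalized")
})
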