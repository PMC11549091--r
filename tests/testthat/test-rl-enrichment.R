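toy_db <- function() {
  load_lr_database(data.frame(
    ligand = c("L1", "L2", "L3"),
    receptor = c("R1", "R2", "R3"),
    source = "toy"
  ))
}

test_that("database loading deduplicates and merges source tags", {
  db <- suppressMessages(load_lr_database(data.frame(
    ligand = c("L1", "L1", "L2"),
    receptor = c("R1", "R1", "R2"),
    source = c("ramilowski", "lrdb", "lrdb")
  )))
  expect_equal(nrow(db$pairs), 2)
  expect_equal(db$pairs$source[db$pairs$ligand == "L1"], "lrdb;ramilowski")
  expect_setequal(db$ligands, c("L1", "L2"))
  expect_error(load_lr_database(data.frame(a = 1)), "ligand")
  expect_error(load_lr_database(data.frame(ligand = character(0),
                                           receptor = character(0))), "empty")
})

test_that("candidate pairs are directional", {
  db <- toy_db()
  expect_equal(nrow(candidate_pairs(c("L1"), c("R1"), db)), 1)
  # ligand present only in the target signature: no pair for this direction
  expect_equal(nrow(candidate_pairs(c("R1"), c("L1"), db)), 0)
  expect_equal(nrow(candidate_pairs(character(0), c("R1"), db)), 0)
  sig <- data.frame(gene = c("L1", "L2"))
  expect_equal(nrow(candidate_pairs(sig, data.frame(gene = c("R1", "R2")), db)), 2)
})

test_that("donor co-presence requires >= 2.5% of the same donor in both clusters", {
  meta <- data.frame(
    cell_id = sprintf("C%03d", 1:200),
    donor = c(rep("X", 10), rep("Y", 90), rep("X", 5), rep("Z", 95)),
    cluster = rep(c("A", "B"), each = 100)
  )
  expect_true(donor_copresence(meta, "A", "B"))    # X: 10% of A, 5% of B
  meta$donor[101:105] <- "Z"
  meta$donor[101:102] <- "X"                        # X now 2% of B, only shared donor
  expect_false(donor_copresence(meta, "A", "B", min_frac = 0.025))
  # boundary: exactly 2.5% in both passes
  meta2 <- data.frame(
    cell_id = sprintf("c%03d", 1:80),
    donor = c(rep("X", 1), rep("Y", 39), rep("X", 1), rep("Z", 39)),
    cluster = rep(c("A", "B"), each = 40)
  )
  expect_true(donor_copresence(meta2, "A", "B"))   # 1/40 = 2.5%
  meta3 <- meta
  meta3$donor <- rep(c("P", "Q"), each = 100)      # disjoint donors
  expect_false(donor_copresence(meta3, "A", "B"))
  expect_error(donor_copresence(meta, "A", "Nope"), "empty cluster")
})

test_that("permutation null: degenerate and saturated cases", {
  db <- toy_db()
  expect_equal(permutation_enrichment(0, 1, 1, db, n_perm = 50, seed = 1),
               1)
  # complete bipartite 2x2 with pools = whole universes: every count = 4
  full <- load_lr_database(expand.grid(ligand = c("L1", "L2"),
                                       receptor = c("R1", "R2"),
                                       stringsAsFactors = FALSE))
  expect_equal(permutation_enrichment(4, 2, 2, full, n_perm = 100, seed = 1), 1)
  expect_error(permutation_enrichment(1, 5, 1, db, seed = 1), "universe")
  # add-one estimator keeps p > 0 even for unreachable observed counts
  p <- permutation_enrichment(99, 1, 1, db, n_perm = 200, seed = 1)
  expect_equal(p, 1 / 201)
})

test_that("empirical p matches exhaustive enumeration on the 1/9 toy null", {
  db <- toy_db()  # only (L1,R1) exists among 3x3 single-gene pools
  db$pairs <- db$pairs[1, , drop = FALSE]
  p_exact <- 1 / 9
  n_perm <- 2000
  p_hat <- permutation_enrichment(1, 1, 1, db, n_perm = n_perm, seed = 77)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(p_hat - p_exact), 3 * se)
})

test_that("p is monotone non-increasing in the observed count", {
  db <- load_lr_database(data.frame(
    ligand = sample(sprintf("L%02d", 1:20), 60, replace = TRUE),
    receptor = sample(sprintf("R%02d", 1:20), 60, replace = TRUE)
  ))
  ps <- vapply(0:6, function(k)
    permutation_enrichment(k, 5, 5, db, n_perm = 500, seed = 5), numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("replicates are counter-seeded: chunking never changes results", {
  db <- toy_db()
  full <- permutation_enrichment(1, 2, 2, db, n_perm = 400, seed = 9,
                                 replicates = 1:400)
  chunked <- c(
    permutation_enrichment(1, 2, 2, db, n_perm = 400, seed = 9, replicates = 1:153),
    permutation_enrichment(1, 2, 2, db, n_perm = 400, seed = 9, replicates = 154:400)
  )
  expect_identical(full, chunked)
  p <- permutation_enrichment(1, 2, 2, db, n_perm = 400, seed = 9)
  expect_equal(p, (1 + sum(full >= 1)) / 401)
})

test_that("run_rl_analysis honours the donor prerequisite and BH family", {
  meta <- data.frame(
    cell_id = sprintf("C%03d", 1:120),
    donor = c(rep("d1", 40), rep("d2", 40), rep("d3", 40)),
    cluster = rep(c("A", "B", "C"), times = c(40, 40, 40))
  )
  db <- toy_db()
  sigs <- list(A = c("L1", "R2"), B = c("R1", "L2"), C = c("L3", "R3"))
  res <- run_rl_analysis(meta, sigs, db, n_perm = 200, seed = 3)
  expect_s3_class(res, "interaction_result")
  expect_equal(nrow(res), 6)  # ordered pairs of 3 clusters
  # disjoint donors everywhere: no pair testable, rows still present
  expect_false(any(res$donor_ok))
  expect_true(all(is.na(res$p)) && all(is.na(res$q)))

  # shared donors: tested pairs get p and one BH family across them
  meta$donor <- rep(c("d1", "d2"), 60)
  res2 <- run_rl_analysis(meta, sigs, db, n_perm = 200, seed = 3)
  expect_true(all(res2$donor_ok))
  expect_equal(res2$q, bh_adjust(res2$p))
  expect_true(all(res2$q >= res2$p, na.rm = TRUE))
  ab <- res2[res2$source == "A" & res2$target == "B", ]
  expect_equal(ab$n_obs, 1)  # L1 (A) -> R1 (B)
  expect_equal(ab$pairs, "L1:R1")
  # determinism under a fixed seed
  res3 <- run_rl_analysis(meta, sigs, db, n_perm = 200, seed = 3)
  expect_identical(res2, res3)

  # BH with m = 1 leaves p untouched (donor gating is symmetric, so a
  # one-pair family is exercised directly)
  expect_equal(bh_adjust(res2$p[1]), res2$p[1])
})

test_that("null calibration of the permutation test is near-nominal", {
  # signatures drawn uniformly from the database universes, no structure
  set.seed(123)
  db <- load_lr_database(synthetic_lr_database(sprintf("G%05d", 1:2000),
    n_ligands = 300, n_receptors = 300, n_pairs = 1000, seed = 42))
  ps <- vapply(1:60, function(i) {
    nl <- sample(15:40, 1); nr <- sample(15:40, 1)
    ls <- sample(db$ligands, nl); rs <- sample(db$receptors, nr)
    n_obs <- sum(db$pairs$ligand %in% ls & db$pairs$receptor %in% rs)
    permutation_enrichment(n_obs, nl, nr, db, n_perm = 500, seed = 5000 + i)
  }, numeric(1))
  expect_gt(mean(ps <= 0.05), 0.0)   # sanity: not degenerate at 0/1
  expect_lt(mean(ps <= 0.05), 0.15)  # loose unit-level bound; tight one in acceptance
})
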