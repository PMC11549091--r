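#' Load a ligand-receptor pair database
#'
#' Reads a Ramilowski/LRdb-style table with `ligand` and `receptor` columns
#' (an optional `source` column tags provenance). Duplicate pairs are merged,
#' concatenating their source tags; the ligand and receptor universes are the
#' distinct genes playing each role (a gene may appear in both).
#'
#' @param table a CSV path or a data.frame.
#' @return object of class `lr_database`: list with `pairs` (data.frame
#'   ligand, receptor, source), `ligands`, `receptors`.
#' @export
load_lr_database <- function(table) {
  df <- if (is.character(table)) {
    if (!file.exists(table)) stop("ligand-receptor database not found: ", table)
    utils::read.csv(table, stringsAsFactors = FALSE)
  } else as.data.frame(table, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(df))) {
    stop("ligand-receptor table must have 'ligand' and 'receptor' columns; got: ",
         paste(names(df), collapse = ", "))
  }
  if (!nrow(df)) stop("ligand-receptor table is empty")
  if (!"source" %in% names(df)) df$source <- "unspecified"
  key <- paste(df$ligand, df$receptor, sep = "\r")
  src <- vapply(split(df$source, key), function(s)
    paste(sort(unique(s)), collapse = ";"), character(1))
  first <- !duplicated(key)
  pairs <- data.frame(ligand = df$ligand[first], receptor = df$receptor[first],
                      source = unname(src[key[first]]), stringsAsFactors = FALSE)
  n_dup <- nrow(df) - nrow(pairs)
  if (n_dup > 0) message(n_dup, " duplicate pair(s) merged")
  structure(list(pairs = pairs,
                 ligands = unique(pairs$ligand),
                 receptors = unique(pairs$receptor)),
            class = "lr_database")
}

#' @export
print.lr_database <- function(x, ...) {
  cat(sprintf("lr_database: %d pairs, %d ligands, %d receptors\n",
              nrow(x$pairs), length(x$ligands), length(x$receptors)))
  invisible(x)
}

#' Candidate ligand-receptor pairs for a directed cluster pair
#'
#' Database pairs whose ligand lies in the source cluster's signature and
#' whose receptor lies in the target cluster's signature (directional).
#'
#' @param sig_source,sig_target `signature_set` data.frames (or plain gene
#'   id vectors).
#' @param db an `lr_database`.
#' @return data.frame(ligand, receptor); zero rows when nothing matches.
#' @export
candidate_pairs <- function(sig_source, sig_target, db) {
  stopifnot(inherits(db, "lr_database"))
  gs <- signature_genes(sig_source)
  gt <- signature_genes(sig_target)
  hit <- db$pairs$ligand %in% gs & db$pairs$receptor %in% gt
  db$pairs[hit, c("ligand", "receptor"), drop = FALSE]
}

signature_genes <- function(sig) {
  if (is.character(sig)) sig else sig$gene
}

#' Donor co-presence prerequisite for a cluster pair
#'
#' A cluster pair is testable only when at least one donor contributes at
#' least `min_frac` (default 2.5%) of the cells of *both* clusters.
#'
#' @param cell_meta data.frame with `cell_id`, `donor`, `cluster`.
#' @param cluster_a,cluster_b cluster labels.
#' @param min_frac minimum shared-donor fraction in each cluster.
#' @return TRUE/FALSE.
#' @export
donor_copresence <- function(cell_meta, cluster_a, cluster_b, min_frac = 0.025) {
  a <- cell_meta$donor[cell_meta$cluster == cluster_a]
  b <- cell_meta$donor[cell_meta$cluster == cluster_b]
  if (!length(a) || !length(b)) {
    stop("empty cluster: ", if (!length(a)) cluster_a else cluster_b)
  }
  fa <- table(a) / length(a)
  fb <- table(b) / length(b)
  shared <- intersect(names(fa)[fa >= min_frac], names(fb)[fb >= min_frac])
  length(shared) > 0
}

#' Permutation test for ligand-receptor pair enrichment
#'
#' Null model: each replicate draws a ligand pool and receptor pool of the
#' same sizes as the observed signature contributes to each database
#' universe, uniformly without replacement from those universes, and counts
#' the database pairs the random pools form. The empirical p-value uses the
#' add-one estimator `(1 + #{count >= n_obs}) / (n_perm + 1)`, so p > 0
#' always. Replicates are seeded individually from a counter-based stream,
#' making results independent of how the replicate loop is chunked.
#'
#' @param n_obs observed candidate-pair count.
#' @param n_ligands,n_receptors pool sizes (observed signature sizes within
#'   each universe).
#' @param db an `lr_database`.
#' @param n_perm permutation replicates (published choice: 10,000).
#' @param seed integer seed.
#' @param replicates optional integer subset of replicate indices (worker
#'   chunking); results concatenate exactly.
#' @return when `replicates` is NULL, the empirical p-value; otherwise the
#'   integer vector of per-replicate null counts.
#' @export
permutation_enrichment <- function(n_obs, n_ligands, n_receptors, db,
                                   n_perm = 10000L, seed, replicates = NULL) {
  stopifnot(inherits(db, "lr_database"))
  if (missing(seed)) stop("seed is required")
  if (n_ligands > length(db$ligands) || n_receptors > length(db$receptors)) {
    stop("pool size exceeds database universe (",
         n_ligands, " ligands of ", length(db$ligands), "; ",
         n_receptors, " receptors of ", length(db$receptors), ")")
  }
  idx <- replicates %||% seq_len(n_perm)
  pl <- db$pairs$ligand
  pr <- db$pairs$receptor
  counts <- vapply(idx, function(i) {
    set.seed(replicate_seed(seed, i))
    ls <- sample(db$ligands, n_ligands)
    rs <- sample(db$receptors, n_receptors)
    sum(pl %in% ls & pr %in% rs)
  }, integer(1))
  if (!is.null(replicates)) return(counts)
  (1 + sum(counts >= n_obs)) / (n_perm + 1)
}

#' Full receptor-ligand enrichment analysis across cluster pairs
#'
#' For every ordered cluster pair with signatures: check the donor
#' co-presence prerequisite, collect candidate pairs, compute the permutation
#' p, then Benjamini-Hochberg-correct across all tested pairs in one family.
#' Pairs failing the prerequisite are reported with `donor_ok = FALSE` and no
#' p/q. Significance is flagged at `q <= alpha`.
#'
#' @param cell_meta data.frame with cell_id, donor, cluster.
#' @param signatures named list (cluster -> `signature_set` or gene vector).
#' @param db an `lr_database`.
#' @param n_perm permutation replicates per pair (default 10,000).
#' @param alpha BH significance level (default 0.05).
#' @param seed integer seed; pair-specific seeds derive from it and the
#'   pair's position in the fixed (sorted) pair ordering.
#' @param min_frac donor co-presence threshold (default 0.025).
#' @return data.frame of class `interaction_result`: source, target,
#'   n_ligands, n_receptors, n_obs, donor_ok, p, q, significant, pairs
#'   (semicolon-joined "L:R").
#' @export
run_rl_analysis <- function(cell_meta, signatures, db, n_perm = 10000L,
                            alpha = 0.05, seed, min_frac = 0.025) {
  stopifnot(inherits(db, "lr_database"))
  if (missing(seed)) stop("seed is required")
  cls <- sort(names(signatures))
  if (length(cls) < 2L) stop("need signatures for at least 2 clusters")
  grid <- expand.grid(source = cls, target = cls, stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, , drop = FALSE]
  grid <- grid[order(grid$source, grid$target), , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$source[i]; t <- grid$target[i]
    ok <- donor_copresence(cell_meta, s, t, min_frac = min_frac)
    cand <- candidate_pairs(signatures[[s]], signatures[[t]], db)
    n_l <- length(intersect(signature_genes(signatures[[s]]), db$ligands))
    n_r <- length(intersect(signature_genes(signatures[[t]]), db$receptors))
    p <- if (ok) {
      permutation_enrichment(nrow(cand), n_l, n_r, db, n_perm = n_perm,
                             seed = replicate_seed(seed, i))
    } else NA_real_
    data.frame(
      source = s, target = t, n_ligands = n_l, n_receptors = n_r,
      n_obs = nrow(cand), donor_ok = ok, p = p,
      pairs = paste(paste(cand$ligand, cand$receptor, sep = ":"),
                    collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  if (any(tested)) out$q[tested] <- bh_adjust(out$p[tested])
  out$significant <- !is.na(out$q) & out$q <= alpha
  out <- out[, c("source", "target", "n_ligands", "n_receptors", "n_obs",
                 "donor_ok", "p", "q", "significant", "pairs")]
  class(out) <- c("interaction_result", "data.frame")
  out
}
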