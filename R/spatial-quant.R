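#' Phenotype cells from marker-positivity calls
#'
#' Applies the in situ marker combinations: total CAFs are COL1A1+, iCAFs are
#' COL1A1+ MMP1+, mCAFs are COL1A1+ COL11A1+ MMP1-. iCAF and mCAF are
#' mutually exclusive by construction, and every iCAF/mCAF is also a total
#' CAF. Cells positive for none are labelled `none`.
#'
#' @param marker_calls data.frame with logical columns `COL1A1`, `MMP1`,
#'   `COL11A1` (one row per cell); missing values are an error.
#' @return data.frame with logical columns totalCAF, iCAF, mCAF, none
#'   appended to the input.
#' @export
phenotype_cells <- function(marker_calls) {
  need <- c("COL1A1", "MMP1", "COL11A1")
  missing <- setdiff(need, names(marker_calls))
  if (length(missing)) stop("missing marker call column(s): ",
                            paste(missing, collapse = ", "))
  for (m in need) {
    if (anyNA(marker_calls[[m]]) || !is.logical(marker_calls[[m]])) {
      stop("marker column ", m, " must be logical with no missing calls")
    }
  }
  out <- marker_calls
  out$totalCAF <- out$COL1A1
  out$iCAF <- out$COL1A1 & out$MMP1
  out$mCAF <- out$COL1A1 & out$COL11A1 & !out$MMP1
  out$none <- !out$totalCAF
  out
}

#' Aggregate ROI counts to a per-sample density
#'
#' Pooled-count density: the sample's counts are summed across its ROIs and
#' divided by the summed tissue area (cells/mm^2) — not a mean of per-ROI
#' ratios. At least five representative ROIs per sample are required.
#'
#' @param roi_table ROI data.frame (see [generate_roi_table()]): sample_id,
#'   tumor_class, roi_id, area_mm2 and one count column per phenotype.
#' @param sample_id the sample to aggregate.
#' @param phenotype name of the count column.
#' @return list: sample_id, tumor_class, phenotype, density, n_rois.
#' @export
aggregate_density <- function(roi_table, sample_id, phenotype) {
  rows <- roi_table[roi_table$sample_id == sample_id, , drop = FALSE]
  if (!nrow(rows)) stop("unknown sample: ", sample_id)
  if (nrow(rows) < 5L) {
    stop("sample ", sample_id, " has ", nrow(rows),
         " ROIs; a minimum of five representative ROIs is required")
  }
  if (!phenotype %in% names(rows)) stop("no count column for phenotype ", phenotype)
  if (any(rows$area_mm2 <= 0)) stop("nonpositive ROI area in sample ", sample_id)
  total_area <- sum(rows$area_mm2)
  list(sample_id = sample_id,
       tumor_class = rows$tumor_class[1],
       phenotype = phenotype,
       density = sum(rows[[phenotype]]) / total_area,
       n_rois = nrow(rows))
}

#' Per-sample densities for all samples and phenotypes
#'
#' @param roi_table ROI data.frame.
#' @param phenotypes count columns to aggregate (default: the standard CAF
#'   phenotypes present in the table).
#' @return data.frame: sample_id, tumor_class, phenotype, density, n_rois.
#' @export
aggregate_densities <- function(roi_table,
                                phenotypes = intersect(c("totalCAF", "iCAF", "mCAF"),
                                                       names(roi_table))) {
  samples <- unique(roi_table$sample_id)
  rows <- list()
  for (s in samples) for (ph in phenotypes) {
    rows[[length(rows) + 1L]] <- as.data.frame(
      aggregate_density(roi_table, s, ph), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Compare per-sample densities between two tumor classes
#'
#' Two-sided Mann-Whitney test on per-sample densities: exact enumeration up
#' to 8 samples per class, tie-corrected normal approximation beyond.
#'
#' @param densities data.frame from [aggregate_densities()].
#' @param class_a,class_b tumor-class labels.
#' @param phenotype which phenotype's densities to compare.
#' @return list: `U` (Mann-Whitney U for class_a), `p` (two-sided), `n_a`,
#'   `n_b`, `exact`.
#' @export
compare_classes <- function(densities, class_a, class_b, phenotype) {
  d <- densities[densities$phenotype == phenotype, , drop = FALSE]
  a <- d$density[d$tumor_class == class_a]
  b <- d$density[d$tumor_class == class_b]
  if (length(a) < 3L || length(b) < 3L) {
    stop("need at least 3 samples per class (",
         class_a, ": ", length(a), ", ", class_b, ": ", length(b), ")")
  }
  res <- rank_sum_test(a, b, exact_limit = 8L)
  list(U = res$statistic, p = res$p, n_a = length(a), n_b = length(b),
       exact = res$exact)
}

#' T-cell exclusion log-log regression
#'
#' Ordinary least squares of `log10(cd3 + pseudocount)` on
#' `log10(caf + pseudocount)` over paired per-ROI (or per-sample) densities.
#' A negative slope quantifies exclusion of CD3+ cells from tumor nests with
#' increasing CAF density.
#'
#' @param cd3_density response densities (cells/mm^2).
#' @param caf_density predictor densities (cells/mm^2), same length.
#' @param pseudocount added before the log (default 1 cell/mm^2).
#' @return list: slope, intercept, r_squared, n.
#' @export
exclusion_regression <- function(cd3_density, caf_density, pseudocount = 1) {
  if (length(cd3_density) != length(caf_density)) stop("length mismatch")
  if (length(cd3_density) < 3L) stop("need at least 3 points")
  x <- log10(caf_density + pseudocount)
  y <- log10(cd3_density + pseudocount)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("nonpositive density + pseudocount produced non-finite logs")
  }
  if (stats::var(x) == 0) stop("zero variance in predictor")
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r_squared = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot,
       n = length(x))
}

#' Stratify by CAF density and compare log CD3 densities
#'
#' Splits observations into high/low CAF strata at `cutoff` (inclusive on the
#' high side: density >= cutoff is high; published cutoffs are 140 cells/mm^2
#' for total CAFs and 40 cells/mm^2 for mCAFs/iCAFs) and compares
#' `log10(cd3 + pseudocount)` between strata with an unpaired two-sided
#' t-test (Welch by default).
#'
#' @param cd3_density,caf_density paired densities.
#' @param cutoff high/low CAF cutoff in cells/mm^2 (> 0).
#' @param var_equal pooled-variance t-test instead of Welch.
#' @param pseudocount added before the log (default 1).
#' @return list: high (logical per observation), n_high, n_low, t, p,
#'   mean_log_cd3_high, mean_log_cd3_low.
#' @export
stratify_high_low <- function(cd3_density, caf_density, cutoff,
                              var_equal = FALSE, pseudocount = 1) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (length(cd3_density) != length(caf_density)) stop("length mismatch")
  high <- caf_density >= cutoff
  if (!any(high) || all(high)) {
    stop("empty stratum at cutoff ", cutoff, ": ", sum(high), " high / ",
         sum(!high), " low")
  }
  y <- log10(cd3_density + pseudocount)
  tt <- stats::t.test(y[high], y[!high], var.equal = var_equal)
  list(high = high, n_high = sum(high), n_low = sum(!high),
       t = unname(tt$statistic), p = tt$p.value,
       mean_log_cd3_high = mean(y[high]), mean_log_cd3_low = mean(y[!high]))
}
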