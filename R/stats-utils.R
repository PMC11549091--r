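#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false discovery rate correction with monotonicity enforcement.
#' Implemented directly (sort, scale by m/rank, running minimum from the
#' largest p down) so it can be checked against textbook oracles.
#'
#' @param p numeric vector of raw p-values, each in (0, 1].
#' @return numeric vector of q-values, same order as `p`, each `<= 1` and
#'   `>=` its raw p.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1] with no missing values")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p[o]))
  q[order(o)]
}

#' Two-sample Wilcoxon / Mann-Whitney rank-sum test
#'
#' Exact enumeration of the permutation null when both groups are small
#' (handles ties correctly, unlike the classical exact tables); otherwise a
#' tie-corrected normal approximation with continuity correction. The exact
#' two-sided p is `2 * min(lower tail, upper tail)` of the rank-sum over all
#' choose(nx+ny, nx) group assignments, capped at 1.
#'
#' @param x,y numeric vectors (the two groups).
#' @param exact_limit use exact enumeration when both groups have at most
#'   this many observations.
#' @return list with `statistic` (Mann-Whitney U for `x`), `statistic_centered`
#'   (U minus its null mean, sign-flips under label swap), `p` (two-sided)
#'   and `exact` (logical).
#' @export
rank_sum_test <- function(x, y, exact_limit = 10L) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  if (anyNA(x) || anyNA(y)) stop("missing values not supported")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2
  if (nx <= exact_limit && ny <= exact_limit) {
    combs <- utils::combn(n, nx)
    stats <- colSums(matrix(r[combs], nrow = nx))
    p <- min(1, 2 * min(mean(stats <= W), mean(stats >= W)))
    exact <- TRUE
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    sigma2 <- (nx * ny / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    exact <- FALSE
  }
  list(statistic = U, statistic_centered = U - nx * ny / 2, p = p, exact = exact)
}

# Centered moving average with edge truncation, column-wise over a matrix.
# Windows never extend past the first/last row; edge positions average over
# the rows actually available.
smooth_columns <- function(m, window) {
  n <- nrow(m)
  if (window > n) window <- n
  h <- (window - 1L) %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  cs <- rbind(0, matrixStats::colCumsums(m))
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

# Deterministic per-replicate seed stream: independent of how replicates are
# chunked across workers (counter-based, one seed per replicate index).
replicate_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}
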