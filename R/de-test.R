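# Differential expression for digital (count-based) expression data:
# the log-likelihood-ratio R statistic across sequencing libraries under a
# Poisson model, p-value calibration, Benjamini-Hochberg FDR, the tables'
# fold-change convention, and the combined calling rule (FDR <= 0.01 and
# fold change >= 3).

#' The R statistic for digital gene expression
#'
#' For counts `x_i` in libraries of total size `N_i`, with pooled proportion
#' `f = sum(x) / sum(N)`, the statistic is
#' `R = sum over x_i > 0 of x_i * log(x_i / (N_i * f))` (natural log).
#' It is the log-likelihood ratio comparing per-library Poisson rates to a
#' shared rate, so `2R` is asymptotically chi-square with `m - 1` degrees of
#' freedom under the null of equal proportions across `m` libraries.
#'
#' @param x Nonnegative integer counts, one per library (length >= 2).
#' @param N Positive library totals, same length as `x`.
#' @return The statistic `R >= 0`; zero-count libraries contribute 0, and
#'   `R = 0` when `sum(x) = 0`.
#' @examples
#' r_statistic(c(5, 50), c(1e6, 1e6))
#' @export
r_statistic <- function(x, N) {
  if (length(x) != length(N) || length(x) < 2L) {
    stop("x and N must have equal length >= 2", call. = FALSE)
  }
  if (any(x < 0)) stop("negative counts are invalid", call. = FALSE)
  if (any(N <= 0)) stop("library totals must be positive", call. = FALSE)
  if (sum(x) == 0) return(0)
  f <- sum(x) / sum(N)
  pos <- x > 0
  R <- sum(x[pos] * log(x[pos] / (N[pos] * f)))
  max(R, 0)  # guard against tiny negative round-off
}

#' P-value for the R statistic
#'
#' Under `method = "chi2"` the p-value is the upper tail of a chi-square
#' distribution with `m - 1` degrees of freedom evaluated at `2R`
#' (asymptotically exact for the Poisson model). Under `method =
#' "bootstrap"` counts are resampled as Poisson draws under the pooled rate
#' and `p = (1 + #(R* >= R)) / (n_boot + 1)`, which is preferable for very
#' low counts.
#'
#' @param R The observed statistic.
#' @param m Number of libraries (>= 2).
#' @param method `"chi2"` or `"bootstrap"`.
#' @param x,N Counts and library totals (required for bootstrap).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return A p-value in `[0, 1]`.
#' @export
p_from_r <- function(R, m = 2L, method = c("chi2", "bootstrap"),
                     x = NULL, N = NULL, n_boot = 10000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(m >= 2L, R >= 0)
  if (method == "chi2") {
    return(stats::pchisq(2 * R, df = m - 1L, lower.tail = FALSE))
  }
  if (is.null(x) || is.null(N)) {
    stop("bootstrap calibration requires x and N", call. = FALSE)
  }
  if (n_boot <= 0) stop("n_boot must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  f <- sum(x) / sum(N)
  rstar <- vapply(seq_len(n_boot), function(i) {
    r_statistic(stats::rpois(length(N), lambda = f * N), N)
  }, numeric(1))
  (1 + sum(rstar >= R)) / (n_boot + 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min over j >= i of min(1, p_(j) * m / j)`, mapped back to the
#' input order. Delegates to [stats::p.adjust()] after input validation.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted values `q`, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Fold change with the zero-denominator table convention
#'
#' Ratio of test to reference expression (green/white orientation). When the
#' reference is 0 and the test positive, the reported ratio equals the test
#' value itself (a unit denominator) — the convention used in published
#' RPKM ratio tables; when both are 0 the ratio is 1.
#'
#' @param test_rpkm,ref_rpkm Nonnegative expression values (vectorized).
#' @return Positive fold changes.
#' @examples
#' fold_change(320, 50.6)   # 6.32411...
#' fold_change(23.1, 0)     # 23.1 by the zero-denominator convention
#' @export
fold_change <- function(test_rpkm, ref_rpkm) {
  if (any(test_rpkm < 0) || any(ref_rpkm < 0)) {
    stop("expression values must be >= 0", call. = FALSE)
  }
  ifelse(ref_rpkm > 0, test_rpkm / ref_rpkm,
         ifelse(test_rpkm > 0, test_rpkm, 1))
}

#' Call differentially expressed unigenes
#'
#' Computes the R statistic and p-value for every unigene with nonzero total
#' count, adjusts p-values by Benjamini-Hochberg over that batch, computes
#' RPKM fold changes (test/reference), and calls a unigene `up` when
#' `q <= fdr_max` and `fold >= min_fold`, `down` when `q <= fdr_max` and
#' `fold <= 1/min_fold`, else `none`.
#'
#' @param ct A `count_table` with exactly two libraries.
#' @param fdr_max FDR threshold (default 0.01).
#' @param min_fold Fold-change threshold (default 3).
#' @param test,reference Library (column) names of the test and reference
#'   conditions; defaults: column 2 is the test (green), column 1 the
#'   reference (white).
#' @param p_method Passed to [p_from_r()].
#' @param n_boot,seed Bootstrap controls (when `p_method = "bootstrap"`).
#' @return A tibble (`unigene_id`, `count_ref`, `count_test`, `rpkm_ref`,
#'   `rpkm_test`, `R`, `p`, `q`, `fold`, `call`), one row per unigene
#'   (untested all-zero unigenes carry `NA` statistics and call `none`),
#'   with attribute `summary` — a list with `n_tested`, `n_up`, `n_down`,
#'   `pct_up`, `pct_down` (percentages of all unigenes, 2 decimals).
#' @export
call_de <- function(ct, fdr_max = 0.01, min_fold = 3,
                    test = NULL, reference = NULL,
                    p_method = c("chi2", "bootstrap"),
                    n_boot = 10000L, seed = 1L) {
  stopifnot(inherits(ct, "count_table"))
  p_method <- match.arg(p_method)
  stopifnot(fdr_max > 0, fdr_max <= 1, min_fold >= 1)
  cn <- colnames(ct$counts)
  if (length(cn) != 2L) stop("call_de expects exactly two libraries", call. = FALSE)
  reference <- reference %||% cn[1]
  test <- test %||% cn[2]
  stopifnot(test %in% cn, reference %in% cn, test != reference)

  counts <- ct$counts[, c(reference, test), drop = FALSE]
  N <- ct$library_sizes[c(reference, test)]
  rpkm <- compute_rpkm(ct)[, c(reference, test), drop = FALSE]

  total <- rowSums(counts)
  tested <- total > 0
  Rv <- rep(NA_real_, nrow(counts))
  pv <- rep(NA_real_, nrow(counts))
  if (any(tested)) {
    Rv[tested] <- apply(counts[tested, , drop = FALSE], 1L,
                        function(x) r_statistic(x, N))
    if (p_method == "chi2") {
      pv[tested] <- stats::pchisq(2 * Rv[tested], df = 1L, lower.tail = FALSE)
    } else {
      idx <- which(tested)
      pv[idx] <- vapply(seq_along(idx), function(j) {
        p_from_r(Rv[idx[j]], m = 2L, method = "bootstrap",
                 x = counts[idx[j], ], N = N, n_boot = n_boot,
                 seed = child_seed(seed, "de") + j)
      }, numeric(1))
    }
  }
  qv <- rep(NA_real_, nrow(counts))
  qv[tested] <- bh_fdr(pv[tested])

  fold <- fold_change(rpkm[, test], rpkm[, reference])
  call <- rep("none", nrow(counts))
  sig <- tested & !is.na(qv) & qv <= fdr_max
  call[sig & fold >= min_fold] <- "up"
  call[sig & fold <= 1 / min_fold] <- "down"

  out <- tibble::tibble(unigene_id = rownames(counts),
                        count_ref = counts[, reference],
                        count_test = counts[, test],
                        rpkm_ref = rpkm[, reference],
                        rpkm_test = rpkm[, test],
                        R = Rv, p = pv, q = qv, fold = fold, call = call)
  n_total <- nrow(out)
  attr(out, "summary") <- list(
    n_total = n_total,
    n_tested = sum(tested),
    n_up = sum(call == "up"),
    n_down = sum(call == "down"),
    pct_up = de_percent(sum(call == "up"), n_total),
    pct_down = de_percent(sum(call == "down"), n_total))
  out
}

#' Percentage of calls among all unigenes, to two decimals
#'
#' @param n_calls,n_total Counts.
#' @return `round(100 * n_calls / n_total, 2)`.
#' @examples
#' de_percent(4436, 118000)  # 3.76
#' @export
de_percent <- function(n_calls, n_total) {
  stopifnot(n_total > 0, n_calls >= 0)
  round(100 * n_calls / n_total, 2)
}
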