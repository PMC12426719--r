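#' Two-sided Mann-Whitney U test with rank-biserial effect size
#'
#' Rank test for a difference between two independent samples. The
#' statistic reported is \eqn{U = \#\{x > y\} + \tfrac12 \#\{x = y\}}
#' over all pairs. For small samples without ties
#' (`n1 + n2 <= exact_limit`) the exact permutation distribution is
#' used; otherwise the normal approximation with continuity and tie
#' correction. The effect size is the rank-biserial correlation
#' \eqn{r = |1 - 2U/(n_1 n_2)|}; the signed value (positive when `x`
#' tends to exceed `y`) is kept alongside.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param label Comparison label carried into reports.
#' @param exact_limit Largest `n1 + n2` for which the exact distribution
#'   is used (ties force the approximation). Default 12.
#' @return A `test_result` list: `test_name`, `label`, `statistic` (U),
#'   `p_raw`, `effect_size` (|r|), `effect_signed`, `n1`, `n2`.
#' @export
mann_whitney <- function(x, y, label = "x vs y", exact_limit = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples contain missing values")
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2  # pairs x>y (+ half ties)
  if (max(c(x, y)) == min(c(x, y))) {
    # degenerate: every observation identical, no evidence either way
    return(test_result("mann_whitney", label, statistic = u, p_raw = 1,
                       effect_size = 0, effect_signed = 0, n1 = n1, n2 = n2))
  }
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 + n2) <= exact_limit && !has_ties
  p <- stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                          correct = TRUE)$p.value
  r_signed <- 2 * u / (n1 * n2) - 1
  test_result("mann_whitney", label, statistic = u, p_raw = p,
              effect_size = abs(r_signed), effect_signed = r_signed,
              n1 = n1, n2 = n2)
}

#' Two-sided t-test for a mean difference
#'
#' Welch's unequal-variance t-test by default; Student's pooled-variance
#' test via `var_equal = TRUE`. Cohen's d (pooled SD) is reported as
#' effect size.
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @param label Comparison label.
#' @param var_equal Assume equal variances (Student's test).
#' @return A `test_result` list (statistic is t).
#' @export
welch_t <- function(x, y, label = "x vs y", var_equal = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per sample")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("zero variance in both samples: t statistic undefined")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  d <- if (sp > 0) (mean(x) - mean(y)) / sp else NA_real_
  test_result(if (var_equal) "student_t" else "welch_t", label,
              statistic = unname(tt$statistic), p_raw = tt$p.value,
              effect_size = abs(d), effect_signed = d,
              n1 = length(x), n2 = length(y))
}

#' Friedman test across k matched samples
#'
#' Rank test for differences among `k >= 3` scoring methods observed on
#' the same blocks (e.g. per-subject summaries under each method). The
#' statistic is the Friedman chi-square H with `k - 1` degrees of
#' freedom (tie-corrected). The effect size reported is the Kendall's-W
#' style eta squared \eqn{\eta^2 = H / (n (k - 1))}, which is 1 under
#' perfect concordance of the within-block rankings.
#'
#' @param samples A numeric matrix or data frame, blocks in rows and the
#'   k matched conditions in columns (equal lengths required).
#' @param label Comparison label.
#' @return A `test_result` list (statistic is H; `n1` = blocks,
#'   `n2` = k).
#' @export
friedman <- function(samples, label = "methods") {
  m <- as.matrix(samples)
  if (anyNA(m)) stop("unequal block lengths / missing cells in Friedman input")
  if (ncol(m) < 3L) stop("Friedman test needs k >= 3 matched samples")
  if (nrow(m) < 2L) stop("Friedman test needs at least 2 blocks")
  if (all(apply(m, 1L, function(r) max(r) == min(r)))) {
    # every block fully tied: no rank information, H = 0 by convention
    return(test_result("friedman", label, statistic = 0, p_raw = 1,
                       effect_size = 0, effect_signed = 0,
                       n1 = nrow(m), n2 = ncol(m)))
  }
  ft <- stats::friedman.test(m)
  h <- unname(ft$statistic)
  eta2 <- h / (nrow(m) * (ncol(m) - 1))
  test_result("friedman", label, statistic = h, p_raw = ft$p.value,
              effect_size = eta2, effect_signed = eta2,
              n1 = nrow(m), n2 = ncol(m))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: p-values sorted ascending get
#' \eqn{\tilde p_{(i)} = p_{(i)} m / i}, made monotone non-decreasing by
#' a running minimum from the largest rank down, and capped at 1. A test
#' is declared significant when its adjusted p-value is at most the
#' target false discovery rate (default 10%).
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @param fdr Target FDR in (0, 1), default 0.10.
#' @return Data frame in the input order with columns `p_raw`, `rank`
#'   (position in the ascending sort), `p_adjusted`, `significant`.
#' @export
bh_adjust <- function(p_values, fdr = 0.10) {
  p <- as.numeric(p_values)
  if (!length(p)) stop("no p-values to adjust")
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  stopifnot(fdr > 0, fdr < 1)
  m <- length(p)
  o <- order(p)
  adj_sorted <- p[o] * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(adj_sorted)))   # enforce monotone step-up
  adj_sorted <- pmin(adj_sorted, 1)
  adj <- numeric(m); adj[o] <- adj_sorted
  rank <- integer(m); rank[o] <- seq_len(m)
  data.frame(p_raw = p, rank = rank, p_adjusted = adj,
             significant = adj <= fdr)
}

test_result <- function(test_name, label, statistic, p_raw,
                        effect_size = NA_real_, effect_signed = NA_real_,
                        n1 = NA_integer_, n2 = NA_integer_) {
  structure(list(test_name = test_name, label = label,
                 statistic = as.numeric(statistic),
                 p_raw = as.numeric(p_raw),
                 p_adjusted = NA_real_, rank = NA_integer_,
                 effect_size = as.numeric(effect_size),
                 effect_signed = as.numeric(effect_signed),
                 n1 = as.integer(n1), n2 = as.integer(n2)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> %s: stat = %.4g, p = %.3g, effect = %.3g (n = %d + %d)\n",
              x$test_name, x$label, x$statistic, x$p_raw, x$effect_size,
              x$n1, x$n2))
  invisible(x)
}

#' Jointly adjust a family of test results
#'
#' Collects `test_result` objects into one table and applies
#' [bh_adjust()] across the whole family — one correction over the total
#' number of tests in a run, mirroring how multi-stage analyses report a
#' single adjusted column.
#'
#' @param results List of `test_result` objects.
#' @param fdr Target FDR, default 0.10.
#' @return Data frame of class `comparison_report` (one row per test,
#'   original order) with `p_adjusted`, `rank` and `significant` filled;
#'   attributes `fdr` and `m`.
#' @export
comparison_report <- function(results, fdr = 0.10) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "test_result")))
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(label = r$label, test = r$test_name, statistic = r$statistic,
               p_raw = r$p_raw, effect_size = r$effect_size,
               effect_signed = r$effect_signed, n1 = r$n1, n2 = r$n2)
  }))
  adj <- bh_adjust(tab$p_raw, fdr = fdr)
  tab$rank <- adj$rank
  tab$p_adjusted <- adj$p_adjusted
  tab$significant <- adj$significant
  rownames(tab) <- NULL
  structure(tab, fdr = fdr, m = nrow(tab),
            class = c("comparison_report", "data.frame"))
}
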