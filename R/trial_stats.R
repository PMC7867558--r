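# Core signed-rank machinery.
#
# signed_rank_p(d): two-sided p-value of the Wilcoxon signed-rank test of
# symmetry about zero for the differences d. Zero differences are dropped
# (Wilcoxon's rule). With n <= 25 remaining differences and no ties among
# |d|, the exact null distribution is used; otherwise the normal
# approximation with average ranks, tie-corrected variance and continuity
# correction.
signed_rank_p <- function(d, exact_max_n = 25L) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p = 1, n_used = 0L, method = "degenerate"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= exact_max_n) {
    p <- min(1, 2 * min(stats::psignrank(v, n),
                        1 - stats::psignrank(v - 1, n)))
    return(list(statistic = v, p = p, n_used = n, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0)
    return(list(statistic = v, p = 1, n_used = n, method = "degenerate"))
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
  list(statistic = v, p = min(1, 2 * stats::pnorm(-abs(z))), n_used = n,
       method = "normal")
}

#' Hodges-Lehmann estimate and signed-rank confidence interval
#'
#' The location estimate is the median of all Walsh averages
#' `(d_i + d_j) / 2`, `i <= j`; the confidence interval is read off the
#' ordered Walsh averages at the signed-rank critical values (exact null
#' quantiles for n <= 25, normal approximation beyond). This is the
#' standard interval accompanying the paired Wilcoxon signed-rank test.
#'
#' @param diffs Numeric vector of paired differences (length >= 2).
#' @param level Confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper`.
#' @export
#' @examples
#' hodges_lehmann_ci(c(1, 3))$estimate  # median of Walsh averages {1, 2, 3}
hodges_lehmann_ci <- function(diffs, level = 0.95) {
  n <- length(diffs)
  if (n < 2) stop("need at least 2 differences", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  w <- outer(diffs, diffs, "+")[upper.tri(matrix(0, n, n), diag = TRUE)] / 2
  w <- sort(w)
  m <- length(w)                          # n (n + 1) / 2
  alpha <- 1 - level
  if (n <= 25) {
    k <- stats::qsignrank(alpha / 2, n)
  } else {
    k <- floor(n * (n + 1) / 4 -
                 stats::qnorm(1 - alpha / 2) *
                 sqrt(n * (n + 1) * (2 * n + 1) / 24))
  }
  if (k < 1) k <- 1
  list(estimate = stats::median(w), lower = w[k], upper = w[m - k + 1])
}

#' Paired Wilcoxon signed-rank test with Hodges-Lehmann interval
#'
#' Two-sided test of `x` versus `y` on the paired differences `x - y`.
#' Pairs with missing values are removed (complete-case analysis); zero
#' differences are dropped before ranking. P-values are exact for up to 25
#' tie-free differences and tie-corrected normal-approximate otherwise.
#' When every difference is zero the result is degenerate with `p = 1` and
#' `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors of equal length (paired observations), or `y`
#'   omitted for a one-sample test of `x` against zero.
#' @param label Contrast label carried into the result.
#' @param conf_level Confidence level for the Hodges-Lehmann interval.
#' @return A one-row data frame of class `signed_rank_result` with columns
#'   `contrast`, `n_pairs`, `n_used`, `statistic`, `p`, `estimate`,
#'   `ci_low`, `ci_high`, `method`, `degenerate`.
#' @export
paired_wilcoxon <- function(x, y = NULL, label = "x vs y",
                            conf_level = 0.95) {
  if (is.null(y)) y <- rep(0, length(x))
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  keep <- stats::complete.cases(x, y)
  d <- x[keep] - y[keep]
  if (length(d) < 1) stop("no complete pairs", call. = FALSE)
  tst <- signed_rank_p(d)
  if (length(d) >= 2) {
    hl <- hodges_lehmann_ci(d, conf_level)
  } else {
    hl <- list(estimate = d, lower = NA_real_, upper = NA_real_)
  }
  res <- data.frame(contrast = label, n_pairs = length(d),
                    n_used = tst$n_used, statistic = tst$statistic,
                    p = tst$p, estimate = hl$estimate, ci_low = hl$lower,
                    ci_high = hl$upper, method = tst$method,
                    degenerate = tst$method == "degenerate",
                    stringsAsFactors = FALSE)
  class(res) <- c("signed_rank_result", "data.frame")
  res
}

#' Mean relative band power over regions of interest
#'
#' The ROI value is the arithmetic mean, per band, of the relative power of
#' the member electrodes.
#'
#' @param table A `band_power_table`.
#' @param scheme Named list of electrode-label vectors (default
#'   [roi_scheme()]).
#' @return A ROIs x bands numeric matrix.
#' @export
roi_band_power <- function(table, scheme = roi_scheme()) {
  tab <- unclass(table)
  out <- t(vapply(scheme, function(els) {
    idx <- match_labels(els, rownames(tab), context = "ROI electrode")
    colMeans(tab[idx, , drop = FALSE])
  }, numeric(ncol(tab))))
  rownames(out) <- names(scheme)
  out
}

# Collapse second-arm timepoints onto their first-arm names: analysis pools
# arms by condition, so T1'/T2' are the T1/T2 of the condition they carry.
collapse_timepoint <- function(tp) sub("'$", "", tp)

default_contrasts <- function() {
  list(
    list(label = "tACS: T0 vs T1", a = c(NA, "T0"), b = c("tACS", "T1")),
    list(label = "tACS: T0 vs T2", a = c(NA, "T0"), b = c("tACS", "T2")),
    list(label = "tACS: T1 vs T2", a = c("tACS", "T1"), b = c("tACS", "T2")),
    list(label = "RNS: T0 vs T1", a = c(NA, "T0"), b = c("RNS", "T1")),
    list(label = "RNS: T0 vs T2", a = c(NA, "T0"), b = c("RNS", "T2")),
    list(label = "RNS: T1 vs T2", a = c("RNS", "T1"), b = c("RNS", "T2")),
    list(label = "tACS vs RNS at T1", a = c("tACS", "T1"), b = c("RNS", "T1")),
    list(label = "tACS vs RNS at T2", a = c("tACS", "T2"), b = c("RNS", "T2"))
  )
}

#' Crossover outcome analysis with paired signed-rank contrasts
#'
#' For every measure in the outcome table and every contrast, extracts the
#' per-subject paired values (pooling first and second arms by condition:
#' T1'/T2' count as the T1/T2 of their condition), keeps complete cases,
#' and runs [paired_wilcoxon()]. Contrasts with fewer than two complete
#' pairs are skipped with a warning. No multiple-comparison correction is
#' applied; the analysis is exploratory by design.
#'
#' The default contrasts compare, within each condition, baseline T0
#' against post-cycle T1 and post-wash-out T2 and T1 against T2, plus the
#' between-condition comparisons at T1 and at T2.
#'
#' @param outcomes Long-format data frame with columns `subject`,
#'   `timepoint`, `condition`, `measure`, `value` (as produced by
#'   [generate_outcomes()]).
#' @param contrasts Optional list of contrasts, each a list with `label`
#'   and `a`, `b` as `c(condition, timepoint)` (condition `NA` for T0).
#' @param conf_level Confidence level for the Hodges-Lehmann intervals.
#' @return Data frame with one row per (measure, contrast) tested, columns
#'   as in [paired_wilcoxon()] plus `measure`.
#' @export
crossover_analysis <- function(outcomes, contrasts = NULL,
                               conf_level = 0.95) {
  need <- c("subject", "timepoint", "condition", "measure", "value")
  if (!all(need %in% names(outcomes)))
    stop("outcome table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  contrasts <- contrasts %||% default_contrasts()
  outcomes$tp <- collapse_timepoint(outcomes$timepoint)

  cell_values <- function(meas, cond, tp, subjects) {
    sel <- outcomes$measure == meas & outcomes$tp == tp &
      (if (is.na(cond)) TRUE else !is.na(outcomes$condition) &
         outcomes$condition == cond)
    sub <- outcomes[sel, c("subject", "value")]
    sub$value[match(subjects, sub$subject)]
  }

  subjects <- sort(unique(outcomes$subject))
  rows <- list()
  for (meas in unique(outcomes$measure)) {
    for (ct in contrasts) {
      a <- cell_values(meas, ct$a[1L], ct$a[2L], subjects)
      b <- cell_values(meas, ct$b[1L], ct$b[2L], subjects)
      ok <- stats::complete.cases(a, b)
      if (sum(ok) < 2) {
        warning(sprintf("skipping '%s' for %s: %d complete pair(s)",
                        ct$label, meas, sum(ok)), call. = FALSE)
        next
      }
      res <- paired_wilcoxon(a[ok], b[ok], label = ct$label,
                             conf_level = conf_level)
      res$measure <- meas
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows))
    return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("measure", setdiff(names(out), "measure"))]
}

#' Write crossover test results as CSV
#'
#' @param results Data frame from [crossover_analysis()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
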