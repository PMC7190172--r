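#' Intra-class correlation, two-way mixed, consistency, single measures
#'
#' ICC(3,1) in the Shrout & Fleiss taxonomy: subjects are random rows,
#' methods (raters) are fixed columns, and consistency is assessed for a
#' single measurement,
#' \deqn{ICC(3,1) = \frac{MS_B - MS_E}{MS_B + (k-1) MS_E}}
#' where \eqn{MS_B} is the between-subjects mean square and \eqn{MS_E} the
#' residual mean square of the two-way subjects-by-methods ANOVA. Because it
#' is a consistency coefficient, a constant offset between methods does not
#' lower it.
#'
#' @param table n x k numeric matrix: n subjects rated by k methods, no
#'   missing cells, n >= 3, k >= 2.
#' @return the ICC value in \[-1, 1\].
#' @seealso [icc_2_1()] for the absolute-agreement variant,
#'   [classify_icc()] for qualitative bands.
#' @export
icc_3_1 <- function(table) {
  ms <- icc_mean_squares(table)
  (ms$msb - ms$mse) / (ms$msb + (ms$k - 1) * ms$mse)
}

#' Intra-class correlation, two-way random, absolute agreement
#'
#' ICC(2,1): like [icc_3_1()] but penalizing systematic differences between
#' methods. Provided as a sensitivity option;
#' \deqn{ICC(2,1) = \frac{MS_B - MS_E}{MS_B + (k-1)MS_E + k(MS_M - MS_E)/n}}
#' with \eqn{MS_M} the between-methods mean square.
#'
#' @inheritParams icc_3_1
#' @return the ICC value.
#' @export
icc_2_1 <- function(table) {
  ms <- icc_mean_squares(table)
  (ms$msb - ms$mse) /
    (ms$msb + (ms$k - 1) * ms$mse + ms$k * (ms$msm - ms$mse) / ms$n)
}

icc_mean_squares <- function(table) {
  x <- as.matrix(table)
  if (!is.numeric(x) || any(!is.finite(x))) stop("ratings must be finite")
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3) stop("need at least 3 subjects")
  if (k < 2) stop("need at least 2 methods")
  grand <- mean(x)
  if (max(abs(x - grand)) < 1e-300) {
    stop("undefined value: all cells identical (zero total variance)")
  }
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssb <- k * sum((row_m - grand)^2)           # between subjects
  ssm <- n * sum((col_m - grand)^2)           # between methods
  sst <- sum((x - grand)^2)
  sse <- sst - ssb - ssm                      # residual
  list(msb = ssb / (n - 1),
       msm = ssm / (k - 1),
       mse = sse / ((n - 1) * (k - 1)),
       n = n, k = k)
}

#' Pearson correlation with two-sided test
#'
#' @param x,y equal-length numeric vectors, n >= 3, each with nonzero
#'   variance.
#' @return list with `r` and the two-sided t-test `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined value: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Convert a correlation to Cohen's d
#'
#' `d = 2 r / sqrt(1 - r^2)`, the standard conversion between the
#' correlation and standardized-mean-difference effect-size metrics.
#'
#' @param r correlation, `|r| < 1`.
#' @return Cohen's d.
#' @export
cohens_d_from_r <- function(r) {
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || abs(r) >= 1) {
    stop("r must lie strictly inside (-1, 1)")
  }
  2 * r / sqrt(1 - r^2)
}

#' Qualitative band for an ICC value
#'
#' Cicchetti's clinical-significance guidelines: below 0.40 "poor",
#' 0.40-0.59 "fair", 0.60-0.74 "good", 0.75 and above "excellent". Boundary
#' values belong to the higher band (inclusive lower edges).
#'
#' @param value ICC in \[-1, 1\].
#' @return one of `"poor"`, `"fair"`, `"good"`, `"excellent"`.
#' @export
classify_icc <- function(value) {
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value) ||
      value < -1 || value > 1) {
    stop("ICC value must lie in [-1, 1]")
  }
  if (value < 0.40) "poor"
  else if (value < 0.60) "fair"
  else if (value < 0.75) "good"
  else "excellent"
}

#' Compare two co-registration methods across a cohort
#'
#' Builds the inter-method comparison reported in co-registration studies:
#' for the error and for each of the six decomposed transform parameters
#' (translations x/y/z in mm, pitch/roll/yaw in degrees), per-method medians
#' and IQRs, the mean of the per-subject signed differences (b - a) with its
#' SD, Pearson r between the methods' errors with the corresponding Cohen's
#' d, ICC(3,1) per measure with its qualitative band, an ICC sensitivity
#' rerun on the error after excluding subjects whose method-b error is
#' strictly greater than `quality_threshold`, and the correlation between
#' each method's errors and the number of headshape points.
#'
#' @param results_a,results_b lists of `coreg_result`, same subjects in the
#'   same order (e.g. manual and automated), n >= 3.
#' @param headshape_counts optional integer vector of digitized
#'   headshape-point counts per subject; defaults to the counts stored in
#'   `results_a`.
#' @param quality_threshold mm; exclusion cutoff for the sensitivity ICC
#'   (default 2).
#' @return a `comparison_report` list; see Details.
#' @details The report holds `measures` (a data frame, one row per measure:
#'   `median_a`, `iqr_a_low/high`, `median_b`, `iqr_b_low/high`,
#'   `mean_diff`, `sd_diff`, `icc`, `band`), `error_pearson` (`r`, `p`),
#'   `error_cohens_d`, `icc_error_after_exclusion`, `n_excluded`,
#'   `excluded_subjects`, and `headshape_count_correlation` per method.
#' @export
compare_methods <- function(results_a, results_b, headshape_counts = NULL,
                            quality_threshold = 2) {
  ok <- function(l) is.list(l) &&
    all(vapply(l, inherits, logical(1), "coreg_result"))
  if (!ok(results_a) || !ok(results_b)) {
    stop("results must be lists of coreg_result objects")
  }
  n <- length(results_a)
  if (length(results_b) != n) stop("mismatched subject lists")
  if (n < 3) stop("need at least 3 subjects")
  if (is.null(headshape_counts)) {
    headshape_counts <- vapply(results_a, `[[`, 0, "n_headshape")
  }
  if (length(headshape_counts) != n) stop("mismatched subject lists")

  measure_values <- function(results) {
    err <- vapply(results, `[[`, 0, "median_error")
    par6 <- t(vapply(results, function(r) {
      p <- decompose(r$transform)
      c(p$tx, p$ty, p$tz, p$pitch, p$roll, p$yaw)
    }, numeric(6)))
    cbind(error = err, tx = par6[, 1], ty = par6[, 2], tz = par6[, 3],
          pitch = par6[, 4], roll = par6[, 5], yaw = par6[, 6])
  }
  va <- measure_values(results_a)
  vb <- measure_values(results_b)

  rows <- lapply(colnames(va), function(m) {
    a <- va[, m]; b <- vb[, m]
    qa <- stats::quantile(a, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    qb <- stats::quantile(b, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    # a measure with no variance at all (e.g. two constant columns) has no
    # defined ICC; report NA rather than aborting the whole comparison
    icc <- tryCatch(icc_3_1(cbind(a, b)), error = function(e) NA_real_)
    data.frame(measure = m,
               median_a = qa[2], iqr_a_low = qa[1], iqr_a_high = qa[3],
               median_b = qb[2], iqr_b_low = qb[1], iqr_b_high = qb[3],
               mean_diff = mean(b - a), sd_diff = stats::sd(b - a),
               icc = icc,
               band = if (is.na(icc)) NA_character_ else classify_icc(icc),
               stringsAsFactors = FALSE)
  })
  measures <- do.call(rbind, rows)

  err_a <- va[, "error"]; err_b <- vb[, "error"]
  er <- pearson_r(err_a, err_b)
  excluded <- which(err_b > quality_threshold)
  kept <- setdiff(seq_len(n), excluded)
  icc_excl <- if (length(kept) >= 3) {
    icc_3_1(cbind(err_a[kept], err_b[kept]))
  } else NA_real_

  structure(list(
    n_subjects = n,
    measures = measures,
    error_pearson = er,
    error_cohens_d = if (abs(er$r) < 1) cohens_d_from_r(er$r) else
      sign(er$r) * Inf,
    quality_threshold = quality_threshold,
    n_excluded = length(excluded),
    excluded_subjects = excluded,
    icc_error_after_exclusion = icc_excl,
    headshape_count_correlation = list(
      a = pearson_r(err_a, headshape_counts),
      b = pearson_r(err_b, headshape_counts))),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d subjects\n", x$n_subjects))
  err <- x$measures[x$measures$measure == "error", ]
  cat(sprintf("  error: median a %.3f mm, b %.3f mm; mean diff %.3f (SD %.3f)\n",
              err$median_a, err$median_b, err$mean_diff, err$sd_diff))
  cat(sprintf("  error ICC %.3f (%s); after >%.1f mm exclusion (%d dropped): %.3f\n",
              err$icc, err$band, x$quality_threshold, x$n_excluded,
              x$icc_error_after_exclusion))
  cat(sprintf("  error r = %.3f (p = %.3g), Cohen's d = %.2f\n",
              x$error_pearson$r, x$error_pearson$p, x$error_cohens_d))
  pm <- x$measures[x$measures$measure != "error", ]
  cat("  parameter ICCs: ",
      paste(sprintf("%s %.3f", pm$measure, pm$icc), collapse = ", "), "\n")
  invisible(x)
}
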