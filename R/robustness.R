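# Contour-robustness screening: single-measurement absolute-agreement ICC
# over the four contour variants, with an F-based 95% confidence interval,
# and the lower-bound >= 0.60 retention filter.

#' Absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Two-way random-effects, single-measurement, absolute-agreement ICC
#' (McGraw & Wong's ICC(A,1)): with subject, rater and error mean squares
#' `MS_R`, `MS_C`, `MS_E` from the two-way ANOVA of an `n x k` matrix,
#' `ICC = (MS_R - MS_E) / (MS_R + (k - 1) MS_E + (k / n)(MS_C - MS_E))`.
#' The 95% confidence interval uses the F approximation with
#' Satterthwaite-style denominator degrees of freedom from the same
#' reference. Here the "raters" are the four contour variants, so the ICC
#' quantifies how much of a feature's variance survives contour perturbation.
#'
#' @param m numeric matrix, subjects in rows, contour variants (raters) in
#'   columns; no missing cells; at least 3 rows and 2 columns.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return A tibble of class `icc_result` with columns `icc`, `ci_lower`,
#'   `ci_upper`, `n_subjects`, `k_raters` and `undefined` (TRUE when the
#'   total variance is zero and the ICC does not exist).
#' @export
#' @examples
#' m <- matrix(rnorm(24), 6, 4) + rnorm(6) # subject effect
#' icc_a1(m + 0 * m) # perfect agreement across identical columns has ICC 1
icc_a1 <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("missing cells are not allowed", call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3 || k < 2) stop("need >= 3 subjects and >= 2 raters", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_e <- sum((m - outer(row_m, rep(1, k)) -
                 outer(rep(1, n), col_m) + grand)^2)
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  if (abs(denom) < 1e-300 || (ms_r < 1e-300 && ms_c < 1e-300 && ms_e < 1e-300)) {
    return(tibble::new_tibble(list(icc = NA_real_, ci_lower = NA_real_,
                                   ci_upper = NA_real_, n_subjects = n,
                                   k_raters = k, undefined = TRUE),
                              class = "icc_result"))
  }
  icc <- (ms_r - ms_e) / denom
  alpha <- 1 - conf_level
  if (ms_e == 0 && ms_c == 0) {
    # perfect agreement: no residual or rater variance
    lo <- hi <- 1
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    if (!is.finite(a) || !is.finite(b)) {
      lo <- hi <- 1
    } else {
      v <- (a * ms_c + b * ms_e)^2 /
        ((a * ms_c)^2 / (k - 1) + (b * ms_e)^2 / ((n - 1) * (k - 1)))
      f_l <- stats::qf(1 - alpha / 2, n - 1, v)
      f_u <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (ms_r - f_l * ms_e) /
        (f_l * (k * ms_c + (k * n - k - n) * ms_e) + n * ms_r)
      hi <- n * (f_u * ms_r - ms_e) /
        (k * ms_c + (k * n - k - n) * ms_e + n * f_u * ms_r)
    }
  }
  tibble::new_tibble(list(icc = icc, ci_lower = min(lo, icc),
                          ci_upper = max(hi, icc), n_subjects = n,
                          k_raters = k, undefined = FALSE),
                     class = "icc_result")
}

#' Screen features for contour robustness
#'
#' Computes ICC(A,1) across the contour variants for every feature in a tidy
#' feature table and retains the features whose lower 95% confidence bound
#' meets `threshold` (inclusive). Subjects with missing or non-finite values
#' in any variant of a feature are dropped for that feature and reported in
#' the `n_subjects` column; features with an undefined ICC (zero variance)
#' are never retained.
#'
#' @param feature_table tibble with columns `patient_id`, `contour_variant`,
#'   `feature`, `value` — typically percentage changes between the two
#'   timepoints, variant-matched.
#' @param threshold retention cutoff on the lower confidence bound
#'   (default 0.60, inclusive).
#' @param conf_level confidence level for the ICC interval.
#' @return A tibble of class `robustness_result` with one row per feature:
#'   `feature`, `icc`, `ci_lower`, `ci_upper`, `n_subjects`, `k_raters`,
#'   `undefined`, `robust`.
#' @export
robust_filter <- function(feature_table, threshold = 0.60, conf_level = 0.95) {
  need <- c("patient_id", "contour_variant", "feature", "value")
  if (!all(need %in% names(feature_table))) {
    stop("feature_table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  variants <- unique(feature_table$contour_variant)
  res <- feature_table |>
    dplyr::group_by(.data$feature) |>
    dplyr::group_modify(function(df, key) {
      wide <- tidyr::pivot_wider(df, id_cols = "patient_id",
                                 names_from = "contour_variant",
                                 values_from = "value")
      m <- as.matrix(wide[, variants, drop = FALSE])
      keep <- apply(m, 1, function(r) all(is.finite(r)))
      m <- m[keep, , drop = FALSE]
      if (nrow(m) < 3) {
        return(tibble::tibble(icc = NA_real_, ci_lower = NA_real_,
                              ci_upper = NA_real_, n_subjects = nrow(m),
                              k_raters = ncol(m), undefined = TRUE))
      }
      tibble::as_tibble(icc_a1(m, conf_level = conf_level))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(robust = !.data$undefined &
                    .data$ci_lower >= threshold - 1e-12)
  attr(res, "threshold") <- threshold
  class(res) <- c("robustness_result", class(res))
  res
}

#' Retained features from a robustness screen
#'
#' @param robustness a `robustness_result` from [robust_filter()].
#' @return Character vector of retained feature ids.
#' @export
robust_features <- function(robustness) {
  robustness$feature[robustness$robust]
}
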