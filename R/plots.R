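# ggplot2 visualisations for the main result types.

#' Plot a robustness screen
#'
#' Dot-and-interval plot of the ICC and its lower 95% confidence bound per
#' feature, with the retention threshold drawn as a dashed line.
#'
#' @param object a `robustness_result` from [robust_filter()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot robustness_result
#' @export
autoplot.robustness_result <- function(object, ...) {
  thr <- attr(object, "threshold")
  df <- dplyr::filter(object, !.data$undefined) |>
    dplyr::mutate(feature = stats::reorder(.data$feature, .data$ci_lower))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$icc, y = .data$feature,
                                   colour = .data$robust)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ci_lower,
                                       xend = .data$ci_upper,
                                       yend = .data$feature),
                          linewidth = 0.4) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "ICC(A,1) with 95% CI", y = NULL,
                  colour = sprintf("lower bound ≥ %.2f", thr)) +
    ggplot2::theme_minimal()
}

#' Plot a per-patient response waterfall
#'
#' Background-corrected SUV_max percentage change per patient, coloured by
#' EORTC class.
#'
#' @param object a `response_table` from [build_response_table()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot response_table
#' @export
autoplot.response_table <- function(object, ...) {
  df <- dplyr::filter(object, is.finite(.data$suv_max_change_pct)) |>
    dplyr::mutate(patient_id = stats::reorder(.data$patient_id,
                                              -.data$suv_max_change_pct))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$patient_id,
                                   y = .data$suv_max_change_pct,
                                   fill = .data$eortc_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "SUV_max change from baseline (%)",
                  fill = "EORTC class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the cross-validation curve and selected terms of a LASSO fit
#'
#' @param object a `lasso_fit`.
#' @param ... unused.
#' @return A ggplot object (LOOCV deviance vs log lambda, with the selected
#'   penalty marked).
#' @method autoplot lasso_fit
#' @export
autoplot.lasso_fit <- function(object, ...) {
  if (isTRUE(object$intercept_only) || !length(object$lambda)) {
    stop("intercept-only fit has no cross-validation curve", call. = FALSE)
  }
  df <- tibble::tibble(log_lambda = log(object$lambda), deviance = object$cvm)
  ggplot2::ggplot(df, ggplot2::aes(.data$log_lambda, .data$deviance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = log(object$lambda_min),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(log(lambda)),
                  y = "LOOCV binomial deviance") +
    ggplot2::theme_minimal()
}
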