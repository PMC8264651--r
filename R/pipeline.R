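# Cohort-level orchestration: feature tables, percentage changes, robustness
# screen, response coding, and the two LASSO models, with artifact output.

#' Extract the cohort feature table
#'
#' Runs [extract_variant_features()] on every patient and timepoint,
#' producing the tidy table `patient_id, timepoint, contour_variant,
#' feature, value`.
#'
#' @param cohort an `flt_cohort`.
#' @param config a [feature_config()].
#' @param deltas_mm contour perturbation margins (0 = original contour).
#' @return A tibble.
#' @export
cohort_feature_table <- function(cohort, config = feature_config(),
                                 deltas_mm = c(0, 1, 2, -1)) {
  stopifnot(inherits(cohort, "flt_cohort"))
  purrr::map_dfr(cohort$patients, function(p) {
    purrr::map_dfr(c("FLT1", "FLT2"), function(tp) {
      vol <- if (tp == "FLT1") p$flt1 else p$flt2
      extract_variant_features(vol, p$lesion_mask, config,
                               deltas_mm = deltas_mm) |>
        dplyr::mutate(patient_id = p$patient_id, timepoint = tp,
                      .before = 1)
    })
  })
}

#' Percentage-change feature table
#'
#' Joins the two timepoints variant-by-variant and computes the percentage
#' change from baseline, `(FLT1 - FLT2) / FLT1 * 100`, per patient, contour
#' variant and feature. Changes with a (numerically) zero baseline are `NA`.
#'
#' @param feature_table output of [cohort_feature_table()].
#' @return Tibble with `patient_id`, `contour_variant`, `feature`, `value`.
#' @export
percent_change_table <- function(feature_table) {
  wide <- tidyr::pivot_wider(feature_table, names_from = "timepoint",
                             values_from = "value")
  if (!all(c("FLT1", "FLT2") %in% names(wide))) {
    stop("feature_table must contain both FLT1 and FLT2 timepoints",
         call. = FALSE)
  }
  wide |>
    dplyr::mutate(value = percent_change(.data$FLT1, .data$FLT2)) |>
    dplyr::select("patient_id", "contour_variant", "feature", "value")
}

#' Run the full early-response pipeline on a synthetic cohort
#'
#' Orchestrates synthesis, feature extraction over the four contour
#' variants, percentage-change computation, the ICC robustness screen, EORTC
#' and pathological response coding with concordance testing, and the two
#' LASSO-LOOCV models (PET response on robust percentage-change features;
#' pathological response on the same features with the PET response as an
#' optional extra covariate). If `out_dir` is given, artifacts are written
#' as CSV/JSON with deterministic content for a fixed cohort seed.
#'
#' @param cohort an `flt_cohort`, or a [cohort_config()] to generate one.
#' @param config a [feature_config()].
#' @param icc_threshold retention cutoff for the robustness screen.
#' @param with_pet_covariate also fit the pathological-response model with
#'   the binary PET response added to the covariates.
#' @param out_dir optional output directory for artifacts.
#' @return A list of class `flt_pipeline` with elements `features`,
#'   `changes`, `robustness`, `robust_features`, `response`, `concordance`,
#'   `fisher_p`, `model_pet`, `model_path`, `model_path_with_pet`, `log`.
#' @export
run_pipeline <- function(cohort, config = feature_config(),
                         icc_threshold = 0.60, with_pet_covariate = TRUE,
                         out_dir = NULL) {
  if (inherits(cohort, "cohort_config")) cohort <- generate_cohort(cohort)
  stopifnot(inherits(cohort, "flt_cohort"))
  log <- list(n_enrolled = length(cohort$patients),
              n_evaluable = length(cohort$patients),
              n_excluded = 0L,
              seed = cohort$config$seed,
              icc_threshold = icc_threshold,
              n_bins = config$n_bins, resample_mm = config$resample_mm)

  features <- cohort_feature_table(cohort, config)
  changes <- percent_change_table(features)
  robustness <- robust_filter(changes, threshold = icc_threshold)
  robust_set <- robust_features(robustness)
  log$n_robust_features <- length(robust_set)

  response <- build_response_table(cohort, config)
  conc <- concordance(response)
  fisher_p <- fisher_exact_2x2(conc$table)

  orig <- dplyr::filter(changes, .data$contour_variant == "original")
  fit_or_null <- function(x, y) {
    tryCatch(lasso_logistic_loocv(x, y),
             error = function(e) {
               warning("model not fitted: ", conditionMessage(e),
                       call. = FALSE)
               NULL
             })
  }
  model_pet <- model_path <- model_path_with_pet <- NULL
  if (length(robust_set) >= 1) {
    x <- feature_matrix(orig, robust_set)
    ord <- match(rownames(x), response$patient_id)
    y_pet <- response$pet_binary[ord]
    y_path <- response$path_binary[ord]
    model_pet <- fit_or_null(x, y_pet)
    model_path <- fit_or_null(x, y_path)
    if (with_pet_covariate) {
      pet_named <- stats::setNames(response$pet_binary, response$patient_id)
      x2 <- feature_matrix(orig, robust_set, pet_binary = pet_named)
      model_path_with_pet <- fit_or_null(x2, y_path)
    }
  } else {
    warning("robustness screen retained no features; models skipped",
            call. = FALSE)
  }

  out <- structure(list(features = features, changes = changes,
                        robustness = robustness,
                        robust_features = robust_set,
                        response = response, concordance = conc,
                        fisher_p = fisher_p, model_pet = model_pet,
                        model_path = model_path,
                        model_path_with_pet = model_path_with_pet,
                        log = log),
                   class = "flt_pipeline")
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

#' @export
print.flt_pipeline <- function(x, ...) {
  cat("<flt_pipeline> ", x$log$n_evaluable, " patients, ",
      length(x$robust_features), " robust features, agreement ",
      x$concordance$agreement, "/", x$concordance$n,
      " (fisher p = ", signif(x$fisher_p, 3), ")\n", sep = "")
  invisible(x)
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wjson <- function(x, name) {
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  wcsv(result$features, "features.csv")
  wcsv(result$changes, "percent_changes.csv")
  wcsv(dplyr::select(result$robustness, "feature", "icc", "ci_lower",
                     "robust"), "icc_table.csv")
  wcsv(result$response, "response.csv")
  wjson(list(table = as.vector(result$concordance$table),
             agreement = result$concordance$agreement,
             n = result$concordance$n,
             fisher_p = result$fisher_p), "concordance.json")
  model_report <- function(fit) {
    if (is.null(fit)) return(NULL)
    list(coefficients = as.list(fit$coefficients),
         lambda_min = fit$lambda_min, loocv_error = fit$loocv_error)
  }
  wjson(list(pet_response = model_report(result$model_pet),
             path_response = model_report(result$model_path),
             path_response_with_pet = model_report(result$model_path_with_pet)),
        "models.json")
  wjson(result$log, "run_log.json")
  invisible(out_dir)
}
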