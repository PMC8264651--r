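# Response coding: percentage change, contralateral background correction,
# EORTC PET classes, residual-cancer-burden mapping, and the PET-vs-pathology
# concordance with an exact Fisher test.

#' Percentage change from baseline
#'
#' `(v1 - v2) / v1 * 100`: positive values are reductions from baseline.
#' When the baseline is (numerically) zero the change is undefined and `NA`
#' is returned so the record can be excluded from modelling.
#'
#' @param v1 baseline value(s).
#' @param v2 follow-up value(s).
#' @param eps magnitude below which the baseline counts as zero.
#' @return Numeric vector of percentage changes (`NA` where undefined).
#' @export
#' @examples
#' percent_change(10, 5) # 50
#' percent_change(4, 6) # -50
percent_change <- function(v1, v2, eps = 1e-9) {
  out <- (v1 - v2) / v1 * 100
  out[!is.finite(v1) | abs(v1) < eps] <- NA_real_
  out
}

#' Background-correct SUV statistics
#'
#' Subtracts, statistic by statistic, the contralateral (mirrored VOI) SUV
#' statistics from the lesion statistics, flooring at zero: residual uptake
#' at or below the background level counts as none.
#'
#' @param lesion_stats named list/vector with `SUV_max`, `SUV_mean`,
#'   `SUV_peak` from the lesion VOI.
#' @param contralateral_stats matching statistics from the mirrored VOI.
#' @return Named list of corrected statistics.
#' @export
background_correct <- function(lesion_stats, contralateral_stats) {
  ids <- c("SUV_max", "SUV_mean", "SUV_peak")
  out <- lapply(ids, function(id) {
    max(lesion_stats[[id]] - contralateral_stats[[id]], 0)
  })
  stats::setNames(out, ids)
}

#' EORTC PET response class
#'
#' Classifies the change in background-corrected SUV_max between the two
#' scans: complete metabolic response (CMR) when follow-up corrected uptake
#' has disappeared into the background (floored value ~ 0); progressive
#' disease (PMD) when uptake increased by more than `pmd_increase_pct`;
#' partial response (PMR) when the reduction is at least `pmr_reduction_pct`
#' (15% after one cycle); stable disease (SMD) otherwise. The binary PET
#' code used for modelling is 1 for CMR, 0 otherwise.
#'
#' @param suv1_corrected baseline background-corrected SUV_max.
#' @param suv2_corrected follow-up background-corrected SUV_max.
#' @param pmr_reduction_pct reduction threshold for PMR (percent).
#' @param pmd_increase_pct increase threshold for PMD (percent).
#' @param tol tolerance under which corrected uptake counts as absent.
#' @return Character scalar: `"CMR"`, `"PMR"`, `"SMD"`, `"PMD"`, or `NA` when
#'   the baseline uptake is zero and the change is unevaluable.
#' @export
classify_eortc <- function(suv1_corrected, suv2_corrected,
                           pmr_reduction_pct = 15, pmd_increase_pct = 25,
                           tol = 1e-9) {
  if (suv2_corrected <= tol) return("CMR")
  pct <- percent_change(suv1_corrected, suv2_corrected)
  if (is.na(pct)) return(NA_character_)
  if (pct < -pmd_increase_pct) return("PMD")
  if (pct >= pmr_reduction_pct) return("PMR")
  "SMD"
}

#' Map residual cancer burden category to binary pathological response
#'
#' RCB-0 and RCB-I count as pathological complete response (pCR, coded 1);
#' RCB-II and RCB-III as partial response (pPR, coded 0).
#'
#' @param rcb_category character vector of `"RCB-0"`, `"RCB-I"`, `"RCB-II"`,
#'   `"RCB-III"`.
#' @return Integer vector of 0/1 codes.
#' @export
map_rcb <- function(rcb_category) {
  lut <- c("RCB-0" = 1L, "RCB-I" = 1L, "RCB-II" = 0L, "RCB-III" = 0L)
  bad <- setdiff(unique(rcb_category), names(lut))
  if (length(bad)) {
    stop("unknown RCB category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(lut[rcb_category])
}

#' PET-vs-pathology concordance
#'
#' Cross-tabulates the binary PET response against the binary pathological
#' response; agreement is the diagonal count.
#'
#' @param records tibble with columns `pet_binary` and `path_binary`
#'   (0/1 codes); rows with `NA` in either are dropped.
#' @return List with `table` (2x2 matrix, PET in rows: CR then PR; pathology
#'   in columns: pCR then pPR), `agreement`, `n` and `agreement_pct`.
#' @export
concordance <- function(records) {
  ok <- !is.na(records$pet_binary) & !is.na(records$path_binary)
  pet <- records$pet_binary[ok]
  path <- records$path_binary[ok]
  if (!length(pet)) stop("no records with both response codes", call. = FALSE)
  tab <- matrix(c(sum(pet == 1 & path == 1), sum(pet == 1 & path == 0),
                  sum(pet == 0 & path == 1), sum(pet == 0 & path == 0)),
                nrow = 2, byrow = TRUE,
                dimnames = list(PET = c("CR", "PR"),
                                pathology = c("pCR", "pPR")))
  agreement <- tab["CR", "pCR"] + tab["PR", "pPR"]
  list(table = tab, agreement = agreement, n = length(pet),
       agreement_pct = 100 * agreement / length(pet))
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Enumerates, with margins fixed, all tables whose hypergeometric
#' probability does not exceed that of the observed table (to a small
#' relative tolerance for ties) and sums their probabilities.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @param tie_tol relative tolerance treating near-equal probabilities as
#'   ties.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(7, 2, 0, 6), 2)) # 0.007
fisher_exact_2x2 <- function(tab, tie_tol = 1e-7) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(abs(tab - round(tab)) > 1e-9)) {
    stop("`tab` must be a 2x2 matrix of nonnegative integers", call. = FALSE)
  }
  tab <- round(tab)
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  x_obs <- tab[1, 1]
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(x_obs, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + tie_tol)])
}

#' Build the per-patient response table for a synthetic cohort
#'
#' For each patient, resamples both timepoints, computes lesion and
#' contralateral SUV statistics, background-corrects them, classifies the
#' EORTC PET response, maps the RCB category to the binary pathological
#' response and records the background-corrected SUV_max percentage change.
#'
#' @param cohort an `flt_cohort` from [generate_cohort()].
#' @param config a [feature_config()] controlling resampling.
#' @param resample resample to the isotropic grid before computing SUV
#'   statistics (default TRUE, matching the feature pipeline).
#' @return A tibble of class `response_table`: `patient_id`, `eortc_class`,
#'   `pet_binary`, `rcb_category`, `path_binary`, `suv_max_change_pct`.
#' @export
build_response_table <- function(cohort, config = feature_config(),
                                 resample = TRUE) {
  stopifnot(inherits(cohort, "flt_cohort"))
  corrected_suv_max <- function(vol, lesion, contra) {
    stat_for <- function(mask) {
      if (resample) {
        cr <- crop_to_mask(vol, mask, margin_mm = config$margin_mm)
        rs <- resample_isotropic(cr$vol, cr$mask,
                                 target_mm = config$resample_mm)
        suv_statistics(rs$vol, rs$mask)
      } else {
        suv_statistics(vol, mask)
      }
    }
    background_correct(stat_for(lesion), stat_for(contra))$SUV_max
  }
  rows <- purrr::map_dfr(cohort$patients, function(p) {
    s1 <- corrected_suv_max(p$flt1, p$lesion_mask, p$contralateral_mask)
    s2 <- corrected_suv_max(p$flt2, p$lesion_mask, p$contralateral_mask)
    cls <- classify_eortc(s1, s2)
    tibble::tibble(
      patient_id = p$patient_id,
      eortc_class = cls,
      pet_binary = ifelse(is.na(cls), NA_integer_,
                          as.integer(cls == "CMR")),
      rcb_category = p$rcb_category,
      path_binary = map_rcb(p$rcb_category),
      suv_max_change_pct = percent_change(s1, s2)
    )
  })
  class(rows) <- c("response_table", class(rows))
  rows
}

#' Patient-flow accounting
#'
#' Splits an enrolled cohort into evaluable and excluded patients with
#' per-reason counts: a patient is evaluable only with histology available
#' and both PET scans acquired.
#'
#' @param records tibble with logical columns `has_histology` and `has_flt2`
#'   (one row per enrolled patient).
#' @return List with `n_enrolled`, `n_evaluable`, `n_excluded`, a
#'   per-reason count table `exclusions`, and the `evaluable` subset.
#' @export
patient_flow <- function(records) {
  stopifnot(all(c("has_histology", "has_flt2") %in% names(records)))
  no_hist <- !records$has_histology
  no_flt2 <- records$has_histology & !records$has_flt2
  keep <- records$has_histology & records$has_flt2
  flow <- list(
    n_enrolled = nrow(records),
    n_evaluable = sum(keep),
    n_excluded = sum(!keep),
    exclusions = c(no_histology = sum(no_hist),
                   no_second_scan = sum(no_flt2)),
    evaluable = records[keep, , drop = FALSE]
  )
  stopifnot(flow$n_enrolled == flow$n_evaluable + flow$n_excluded)
  flow
}
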