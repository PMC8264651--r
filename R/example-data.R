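#' Worked-example neoadjuvant FLT-PET cohort outcomes
#'
#' A 20-patient enrolment table from a neoadjuvant-chemotherapy breast-cancer
#' setting, used throughout the documentation as the worked example for the
#' response-coding and concordance operations. Three patients lack histology
#' (one refused surgery, two progressed systemically) and two lack the second
#' PET scan, leaving 15 evaluable patients: 9 with pathological complete
#' response (8 RCB-0, 1 RCB-I) and 6 with partial response (5 RCB-II,
#' 1 RCB-III); 7 PET complete responders, all pathological complete
#' responders, and 8 PET partial responders of whom 2 (one RCB-0, one RCB-I)
#' were nonetheless complete responders at pathology.
#'
#' @return A tibble with one row per enrolled patient and columns
#'   `patient_id`, `has_histology`, `has_flt2`, `eortc_class`, `pet_binary`,
#'   `rcb_category`, `path_binary` (response columns are `NA` for
#'   non-evaluable patients).
#' @export
#' @examples
#' flow <- patient_flow(flt_example_outcomes())
#' flow$n_evaluable # 15
#' concordance(flow$evaluable)$agreement # 13
flt_example_outcomes <- function() {
  eortc <- c(rep("CMR", 7), rep("PMR", 8))
  rcb <- c(rep("RCB-0", 7), # PET CR, all pathological CR
           "RCB-0", "RCB-I", # PET PR, pathological CR (the discordant pair)
           rep("RCB-II", 5), "RCB-III") # PET PR, pathological PR
  evaluable <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:15),
    has_histology = TRUE,
    has_flt2 = TRUE,
    eortc_class = eortc,
    pet_binary = as.integer(eortc == "CMR"),
    rcb_category = rcb,
    path_binary = map_rcb(rcb)
  )
  excluded <- tibble::tibble(
    patient_id = sprintf("P%02d", 16:20),
    has_histology = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    has_flt2 = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    eortc_class = NA_character_,
    pet_binary = NA_integer_,
    rcb_category = NA_character_,
    path_binary = NA_integer_
  )
  dplyr::bind_rows(evaluable, excluded)
}
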