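test_that("percentage change follows the baseline-referenced formula", {
  expect_equal(percent_change(10, 5), 50)
  expect_equal(percent_change(4, 6), -50)
  # the worked pair of scans: SUV_max 9.1 at baseline, 5.6 after one cycle
  expect_equal(percent_change(9.1, 5.6), 100 * (9.1 - 5.6) / 9.1,
               tolerance = 1e-12)
  expect_equal(round(percent_change(9.1, 5.6), 2), 38.46)
  expect_true(is.na(percent_change(0, 5)))
  expect_equal(percent_change(7, 7), 0)
  expect_equal(percent_change(7, 14), -100)
})

test_that("background correction subtracts per-statistic and floors at zero", {
  lesion <- list(SUV_max = 9, SUV_mean = 5, SUV_peak = 7)
  bg <- list(SUV_max = 1, SUV_mean = 1, SUV_peak = 1)
  out <- background_correct(lesion, bg)
  expect_equal(unlist(out), c(SUV_max = 8, SUV_mean = 4, SUV_peak = 6))
  hot_bg <- list(SUV_max = 10, SUV_mean = 6, SUV_peak = 8)
  floored <- background_correct(lesion, hot_bg)
  expect_true(all(unlist(floored) == 0))
})

test_that("EORTC classes follow the configured thresholds", {
  # a 38% reduction with persistent uptake is a partial response
  expect_equal(classify_eortc(9.1, 5.6), "PMR")
  # complete disappearance of corrected uptake is a complete response
  expect_equal(classify_eortc(2.7, 0), "CMR")
  # a 30% increase is progressive disease
  expect_equal(classify_eortc(10, 13), "PMD")
  # small changes are stable disease
  expect_equal(classify_eortc(10, 9), "SMD")
  expect_equal(classify_eortc(10, 8.5), "PMR") # 15% boundary inclusive
  expect_true(is.na(classify_eortc(0, 1)))
})

test_that("residual-cancer-burden categories map to the binary pathology code", {
  expect_equal(map_rcb(c("RCB-0", "RCB-I", "RCB-II", "RCB-III")),
               c(1L, 1L, 0L, 0L))
  expect_error(map_rcb("RCB-IV"), "unknown")
})

test_that("concordance of the worked example cohort is 13 of 15", {
  flow <- patient_flow(flt_example_outcomes())
  conc <- concordance(flow$evaluable)
  expect_equal(conc$table, matrix(c(7, 0, 2, 6), 2, byrow = TRUE,
                                  dimnames = dimnames(conc$table)))
  expect_equal(conc$agreement, 13)
  expect_equal(conc$n, 15)

  toy <- tibble::tibble(pet_binary = c(1, 1, 0, 0),
                        path_binary = c(1, 1, 0, 0))
  expect_equal(concordance(toy)$agreement, 4)
  empty <- tibble::tibble(pet_binary = NA_integer_, path_binary = 1L)
  expect_error(concordance(empty), "no records")
})

test_that("patient-flow accounting reproduces the enrolment arithmetic", {
  flow <- patient_flow(flt_example_outcomes())
  expect_equal(flow$n_enrolled, 20)
  expect_equal(flow$n_evaluable, 15)
  expect_equal(unname(flow$exclusions["no_histology"]), 3)
  expect_equal(unname(flow$exclusions["no_second_scan"]), 2)
  expect_equal(sum(flow$evaluable$path_binary), 9) # pathological CRs
  expect_equal(sum(flow$evaluable$pet_binary), 7) # PET CRs
})

test_that("the exact Fisher test agrees with enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  set.seed(51)
  for (i in 1:25) {
    n <- sample(4:20, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.1, 1)))
    tab <- matrix(cells, 2)
    expect_equal(fisher_exact_2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9,
                 info = paste(cells, collapse = ","))
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 1), 2)), "nonnegative")
})

test_that("synthetic response tables recover the planted contrast", {
  coh <- generate_cohort(cohort_config(n_patients = 6, seed = 9))
  rt <- build_response_table(coh, resample = FALSE)
  truth <- coh$truth
  merged <- dplyr::left_join(rt, truth, by = "patient_id")
  resp <- merged[merged$true_label == "responder", ]
  nonresp <- merged[merged$true_label == "nonresponder", ]
  # background-corrected SUV_max percentage change tracks the planted decline
  expect_equal(resp$suv_max_change_pct / 100, resp$decline, tolerance = 0.15)
  expect_true(all(nonresp$suv_max_change_pct < 25))
  expect_true(all(merged$path_binary ==
                    as.integer(merged$true_label == "responder")))
})

test_that("PET-pathology agreement grows with the planted separation", {
  agreement_for <- function(decl, seed) {
    cfg <- cohort_config(n_patients = 10, seed = seed,
                         responder_decline = decl,
                         heterogeneity = list(corr_mm = 4, amplitude = 0.3))
    coh <- generate_cohort(cfg)
    rt <- build_response_table(coh, resample = FALSE)
    mean(rt$pet_binary == as.integer(coh$truth$true_label == "responder"))
  }
  seps <- list(c(0.10, 0.30), c(0.40, 0.70), c(0.90, 1.00))
  agree <- vapply(1:3, function(s) {
    vapply(seps, agreement_for, numeric(1), seed = 60 + s)
  }, numeric(3))
  means <- rowMeans(agree)
  expect_true(all(diff(means) >= 0))
})
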