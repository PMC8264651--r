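test_that("lesion texture honours the zero-noise limit and determinism", {
  mask <- ellipsoid_fixture(radius_mm = 6, dim = c(21, 21, 21))
  flat <- generate_lesion_texture(mask, list(corr_mm = 4, amplitude = 0),
                                  suv_range = c(2, 8), seed = 1)
  expect_equal(unique(flat$data[mask$data]), 8)
  expect_true(all(flat$data[!mask$data] == 0))

  het <- list(corr_mm = 4, amplitude = 0.6)
  a <- generate_lesion_texture(mask, het, c(2, 8), seed = 7)
  b <- generate_lesion_texture(mask, het, c(2, 8), seed = 7)
  expect_identical(a$data, b$data)

  c2 <- generate_lesion_texture(mask, het, c(2, 8), seed = 8)
  expect_false(identical(a$data, c2$data))
  expect_equal(max(a$data), 8, tolerance = 1e-12)
  expect_equal(max(c2$data), 8, tolerance = 1e-12)
  expect_true(all(a$data[mask$data] > 0))

  empty <- voi_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1), degenerate = TRUE)
  expect_error(generate_lesion_texture(empty, het, c(2, 8)), "degenerate")
})

test_that("cohort construction respects the configured composition", {
  cfg <- cohort_config(n_patients = 10, responder_fraction = 0.5, seed = 123)
  coh <- generate_cohort(cfg)
  expect_length(coh$patients, 10)
  expect_equal(sum(coh$truth$true_label == "responder"), 5)
  # responders carry complete-response RCB categories, non-responders don't
  resp <- coh$truth$true_label == "responder"
  expect_true(all(coh$truth$rcb_category[resp] %in% c("RCB-0", "RCB-I")))
  expect_true(all(coh$truth$rcb_category[!resp] %in% c("RCB-II", "RCB-III")))
  # same seed regenerates the identical cohort
  coh2 <- generate_cohort(cfg)
  expect_identical(coh$truth, coh2$truth)
  expect_identical(coh$patients[[3]]$flt1$data, coh2$patients[[3]]$flt1$data)
})

test_that("label counts are conserved across seeds", {
  for (seed in c(2, 5, 11, 17)) {
    coh <- generate_cohort(cohort_config(n_patients = 7,
                                         responder_fraction = 0.6,
                                         seed = seed))
    expect_equal(sum(coh$truth$true_label == "responder"), round(7 * 0.6))
  }
})

test_that("a responder's lesion maximum declines by the drawn factor", {
  coh <- generate_cohort(cohort_config(n_patients = 4, seed = 31,
                                       responder_fraction = 1,
                                       responder_decline = c(0.5, 0.5)))
  for (p in coh$patients) {
    m1 <- max(p$flt1$data[p$lesion_mask$data])
    m2 <- max(p$flt2$data[p$lesion_mask$data])
    # halving up to background and multiplicative noise
    expect_equal(m2 / m1, 0.5, tolerance = 0.15)
  }
})

test_that("masks are valid: nonempty, disjoint from their mirror, shared grid", {
  coh <- generate_cohort(cohort_config(n_patients = 6, seed = 77))
  for (p in coh$patients) {
    expect_gt(sum(p$lesion_mask$data), 0)
    expect_false(any(p$lesion_mask$data & p$contralateral_mask$data))
    expect_identical(dim(p$flt1$data), dim(p$flt2$data))
    expect_equal(p$flt1$spacing, p$lesion_mask$spacing)
  }
  # both scanner geometries appear under the default mix
  expect_setequal(unique(coh$truth$scanner), c("A", "B"))
})

test_that("realized responder declines recover the configured range", {
  cfg <- cohort_config(n_patients = 30, seed = 99)
  coh <- generate_cohort(cfg)
  rt <- build_response_table(coh, resample = FALSE)
  merged <- dplyr::left_join(rt, coh$truth, by = "patient_id")
  mean_resp <- mean(merged$suv_max_change_pct[merged$true_label == "responder"])
  rng <- cfg$responder_decline * 100
  # Monte-Carlo slack of a few percent around the configured interval
  expect_gt(mean_resp, rng[1] - 5)
  expect_lt(mean_resp, rng[2] + 5)
})

test_that("percentage change of SUV_max separates the labels", {
  overlaps <- vapply(1:3, function(seed) {
    coh <- generate_cohort(cohort_config(n_patients = 30, seed = seed))
    rt <- build_response_table(coh, resample = FALSE)
    merged <- dplyr::left_join(rt, coh$truth, by = "patient_id")
    r <- merged$suv_max_change_pct[merged$true_label == "responder"]
    n <- merged$suv_max_change_pct[merged$true_label == "nonresponder"]
    # count patients on the wrong side of the midpoint threshold
    thr <- (min(r) + max(n)) / 2
    (sum(r < thr) + sum(n > thr)) / nrow(merged)
  }, numeric(1))
  expect_true(all(overlaps <= 0.05))
})

test_that("cohorts write a manifest and volumes to disk", {
  coh <- generate_cohort(cohort_config(n_patients = 2, seed = 15))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(coh, dir)
  expect_equal(nrow(manifest), 2)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "P01_flt1.nii.gz")))
  back <- read_volume(file.path(dir, "P02_flt2.nii.gz"))
  expect_equal(back$data, coh$patients[[2]]$flt2$data, tolerance = 1e-7)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(responder_fraction = 1.4), "fraction")
  expect_error(cohort_config(lesion_radius_mm = c(9, 5)), "range")
})
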