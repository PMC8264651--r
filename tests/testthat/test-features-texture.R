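test_that("GLCM of a constant block collapses to a single cell", {
  lev <- array(1L, c(3, 3, 3))
  disc <- make_disc_from_levels(lev, 2)
  f <- glcm_features(disc)
  expect_equal(f$GLCM_222_1JointAverage, 1)
  expect_equal(f$GLCM_222_1AutoCorrelation, 1)
  expect_equal(f$GLCM_222_1InformationMeasureCor1, 0)
})

test_that("GLCM on a 2x2 sheet matches hand enumeration", {
  lev <- array(NA_integer_, c(2, 2, 1))
  lev[1, 1, 1] <- 1L; lev[2, 1, 1] <- 2L
  lev[1, 2, 1] <- 1L; lev[2, 2, 1] <- 2L
  disc <- make_disc_from_levels(lev, 2)
  M <- glcm_matrix(disc)
  # ordered pairs: 4 cross-level along x and the two diagonals, 2 same-level
  # along y, per order
  expect_equal(M, matrix(c(2, 4, 4, 2), 2, 2))
  f <- glcm_features(disc)
  o <- oracle_glcm_features(lev, 2)
  expect_named_list_equal(f, o, tolerance = 1e-12)
})

test_that("checkerboard sum average is 3", {
  d <- c(4, 4, 4)
  idx <- array(seq_len(prod(d)), d)
  parity <- (slice.index(idx, 1) + slice.index(idx, 2) +
               slice.index(idx, 3)) %% 2
  lev <- array(ifelse(parity == 0, 1L, 2L), d)
  disc <- make_disc_from_levels(lev, 2)
  expect_equal(glcm_features(disc)$GLCM_222_1SumAverage, 3)
  expect_equal(oracle_glcm_features(lev, 2)$GLCM_222_1SumAverage, 3)
})

test_that("run lengths on a line follow the single-direction construction", {
  n <- 7
  lev <- array(1L, c(1, 1, n))
  disc <- make_disc_from_levels(lev, 2)
  dir_z <- matrix(c(0L, 0L, 1L), 1, 3)
  f <- glrlm_features(disc, directions = dir_z)
  expect_equal(f$GLRLM_LongRunEmphasis, n^2)
  expect_equal(f$GLRLM_RunPercentage, 1 / n)

  alt <- array(rep(c(1L, 2L), length.out = n), c(1, 1, n))
  fa <- glrlm_features(make_disc_from_levels(alt, 2), directions = dir_z)
  expect_equal(fa$GLRLM_ShortRunEmphasis, 1)
  expect_equal(fa$GLRLM_LongRunEmphasis, 1)
})

test_that("size-zone features follow the zone construction", {
  # one uniform zone
  one <- make_disc_from_levels(array(1L, c(3, 3, 2)), 2)
  expect_equal(glszm_features(one)$GLSZM_GLNonuniformity, 1)

  # two disjoint single-voxel zones of the same level
  lev <- array(NA_integer_, c(5, 1, 1))
  lev[1, 1, 1] <- 1L
  lev[5, 1, 1] <- 1L
  two <- make_disc_from_levels(lev, 2)
  expect_equal(glszm_features(two)$GLSZM_GLNonuniformity, 2)
  expect_equal(glszm_features(two)$GLSZM_LargeZoneHighGLEmpha, 1)
})

test_that("NGLDM dependence of a constant block interior voxel is 26", {
  lev <- array(1L, c(5, 5, 5))
  disc <- make_disc_from_levels(lev, 2)
  f <- ngldm_features(disc)
  o <- oracle_ngldm_features(lev)
  expect_named_list_equal(f, o, tolerance = 1e-12)
  expect_equal(f$NGLD_HighGLCountEmpha, 1)
})

test_that("NGTDM coarseness hits the guard value on a constant block", {
  disc <- make_disc_from_levels(array(3L, c(4, 4, 4)), 4)
  expect_equal(ngtdm_coarseness(disc), 1e6)
})

test_that("all texture families match brute-force oracles on random blocks", {
  dirs <- texture_directions()
  cases <- list(
    make_disc(c(4, 4, 4), 4, seed = 101),
    make_disc(c(5, 4, 3), 3, seed = 102, p_mask = 0.8),
    make_disc(c(5, 5, 5), 6, seed = 103, p_mask = 0.6),
    make_disc(c(3, 5, 4), 2, seed = 104)
  )
  for (disc in cases) {
    lev <- disc$levels
    ng <- disc$n_bins
    expect_equal(glcm_matrix(disc), oracle_glcm_matrix(lev, ng))
    expect_named_list_equal(glcm_features(disc),
                            oracle_glcm_features(lev, ng), tolerance = 1e-12)
    expect_equal(glrlm_matrix(disc), oracle_glrlm_matrix(lev, ng, dirs))
    expect_named_list_equal(glrlm_features(disc),
                            oracle_glrlm_features(lev, ng, dirs),
                            tolerance = 1e-12)
    expect_named_list_equal(glszm_features(disc), oracle_glszm_features(lev),
                            tolerance = 1e-12)
    expect_named_list_equal(gldzm_features(disc), oracle_gldzm_features(lev),
                            tolerance = 1e-12)
    expect_named_list_equal(ngldm_features(disc), oracle_ngldm_features(lev),
                            tolerance = 1e-12)
    expect_equal(ngtdm_coarseness(disc),
                 oracle_ngtdm_coarseness(lev, ng), tolerance = 1e-12)
  }
})

test_that("texture features are invariant under 90-degree grid rotation", {
  disc <- make_disc(c(5, 5, 5), 4, seed = 110, p_mask = 0.7)
  rot <- disc
  rot$levels <- aperm(disc$levels[, , 5:1], c(3, 2, 1)) # 90° about y
  for (fn in list(glcm_features, glrlm_features, glszm_features,
                  gldzm_features, ngldm_features)) {
    expect_named_list_equal(fn(rot), fn(disc), tolerance = 1e-12)
  }
  expect_equal(ngtdm_coarseness(rot), ngtdm_coarseness(disc),
               tolerance = 1e-12)
})

test_that("the full feature vector is complete, finite and deterministic", {
  pair <- make_lesion_pair(seed = 42)
  f1 <- extract_features(pair$vol, pair$mask)
  f2 <- extract_features(pair$vol, pair$mask)
  expect_identical(f1, f2)
  expect_true(all(is.finite(f1$value)))
  expect_setequal(f1$feature, feature_ids("all"))
  expect_true(all(feature_ids("robust_candidates") %in% f1$feature))
  expect_length(feature_ids("robust_candidates"), 42)
})
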