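# Small in-code fixtures shared across test files.

# spherical lesion with a smooth radial gradient in a quiet background
make_lesion_pair <- function(dim = c(24, 20, 20), spacing = c(2, 2, 2),
                             radius_mm = 9, suv_max = 8, bg = 0.5,
                             seed = 1) {
  set.seed(seed)
  centre <- dim * spacing / 4
  centre[2:3] <- dim[2:3] * spacing[2:3] / 2
  cx <- (seq_len(dim[1]) - 1) * spacing[1]
  cy <- (seq_len(dim[2]) - 1) * spacing[2]
  cz <- (seq_len(dim[3]) - 1) * spacing[3]
  r2 <- outer(outer((cx - centre[1])^2, (cy - centre[2])^2, `+`),
              (cz - centre[3])^2, `+`)
  mask <- array(r2 <= radius_mm^2, dim)
  lesion <- array(suv_max * exp(-r2 / (2 * (radius_mm / 1.5)^2)), dim)
  lesion[!mask] <- 0
  vol <- suv_volume(lesion + bg + array(rnorm(prod(dim), 0, 0.02), dim),
                    spacing)
  list(vol = vol, mask = voi_mask(mask, spacing))
}

make_disc_from_levels <- function(lev, n_g = max(lev, na.rm = TRUE)) {
  structure(list(levels = lev, n_bins = as.integer(n_g), range = c(0, 1),
                 spacing = c(1, 1, 1)),
            class = "discretized_voi")
}

# equality up to float accumulation order, judged on a max(1, |reference|)
# scale so that mathematically-zero quantities are compared absolutely
expect_named_list_equal <- function(got, want, tolerance = 1e-10) {
  for (nm in names(want)) {
    expect_true(nm %in% names(got), label = paste(nm, "present"))
    diff <- abs(unname(got[[nm]]) - unname(want[[nm]]))
    expect_lt(diff / max(1, abs(want[[nm]])), tolerance,
              label = paste(nm, "scaled difference"))
  }
}

ellipsoid_fixture <- function(radius_mm, dim = c(31, 31, 31),
                              spacing = c(1, 1, 1),
                              centre_frac = c(0.5, 0.5, 0.5)) {
  centre <- (dim - 1) * spacing * centre_frac
  cx <- (seq_len(dim[1]) - 1) * spacing[1]
  cy <- (seq_len(dim[2]) - 1) * spacing[2]
  cz <- (seq_len(dim[3]) - 1) * spacing[3]
  r2 <- outer(outer((cx - centre[1])^2, (cy - centre[2])^2, `+`),
              (cz - centre[3])^2, `+`)
  voi_mask(array(r2 <= radius_mm^2, dim), spacing)
}
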