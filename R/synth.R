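# Synthetic paired-timepoint FLT-PET cohorts with known ground truth. The
# generator emulates the acquisition setting the analysis is designed for:
# two scanner geometries, heterogeneous lesion uptake, and a between-timepoint
# uptake decline that separates responders from non-responders.

SCANNER_GEOMETRIES <- list(
  A = list(spacing = c(3.9, 3.9, 4.25), dim = c(42L, 30L, 26L)),
  B = list(spacing = c(4.1, 4.1, 3.0), dim = c(40L, 28L, 36L))
)

#' Synthetic cohort configuration
#'
#' Defaults describe the emulated study setting: 15 evaluable patients, 60%
#' pathological responders, two thirds of patients on scanner geometry A
#' (3.9 x 3.9 x 4.25 mm voxels) and the rest on geometry B (4.1 x 4.1 x 3.0
#' mm), T2-sized lesions (8-14 mm semi-axes), baseline lesion SUV_max between 3
#' and 10, and a fractional SUV decline after one chemotherapy cycle of
#' 0.40-0.70 for responders versus 0.00-0.10 for non-responders.
#'
#' @param n_patients number of patients (>= 1).
#' @param responder_fraction fraction of responders in `[0, 1]`.
#' @param scanner_mix fraction of patients on geometry A.
#' @param lesion_radius_mm range of ellipsoid semi-axes (mm).
#' @param baseline_suv_max range of baseline lesion SUV_max.
#' @param heterogeneity list with `corr_mm` (correlation length of the lesion
#'   texture field, mm) and `amplitude` (log-scale amplitude; 0 gives a
#'   homogeneous lesion).
#' @param responder_decline range of fractional SUV reduction for responders.
#' @param nonresponder_decline range for non-responders.
#' @param background_suv list with `mean` and `sd` of the additive Gaussian
#'   background SUV.
#' @param lesion_noise_sd sd of the multiplicative lognormal lesion noise
#'   (PET count noise is intensity-dependent).
#' @param seed integer seed for the cohort RNG stream.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 15,
                          responder_fraction = 0.6,
                          scanner_mix = 2 / 3,
                          lesion_radius_mm = c(8, 14),
                          baseline_suv_max = c(3, 10),
                          heterogeneity = list(corr_mm = 4, amplitude = 0.6),
                          responder_decline = c(0.40, 0.70),
                          nonresponder_decline = c(0.00, 0.10),
                          background_suv = list(mean = 0.6, sd = 0.08),
                          lesion_noise_sd = 0.05,
                          seed = 1L) {
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || x < 0 || x > 1) {
      stop("`", nm, "` must be a fraction in [0, 1]", call. = FALSE)
    }
  }
  chk_range <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 2 || x[1] > x[2]) {
      stop("`", nm, "` must be a low <= high range", call. = FALSE)
    }
  }
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("`n_patients` must be >= 1", call. = FALSE)
  }
  chk_frac(responder_fraction, "responder_fraction")
  chk_frac(scanner_mix, "scanner_mix")
  chk_range(lesion_radius_mm, "lesion_radius_mm")
  chk_range(baseline_suv_max, "baseline_suv_max")
  chk_range(responder_decline, "responder_decline")
  chk_range(nonresponder_decline, "nonresponder_decline")
  structure(list(n_patients = as.integer(n_patients),
                 responder_fraction = responder_fraction,
                 scanner_mix = scanner_mix,
                 lesion_radius_mm = lesion_radius_mm,
                 baseline_suv_max = baseline_suv_max,
                 heterogeneity = heterogeneity,
                 responder_decline = responder_decline,
                 nonresponder_decline = nonresponder_decline,
                 background_suv = background_suv,
                 lesion_noise_sd = lesion_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a heterogeneous lesion texture field
#'
#' Builds a smooth positive random field inside the mask: Gaussian white
#' noise smoothed with an isotropic Gaussian kernel of physical width
#' `corr_mm`, standardized over the mask, exponentiated with `amplitude`
#' (guaranteeing positivity) and scaled so the maximum in-mask voxel equals
#' the requested SUV maximum (`max(suv_range)`). Amplitude 0 yields a
#' constant field at that maximum. Deterministic for a fixed seed.
#'
#' @param shape_mask a nonempty [voi_mask()].
#' @param heterogeneity list with `corr_mm` and `amplitude`.
#' @param suv_range the requested SUV maximum is `max(suv_range)`.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return An [suv_volume()], zero outside the mask.
#' @export
generate_lesion_texture <- function(shape_mask, heterogeneity, suv_range,
                                    seed = NULL) {
  stopifnot(inherits(shape_mask, "voi_mask"))
  check_nonempty(shape_mask)
  if (!is.null(seed)) set.seed(seed)
  suv_max <- max(suv_range)
  if (suv_max <= 0) stop("requested SUV maximum must be positive", call. = FALSE)
  d <- dim(shape_mask$data)
  amp <- heterogeneity$amplitude
  if (amp > 0) {
    noise <- array(stats::rnorm(prod(d)), d)
    sm <- smooth_gaussian_fft(noise, heterogeneity$corr_mm / shape_mask$spacing)
    z <- sm[shape_mask$data]
    s <- stats::sd(z)
    z <- if (s > 0) (z - mean(z)) / s else z * 0
    field <- exp(amp * z)
  } else {
    field <- rep(1, sum(shape_mask$data))
  }
  out <- array(0, d)
  out[shape_mask$data] <- field * (suv_max / max(field))
  suv_volume(out, shape_mask$spacing, shape_mask$origin)
}

# Circular FFT Gaussian smoothing; sigma in voxels per axis. Wraparound is
# acceptable for a stationary noise field.
smooth_gaussian_fft <- function(arr, sigma_vox) {
  d <- dim(arr)
  k1d <- function(n, s) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  K <- outer(outer(k1d(d[1], sigma_vox[1]), k1d(d[2], sigma_vox[2])),
             k1d(d[3], sigma_vox[3]))
  dim(K) <- d
  Re(stats::fft(stats::fft(arr) * stats::fft(K), inverse = TRUE)) / prod(d)
}

#' Generate a synthetic paired-timepoint PET cohort
#'
#' Produces `n_patients` synthetic patients, each with a baseline volume
#' (`flt1`), a post-one-cycle volume (`flt2`), an ellipsoidal lesion mask and
#' the contralateral mirror mask. `round(n_patients * responder_fraction)`
#' patients are responders; a responder's lesion uptake at the second
#' timepoint is the baseline pattern scaled by `1 - d`, with `d` drawn from
#' `responder_decline` (non-responders from `nonresponder_decline`).
#' Residual-cancer-burden categories are assigned consistently with the true
#' label: responders RCB-0 (p = 0.9) or RCB-I, non-responders RCB-II
#' (p = 0.85) or RCB-III. One cohort RNG stream is split into per-patient
#' sub-streams so individual patients regenerate reproducibly.
#'
#' @param config a [cohort_config()].
#' @return An object of class `flt_cohort`: list with `patients` (list of
#'   per-patient records), `truth` (tibble of ground-truth parameters) and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  set.seed(config$seed)
  n_resp <- round(n * config$responder_fraction)
  labels <- sample(c(rep("responder", n_resp),
                     rep("nonresponder", n - n_resp)))
  n_a <- round(n * config$scanner_mix)
  scanners <- sample(c(rep("A", n_a), rep("B", n - n_a)))
  rcb_u <- stats::runif(n)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n)
  patients <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    p <- generate_patient(sprintf("P%02d", i), labels[i], scanners[i],
                          rcb_u[i], patient_seeds[i], config)
    patients[[i]] <- p
    truth[[i]] <- tibble::tibble(
      patient_id = p$patient_id, scanner = p$scanner,
      true_label = p$true_label, decline = p$decline,
      suv_max_true = p$suv_max_true, rcb_category = p$rcb_category,
      dose_MBq = p$dose_MBq, weight_kg = p$weight_kg
    )
  }
  structure(list(patients = patients,
                 truth = dplyr::bind_rows(truth),
                 config = config),
            class = "flt_cohort")
}

generate_patient <- function(patient_id, label, scanner, rcb_u, seed, config) {
  set.seed(seed)
  geom <- SCANNER_GEOMETRIES[[scanner]]
  d <- geom$dim
  sp <- geom$spacing
  fov <- d * sp
  weight <- stats::runif(1, 55, 85)
  dose <- min(3.5 * weight, 350)
  # lesion centred in the lateral quarter of the FOV so the mirrored
  # contralateral copy stays disjoint
  centre <- c(0.25 * fov[1] + stats::runif(1, -5, 5),
              0.5 * fov[2] + stats::runif(1, -6, 6),
              0.5 * fov[3] + stats::runif(1, -6, 6))
  radii <- stats::runif(3, config$lesion_radius_mm[1], config$lesion_radius_mm[2])
  mask_arr <- ellipsoid_mask(d, sp, centre, radii)
  lesion_mask <- voi_mask(mask_arr, sp, provenance = "original")
  suv_max <- stats::runif(1, config$baseline_suv_max[1],
                          config$baseline_suv_max[2])
  lesion1 <- generate_lesion_texture(lesion_mask, config$heterogeneity,
                                     suv_max, seed = NULL)
  rng <- if (label == "responder") config$responder_decline else
    config$nonresponder_decline
  decline <- stats::runif(1, rng[1], rng[2])
  sdl <- config$lesion_noise_sd
  noise2 <- array(stats::rlnorm(prod(d), meanlog = -sdl^2 / 2, sdlog = sdl), d)
  lesion2 <- lesion1$data * (1 - decline) * noise2
  bg <- function() {
    pmax(array(stats::rnorm(prod(d), config$background_suv$mean,
                            config$background_suv$sd), d), 0)
  }
  flt1 <- suv_volume(bg() + lesion1$data, sp)
  flt2 <- suv_volume(bg() + lesion2, sp)
  rcb <- if (label == "responder") {
    if (rcb_u < 0.9) "RCB-0" else "RCB-I"
  } else {
    if (rcb_u < 0.85) "RCB-II" else "RCB-III"
  }
  list(patient_id = patient_id, true_label = label, scanner = scanner,
       flt1 = flt1, flt2 = flt2, lesion_mask = lesion_mask,
       contralateral_mask = mirror_mask(lesion_mask),
       rcb_category = rcb, decline = decline, suv_max_true = suv_max,
       dose_MBq = dose, weight_kg = weight)
}

ellipsoid_mask <- function(dim, spacing, centre_mm, radii_mm) {
  cx <- (seq_len(dim[1]) - 1) * spacing[1]
  cy <- (seq_len(dim[2]) - 1) * spacing[2]
  cz <- (seq_len(dim[3]) - 1) * spacing[3]
  gx <- ((cx - centre_mm[1]) / radii_mm[1])^2
  gy <- ((cy - centre_mm[2]) / radii_mm[2])^2
  gz <- ((cz - centre_mm[3]) / radii_mm[3])^2
  array(outer(outer(gx, gy, `+`), gz, `+`) <= 1, dim)
}

#' @export
print.flt_cohort <- function(x, ...) {
  cat("<flt_cohort> ", length(x$patients), " patients (",
      sum(x$truth$true_label == "responder"), " responders), seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes each patient's volumes and masks as compressed NIfTI plus a cohort
#' manifest CSV (`patient_id, scanner, label, dose_MBq, weight_kg, rcb`).
#'
#' @param cohort an `flt_cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "flt_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients) {
    base <- file.path(dir, p$patient_id)
    write_volume(p$flt1, paste0(base, "_flt1.nii.gz"))
    write_volume(p$flt2, paste0(base, "_flt2.nii.gz"))
    write_volume(p$lesion_mask, paste0(base, "_lesion.nii.gz"))
    write_volume(p$contralateral_mask, paste0(base, "_contralateral.nii.gz"))
  }
  manifest <- dplyr::transmute(cohort$truth,
                               patient_id = .data$patient_id,
                               scanner = .data$scanner,
                               label = .data$true_label,
                               dose_MBq = .data$dose_MBq,
                               weight_kg = .data$weight_kg,
                               rcb = .data$rcb_category)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
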