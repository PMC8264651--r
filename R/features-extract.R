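# End-to-end feature extraction for one volume/mask pair and for cohorts with
# contour variants.

#' Feature identifiers
#'
#' `feature_ids("all")` lists every feature this package computes (46:
#' 3 SUV statistics, 18 intensity statistics, 3 IVH, local intensity peak and
#' 21 texture-matrix features). `feature_ids("robust_candidates")` is the
#' 42-feature panel screened for contour robustness (the full set minus
#' `ID_Mean`, `ID_Max`, `ID_Skewness`, `ID_Kurtosis`).
#'
#' @param set `"all"` or `"robust_candidates"`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(set = c("all", "robust_candidates")) {
  set <- match.arg(set)
  ids <- c(
    "SUV_max", "SUV_peak", "SUV_mean",
    "ID_Mean", "ID_Variance", "ID_Median", "ID_Min", "ID_Max",
    "ID_10thPercentile", "ID_90thPercentile", "ID_InterquartileRange",
    "ID_Range", "ID_MeanAbsoluteDeviation", "ID_RobustMeanAbsoluteDeviation",
    "ID_MedianAbsoluteDeviation", "ID_CoefficientOfVariation",
    "ID_QuartileCoefficientOfDispersion", "ID_Energy", "ID_RootMeanSquare",
    "ID_Skewness", "ID_Kurtosis",
    "IVH_VolumeIntFract_90", "IVH_IntensityVolFract_10",
    "IVH_AreaUnderIVHCurve",
    "LIF_LocalIntensityPeak",
    "GLCM_222_1JointAverage", "GLCM_222_1SumAverage",
    "GLCM_222_1AutoCorrelation", "GLCM_222_1InformationMeasureCor1",
    "GLRLM_ShortRunEmphasis", "GLRLM_LongRunEmphasis", "GLRLM_HighGLRunEmpha",
    "GLRLM_ShortRunHighGLEmpha", "GLRLM_LongRunHighGLEmpha",
    "GLRLM_GLNonuniformity", "GLRLM_RLNonuniformity", "GLRLM_RunPercentage",
    "GLSZM_LargeZoneHighGLEmpha", "GLSZM_GLNonuniformity",
    "GLDZM_GLNonuniformity", "GLDZM_ZDNonuniformity",
    "NGLD_HighGLCountEmpha", "NGLD_HighDepenHighFLEmpha",
    "NGLD_GLNonuniformity", "NGLD_DepCountNonuniformity",
    "NID_Coarseness"
  )
  if (set == "robust_candidates") {
    ids <- setdiff(ids, c("ID_Mean", "ID_Max", "ID_Skewness", "ID_Kurtosis"))
  }
  ids
}

#' Feature-extraction configuration
#'
#' Consolidates the extraction constants: 32 gray levels, 1 mm isotropic
#' resampling, and the bounding-box margin kept around the lesion (it must
#' cover the 6.2 mm SUV_peak sphere and the largest contour dilation).
#'
#' @param n_bins gray levels for discretization.
#' @param resample_mm isotropic target spacing (mm).
#' @param margin_mm crop margin around the mask bounding box (mm).
#' @param families feature families to compute; any of `"suv"`,
#'   `"intensity"`, `"ivh"`, `"lip"`, `"glcm"`, `"glrlm"`, `"glszm"`,
#'   `"gldzm"`, `"ngldm"`, `"ngtdm"`.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(n_bins = 32, resample_mm = 1.0, margin_mm = 8,
                           families = c("suv", "intensity", "ivh", "lip",
                                        "glcm", "glrlm", "glszm", "gldzm",
                                        "ngldm", "ngtdm")) {
  stopifnot(n_bins >= 2, resample_mm > 0, margin_mm >= 0)
  structure(list(n_bins = n_bins, resample_mm = resample_mm,
                 margin_mm = margin_mm, families = families),
            class = "feature_config")
}

#' Extract all features from one volume/mask pair
#'
#' Crops to the lesion bounding box (plus margin), resamples to the isotropic
#' target grid, discretizes to `n_bins` gray levels and computes the
#' configured feature families. Intensity (`ID_*`), SUV and IVH features are
#' computed on raw SUV values of the resampled grid; texture matrices on the
#' discretized levels.
#'
#' @param vol an [suv_volume()].
#' @param mask a [voi_mask()] on the same grid.
#' @param config a [feature_config()].
#' @param resample resample to the isotropic grid first (set `FALSE` when the
#'   input is already on the target grid, e.g. for perturbed contour
#'   variants of an already-resampled pair).
#' @param sphere optional precomputed sphere-mean field of `vol` (internal
#'   cache used when several contours of one volume are evaluated).
#' @return A tibble with columns `feature`, `value`.
#' @export
#' @examples
#' vol <- suv_volume(array(runif(12^3, 1, 4), c(12, 12, 12)), rep(1, 3))
#' msk <- voi_mask(array(TRUE, c(12, 12, 12)), rep(1, 3))
#' extract_features(vol, msk, feature_config(families = c("suv", "glcm")))
extract_features <- function(vol, mask, config = feature_config(),
                             resample = TRUE, sphere = NULL) {
  stopifnot(inherits(config, "feature_config"))
  if (mask$degenerate || !any(mask$data)) {
    stop("degenerate VOI: cannot extract features from an empty mask",
         call. = FALSE)
  }
  if (resample) {
    cropped <- crop_to_mask(vol, mask, margin_mm = config$margin_mm)
    rs <- resample_isotropic(cropped$vol, cropped$mask,
                             target_mm = config$resample_mm)
    vol <- rs$vol
    mask <- rs$mask
  }
  fam <- config$families
  out <- list()
  if (any(c("suv", "lip") %in% fam)) {
    # the SUV_peak search and the local intensity peak share one sphere
    # field, which depends on the volume only and may be passed in when the
    # caller evaluates several contours of the same volume
    if (is.null(sphere)) {
      sphere <- sphere_mean_field(vol$data, vol$spacing, SPHERE_RADIUS_MM)
    }
    vals <- vol$data[mask$data]
    if ("suv" %in% fam) {
      out <- c(out, list(SUV_max = max(vals), SUV_peak = max(sphere[mask$data]),
                         SUV_mean = mean(vals)))
    }
    if ("lip" %in% fam) {
      v <- vol$data
      v[!mask$data] <- -Inf
      out <- c(out, list(LIF_LocalIntensityPeak = sphere[which.max(v)]))
    }
  }
  if ("intensity" %in% fam) out <- c(out, intensity_features(vol, mask))
  if ("ivh" %in% fam) out <- c(out, ivh_features(vol, mask))
  texture_fams <- c("glcm", "glrlm", "glszm", "gldzm", "ngldm", "ngtdm")
  if (any(texture_fams %in% fam)) {
    # texture matrices only see in-mask voxels: shrink to the tight
    # bounding box (one-voxel border) before discretizing
    tight <- crop_to_mask(vol, mask, margin_mm = max(vol$spacing))
    disc <- discretize_fbn(tight$vol, tight$mask, n_bins = config$n_bins)
    if ("glcm" %in% fam) out <- c(out, glcm_features(disc))
    if ("glrlm" %in% fam) out <- c(out, glrlm_features(disc))
    if (any(c("glszm", "gldzm") %in% fam)) {
      zones <- gray_level_zones(disc, with_distance = "gldzm" %in% fam)
      if ("glszm" %in% fam) out <- c(out, glszm_features(disc, zones))
      if ("gldzm" %in% fam) out <- c(out, gldzm_features(disc, zones))
    }
    if ("ngldm" %in% fam) out <- c(out, ngldm_features(disc))
    if ("ngtdm" %in% fam) out <- c(out, list(NID_Coarseness = ngtdm_coarseness(disc)))
  }
  tibble::tibble(feature = names(out), value = unname(unlist(out)))
}

#' Extract features for the four contour variants
#'
#' Resamples the pair to the isotropic grid once, then perturbs the resampled
#' contour by each margin in `deltas_mm` (0 = original) and extracts features
#' per variant. Perturbation after resampling makes a +/-1 mm margin exactly
#' one voxel on the default 1 mm grid. Variants emptied by erosion are
#' dropped with a warning.
#'
#' @inheritParams extract_features
#' @param deltas_mm signed perturbation margins; 0 is the original contour.
#' @return A tibble with columns `contour_variant`, `feature`, `value`.
#' @export
extract_variant_features <- function(vol, mask, config = feature_config(),
                                     deltas_mm = c(0, 1, 2, -1)) {
  cropped <- crop_to_mask(vol, mask,
                          margin_mm = config$margin_mm + max(deltas_mm, 0))
  rs <- resample_isotropic(cropped$vol, cropped$mask,
                           target_mm = config$resample_mm)
  sphere <- if (any(c("suv", "lip") %in% config$families)) {
    sphere_mean_field(rs$vol$data, rs$vol$spacing, SPHERE_RADIUS_MM)
  }
  purrr::map_dfr(deltas_mm, function(dm) {
    m <- if (dm == 0) rs$mask else perturb_mask(rs$mask, dm)
    if (m$degenerate || !any(m$data)) {
      warning("contour variant ", variant_label(dm),
              " emptied the mask; dropped", call. = FALSE)
      return(tibble::tibble(contour_variant = character(),
                            feature = character(), value = numeric()))
    }
    extract_features(rs$vol, m, config, resample = FALSE, sphere = sphere) |>
      dplyr::mutate(contour_variant = variant_label(dm), .before = 1)
  })
}

variant_label <- function(delta_mm) {
  if (delta_mm == 0) "original" else sprintf("%+gmm", delta_mm)
}
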