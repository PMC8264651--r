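# First-order feature families: SUV statistics, intensity statistics (ID_*),
# intensity-volume histogram (IVH_*) and the local intensity peak. All operate
# on raw (undiscretized) SUV values; only texture matrices and the IVH use the
# 32-bin quantization elsewhere in the pipeline.

SPHERE_RADIUS_MM <- 6.2 # 1 cm^3 sphere: (4/3) * pi * 6.2^3 ~ 998 mm^3

#' SUV statistics inside a lesion VOI
#'
#' `SUV_max` and `SUV_mean` are the in-mask maximum and mean. `SUV_peak` is
#' the mean over a 1 cm^3 sphere (radius 6.2 mm, voxels whose centres lie
#' within the radius, intersected with the volume), centred on the voxel that
#' maximizes that sphere mean among in-mask centres.
#'
#' @param vol an [suv_volume()].
#' @param mask a [voi_mask()] on the same grid.
#' @param peak_radius_mm sphere radius for `SUV_peak` in mm.
#' @return A named list with `SUV_max`, `SUV_mean`, `SUV_peak`.
#' @export
suv_statistics <- function(vol, mask, peak_radius_mm = SPHERE_RADIUS_MM) {
  stopifnot(inherits(vol, "suv_volume"), inherits(mask, "voi_mask"))
  check_same_grid(vol, mask)
  check_nonempty(mask)
  vals <- vol$data[mask$data]
  sphere <- sphere_mean_field(vol$data, vol$spacing, peak_radius_mm)
  list(SUV_max = max(vals),
       SUV_mean = mean(vals),
       SUV_peak = max(sphere[mask$data]))
}

#' Local intensity peak
#'
#' Mean intensity in a 1 cm^3 sphere centred at the global in-mask maximum
#' voxel (first such voxel in array order on ties).
#'
#' @inheritParams suv_statistics
#' @return A single numeric value.
#' @export
local_intensity_peak <- function(vol, mask, peak_radius_mm = SPHERE_RADIUS_MM) {
  stopifnot(inherits(vol, "suv_volume"), inherits(mask, "voi_mask"))
  check_same_grid(vol, mask)
  check_nonempty(mask)
  v <- vol$data
  v[!mask$data] <- -Inf
  centre <- which.max(v)
  sphere <- sphere_mean_field(vol$data, vol$spacing, peak_radius_mm)
  sphere[centre]
}

# Sphere-neighbourhood mean at every voxel, edge-corrected (the sphere is
# intersected with the volume). Computed by FFT convolution of the zero-padded
# array and a binary ball kernel; the parallel convolution of an all-ones
# array yields the per-voxel in-volume sphere counts.
sphere_mean_field <- function(arr, spacing, radius_mm) {
  d <- dim(arr)
  kr <- floor(radius_mm / spacing)
  offs <- rbind(c(0L, 0L, 0L), ball_offsets(spacing, radius_mm))
  n <- d + 2L * kr
  A <- array(0, n); A[seq_len(d[1]) , seq_len(d[2]), seq_len(d[3])] <- arr
  O <- array(0, n); O[seq_len(d[1]) , seq_len(d[2]), seq_len(d[3])] <- 1
  K <- array(0, n)
  K[cbind((offs[, 1] %% n[1]) + 1L,
          (offs[, 2] %% n[2]) + 1L,
          (offs[, 3] %% n[3]) + 1L)] <- 1
  fk <- stats::fft(K)
  conv <- function(x) {
    Re(stats::fft(stats::fft(x) * fk, inverse = TRUE)) / prod(n)
  }
  sums <- conv(A)[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
  cnts <- round(conv(O)[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])])
  sums / cnts
}

#' Intensity-based statistics (ID_* family)
#'
#' Standard first-order statistics of the raw in-mask SUV distribution.
#' Moments are population moments (denominator n); kurtosis is excess
#' kurtosis. `ID_RobustMeanAbsoluteDeviation` is the mean absolute deviation
#' of the values lying in `[P10, P90]` about their own mean;
#' `ID_MedianAbsoluteDeviation` is the mean absolute deviation about the
#' median. `ID_CoefficientOfVariation` is population-sd / mean and
#' `ID_QuartileCoefficientOfDispersion` is `(P75 - P25) / (P75 + P25)`.
#'
#' @inheritParams suv_statistics
#' @return Named list of the 18 `ID_*` statistics.
#' @export
intensity_features <- function(vol, mask) {
  stopifnot(inherits(vol, "suv_volume"), inherits(mask, "voi_mask"))
  check_same_grid(vol, mask)
  check_nonempty(mask)
  x <- vol$data[mask$data]
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  xr <- x[x >= q[1] & x <= q[5]]
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 - 3 else 0
  list(
    ID_Mean = mu,
    ID_Variance = m2,
    ID_Median = q[3],
    ID_Min = min(x),
    ID_Max = max(x),
    ID_10thPercentile = q[1],
    ID_90thPercentile = q[5],
    ID_InterquartileRange = q[4] - q[2],
    ID_Range = max(x) - min(x),
    ID_MeanAbsoluteDeviation = mean(abs(x - mu)),
    ID_RobustMeanAbsoluteDeviation = mean(abs(xr - mean(xr))),
    ID_MedianAbsoluteDeviation = mean(abs(x - q[3])),
    ID_CoefficientOfVariation = if (mu != 0) sqrt(m2) / mu else 0,
    ID_QuartileCoefficientOfDispersion =
      if (q[4] + q[2] != 0) (q[4] - q[2]) / (q[4] + q[2]) else 0,
    ID_Energy = sum(x^2),
    ID_RootMeanSquare = sqrt(mean(x^2)),
    ID_Skewness = skew,
    ID_Kurtosis = kurt
  )
}

#' Intensity-volume histogram features
#'
#' Uses the fractional intensity `gamma(x) = (x - min) / (max - min)` of the
#' in-mask values (defined as 1 everywhere for a constant VOI).
#' `IVH_VolumeIntFract_90` is the volume fraction with `gamma >= 0.90`;
#' `IVH_IntensityVolFract_10` is the smallest fractional intensity attained by
#' the top 10% of voxels by intensity; `IVH_AreaUnderIVHCurve` is the mean,
#' over a fine grid of fractional-intensity thresholds, of the volume fraction
#' at or above each threshold.
#'
#' @inheritParams suv_statistics
#' @param volume_threshold fractional-intensity threshold for the volume
#'   fraction feature (default 0.90).
#' @param intensity_fraction top volume fraction for the intensity feature
#'   (default 0.10).
#' @param grid_n number of thresholds in the AUC grid.
#' @return Named list of the three `IVH_*` features.
#' @export
ivh_features <- function(vol, mask, volume_threshold = 0.90,
                         intensity_fraction = 0.10, grid_n = 1000) {
  stopifnot(inherits(vol, "suv_volume"), inherits(mask, "voi_mask"))
  check_same_grid(vol, mask)
  check_nonempty(mask)
  x <- vol$data[mask$data]
  n <- length(x)
  rng <- max(x) - min(x)
  gam <- if (rng > 0) (x - min(x)) / rng else rep(1, n)
  v90 <- mean(gam >= volume_threshold - 1e-12)
  k <- max(1L, ceiling(intensity_fraction * n))
  i10 <- sort(gam, decreasing = TRUE)[k]
  thr <- seq(0, 1, length.out = grid_n + 1)
  auc <- mean(vapply(thr, function(g) mean(gam >= g - 1e-12), numeric(1)))
  list(IVH_VolumeIntFract_90 = v90,
       IVH_IntensityVolFract_10 = i10,
       IVH_AreaUnderIVHCurve = auc)
}

#' Fixed-bin-number gray-level discretization
#'
#' Quantizes the in-mask intensities to `n_bins` levels between the in-mask
#' minimum and maximum: `level = 1 + floor(n_bins * (x - min) / (max - min))`,
#' with the maximum mapped to `n_bins`. A constant VOI maps to level 1
#' everywhere.
#'
#' @inheritParams suv_statistics
#' @param n_bins number of gray levels (default 32).
#' @return A `discretized_voi`: list with `levels` (integer array, `NA`
#'   outside the mask), `n_bins`, `range` and `spacing`.
#' @export
discretize_fbn <- function(vol, mask, n_bins = 32) {
  stopifnot(inherits(vol, "suv_volume"), inherits(mask, "voi_mask"))
  check_same_grid(vol, mask)
  check_nonempty(mask)
  x <- vol$data
  lo <- min(x[mask$data]); hi <- max(x[mask$data])
  lev <- array(NA_integer_, dim(x))
  if (hi > lo) {
    l <- 1L + as.integer(floor(n_bins * (x[mask$data] - lo) / (hi - lo)))
    l[l > n_bins] <- as.integer(n_bins)
    lev[mask$data] <- l
  } else {
    lev[mask$data] <- 1L
  }
  structure(list(levels = lev, n_bins = as.integer(n_bins),
                 range = c(lo, hi), spacing = mask$spacing),
            class = "discretized_voi")
}

#' @export
print.discretized_voi <- function(x, ...) {
  cat("<discretized_voi> ", sum(!is.na(x$levels)), " voxels, ",
      x$n_bins, " bins over [", signif(x$range[1], 4), ", ",
      signif(x$range[2], 4), "]\n", sep = "")
  invisible(x)
}
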