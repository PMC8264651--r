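# Grid geometry: isotropic resampling, contour perturbation, mirroring.
# Voxel-centre convention throughout: voxel i sits at origin + (i - 1) * spacing.

#' Resample a volume and mask to an isotropic grid
#'
#' Interpolates the volume trilinearly onto a `target_mm` isotropic grid and
#' the mask linearly with a 0.5 threshold (volume-preserving in expectation).
#' The physical extent of the input grid is preserved to within one voxel.
#' Resampling to 1 mm harmonizes the two acquisition geometries before
#' texture analysis.
#'
#' @param vol an [suv_volume()].
#' @param mask a [voi_mask()] on the same grid.
#' @param target_mm isotropic target spacing in mm (default 1).
#' @return A list with elements `vol` and `mask` on the new grid.
#' @export
resample_isotropic <- function(vol, mask, target_mm = 1.0) {
  stopifnot(inherits(vol, "suv_volume"), inherits(mask, "voi_mask"))
  check_same_grid(vol, mask)
  check_nonempty(mask)
  d <- dim(vol$data)
  extent <- d * vol$spacing
  nd <- pmax(1L, as.integer(round(extent / target_mm)))
  # centre the new grid on the physical centre of the old one
  old_centre <- vol$origin + (d - 1) * vol$spacing / 2
  new_spacing <- rep(target_mm, 3)
  new_origin <- old_centre - (nd - 1) * new_spacing / 2
  v <- interp_trilinear(vol$data, vol$spacing, vol$origin, nd, new_spacing,
                        new_origin)
  m <- interp_trilinear(array(as.numeric(mask$data), d), vol$spacing,
                        vol$origin, nd, new_spacing, new_origin) >= 0.5
  if (!any(m)) {
    stop("degenerate VOI: mask empty after resampling", call. = FALSE)
  }
  list(vol = suv_volume(v, new_spacing, new_origin),
       mask = voi_mask(m, new_spacing, new_origin,
                       provenance = mask$provenance))
}

# Trilinear interpolation of `arr` (grid: spacing/origin) onto a new grid.
# Sample points outside the source grid are clamped to the border voxel.
interp_trilinear <- function(arr, spacing, origin, new_dim, new_spacing,
                             new_origin) {
  d <- dim(arr)
  # continuous (0-based) source index of each new voxel centre, per axis
  ax <- lapply(1:3, function(k) {
    (new_origin[k] + (seq_len(new_dim[k]) - 1) * new_spacing[k] -
       origin[k]) / spacing[k]
  })
  gx <- rep(ax[[1]], times = new_dim[2] * new_dim[3])
  gy <- rep(rep(ax[[2]], each = new_dim[1]), times = new_dim[3])
  gz <- rep(ax[[3]], each = new_dim[1] * new_dim[2])
  clamp <- function(v, hi) pmin(pmax(v, 0), hi)
  gx <- clamp(gx, d[1] - 1); gy <- clamp(gy, d[2] - 1); gz <- clamp(gz, d[3] - 1)
  x0 <- floor(gx); y0 <- floor(gy); z0 <- floor(gz)
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  at <- function(ix, iy, iz) arr[1 + ix + d[1] * (iy + d[2] * iz)]
  out <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    at(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
    at(x1, y1, z0) * fx * fy * (1 - fz) +
    at(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    at(x1, y0, z1) * fx * (1 - fy) * fz +
    at(x0, y1, z1) * (1 - fx) * fy * fz +
    at(x1, y1, z1) * fx * fy * fz
  array(out, new_dim)
}

#' Perturb a contour by a signed margin in mm
#'
#' Euclidean distance-threshold morphology, spacing-aware: dilation
#' (`delta_mm > 0`) adds every voxel whose centre lies within `delta_mm` of a
#' foreground voxel centre; erosion (`delta_mm < 0`) keeps voxels whose whole
#' `|delta_mm|`-ball stays in the foreground. Used to build the four contour
#' variants (original, +1 mm, +2 mm, -1 mm) of the robustness analysis. An
#' erosion that empties the mask returns a `degenerate` mask rather than an
#' error so that cohort pipelines can drop and log the variant.
#'
#' @param mask a [voi_mask()].
#' @param delta_mm signed margin in mm; 0 returns the mask unchanged.
#' @return A [voi_mask()] with provenance `"dilated+<d>mm"` / `"eroded-<d>mm"`.
#' @export
perturb_mask <- function(mask, delta_mm) {
  stopifnot(inherits(mask, "voi_mask"))
  if (delta_mm == 0) return(mask)
  r <- abs(delta_mm)
  offs <- ball_offsets(mask$spacing, r)
  if (delta_mm > 0) {
    out <- mask_dilate(mask$data, offs)
    prov <- sprintf("dilated+%gmm", r)
  } else {
    out <- !mask_dilate(!mask$data, offs)
    prov <- sprintf("eroded-%gmm", r)
  }
  voi_mask(out, mask$spacing, mask$origin, provenance = prov,
           degenerate = !any(out))
}

# integer voxel offsets whose physical length is <= r mm (excluding 0,0,0)
ball_offsets <- function(spacing, r) {
  rng <- lapply(spacing, function(s) seq(-floor(r / s), floor(r / s)))
  g <- expand.grid(dx = rng[[1]], dy = rng[[2]], dz = rng[[3]])
  dist2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  g <- g[dist2 <= r^2 + 1e-9 & dist2 > 0, , drop = FALSE]
  as.matrix(g)
}

mask_dilate <- function(m, offs) {
  out <- m
  for (i in seq_len(nrow(offs))) {
    out <- out | shift_array(m, offs[i, ], fill = FALSE)
  }
  out
}

# out[v] = a[v + off]; voxels shifted in from outside get `fill`
shift_array <- function(a, off, fill = NA) {
  d <- dim(a)
  out <- array(fill, d)
  i1 <- pmax(1, 1 - off)
  i2 <- pmin(d, d - off)
  if (any(i1 > i2)) return(out)
  out[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]] <-
    a[(i1[1] + off[1]):(i2[1] + off[1]),
      (i1[2] + off[2]):(i2[2] + off[2]),
      (i1[3] + off[3]):(i2[3] + off[3])]
  out
}

#' Mirror a mask across the volume midline
#'
#' Reflects the mask across the mid-plane of the grid perpendicular to
#' `axis` (default x, the left-right axis), producing the contralateral
#' background VOI: the lesion contour copied onto the opposite breast.
#' Reflection about the geometric midline is an involution and preserves the
#' voxel count exactly.
#'
#' @param mask a [voi_mask()].
#' @param axis axis perpendicular to the mirror plane: 1 = x, 2 = y, 3 = z.
#' @return A [voi_mask()] with provenance `"mirrored"`.
#' @export
mirror_mask <- function(mask, axis = 1) {
  stopifnot(inherits(mask, "voi_mask"), axis %in% 1:3)
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(dim(mask$data)[axis]))
  out <- do.call(`[`, c(list(mask$data), idx))
  voi_mask(array(out, dim(mask$data)), mask$spacing, mask$origin,
           provenance = "mirrored", degenerate = !any(out))
}

# Crop volume+mask to the mask bounding box plus a physical margin (mm).
# Feature extraction uses this to keep resampled arrays small while retaining
# enough context for the SUV_peak sphere and contour dilation.
crop_to_mask <- function(vol, mask, margin_mm = 8) {
  check_same_grid(vol, mask)
  check_nonempty(mask)
  d <- dim(mask$data)
  idx <- which(mask$data, arr.ind = TRUE)
  pad <- ceiling(margin_mm / mask$spacing)
  lo <- pmax(1, apply(idx, 2, min) - pad)
  hi <- pmin(d, apply(idx, 2, max) + pad)
  sub <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  new_origin <- vol$origin + (lo - 1) * vol$spacing
  list(vol = suv_volume(sub(vol$data), vol$spacing, new_origin),
       mask = voi_mask(sub(mask$data), mask$spacing, new_origin,
                       provenance = mask$provenance))
}
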