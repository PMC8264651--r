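#' SUV volume objects
#'
#' An `suv_volume` is a 3D scalar field of standardized uptake values (SUV,
#' dimensionless) on a regular voxel grid. The grid is described by the voxel
#' spacing in mm along (x, y, z) and the physical position of the first voxel
#' centre (`origin`, mm). Spacing metadata is authoritative; the array axis
#' order is always (x, y, z).
#'
#' @param data numeric 3D array of SUV values; must be finite.
#' @param spacing numeric length-3, voxel spacing in mm; strictly positive.
#' @param origin numeric length-3, physical coordinate (mm) of the centre of
#'   voxel (1, 1, 1).
#'
#' @return An object of class `suv_volume`: a list with elements `data`,
#'   `spacing`, `origin`.
#' @export
#' @examples
#' vol <- suv_volume(array(1, c(4, 4, 4)), spacing = c(2, 2, 2))
#' vol
suv_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as_array3d(data, "data")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive finite values (mm)", call. = FALSE)
  }
  if (length(origin) != 3 || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("SUV volume data must be finite", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "suv_volume")
}

#' Volume-of-interest mask objects
#'
#' A `voi_mask` is a binary 3D mask on the same voxel grid as its companion
#' [suv_volume()]. The `provenance` field records how the contour was
#' obtained: the original delineation, a morphological perturbation of it
#' (`"dilated+1mm"`, `"dilated+2mm"`, `"eroded-1mm"`), or the contralateral
#' mirror copy (`"mirrored"`). A mask left empty by erosion is permitted but
#' flagged via `degenerate = TRUE`.
#'
#' @param data 3D array coercible to logical; `TRUE`/1 marks foreground.
#' @inheritParams suv_volume
#' @param provenance character tag describing the contour's origin.
#' @param degenerate logical; `TRUE` when a perturbation emptied the mask.
#'
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(data, spacing, origin = c(0, 0, 0),
                     provenance = "original", degenerate = FALSE) {
  data <- as_array3d(data, "data")
  storage.mode(data) <- "logical"
  data[is.na(data)] <- FALSE
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive finite values (mm)", call. = FALSE)
  }
  if (!any(data) && !degenerate) {
    stop("mask has no foreground voxels; pass degenerate = TRUE to allow",
         call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, origin = origin,
                 provenance = as.character(provenance)[1],
                 degenerate = isTRUE(degenerate)),
            class = "voi_mask")
}

as_array3d <- function(x, what) {
  x <- as.array(x)
  if (length(dim(x)) != 3) {
    stop("`", what, "` must be a 3D array, got ", length(dim(x)),
         " dimension(s)", call. = FALSE)
  }
  x
}

#' @export
print.suv_volume <- function(x, ...) {
  cat("<suv_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "), " mm\n",
      "  SUV range: [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("<voi_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "), " mm, ",
      sum(x$data), " foreground (", x$provenance,
      if (x$degenerate) ", DEGENERATE" else "", ")\n", sep = "")
  invisible(x)
}

#' Physical volume of a mask
#'
#' @param mask a [voi_mask()].
#' @return Foreground volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  sum(mask$data) * prod(mask$spacing)
}

# Shared grid check used by every (volume, mask) operation.
check_same_grid <- function(vol, mask) {
  if (!identical(dim(vol$data), dim(mask$data))) {
    stop("volume and mask dimensions differ", call. = FALSE)
  }
  if (max(abs(vol$spacing - mask$spacing)) > 1e-6) {
    stop("volume and mask spacing differ", call. = FALSE)
  }
  invisible(TRUE)
}

check_nonempty <- function(mask) {
  if (!any(mask$data)) {
    stop("degenerate VOI: mask has no foreground voxels", call. = FALSE)
  }
  invisible(TRUE)
}
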