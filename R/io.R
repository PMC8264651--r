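#' Read a 3D volume from NIfTI or NRRD
#'
#' Reads a scalar 3D volume with its grid metadata. The format is chosen by
#' file extension: `.nii` / `.nii.gz` are parsed with RNifti, `.nrrd` with a
#' built-in reader for raw-encoded NRRD. The payload must be 3D; 4D files are
#' rejected.
#'
#' @param path file path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return An [suv_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    return(read_nrrd(path))
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) {
    img <- array(img[, , , 1], d[1:3])
    d <- d[1:3]
  } else if (length(d) != 3) {
    stop("expected a 3D payload, got ", length(d), "D in ", path, call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("missing or invalid voxel spacing in ", path, call. = FALSE)
  }
  # we write axis-aligned positive-diagonal xforms, so the translation column
  # of the stored affine is the coordinate of the first voxel centre
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- xf_origin(xf, c(0, 0, 0))
  suv_volume(array(as.numeric(img), d), spacing = spacing, origin = origin)
}

xf_origin <- function(xf, fallback) {
  if (inherits(xf, "try-error") || is.null(xf)) return(fallback)
  tr <- as.numeric(xf[1:3, 4])
  if (any(!is.finite(tr))) fallback else tr
}

#' Write a 3D volume to NIfTI or NRRD
#'
#' @param vol an [suv_volume()] or [voi_mask()]. Masks are written as unsigned
#'   8-bit 0/1 volumes.
#' @param path destination ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  is_mask <- inherits(vol, "voi_mask")
  if (!is_mask && !inherits(vol, "suv_volume")) {
    stop("`vol` must be an suv_volume or voi_mask", call. = FALSE)
  }
  arr <- if (is_mask) array(as.integer(vol$data), dim(vol$data)) else vol$data
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    return(write_nrrd(arr, vol$spacing, vol$origin, path))
  }
  img <- RNifti::asNifti(arr)
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::pixdim(img) <- vol$spacing
  datatype <- if (is_mask) "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# Minimal NRRD (raw encoding, little endian) support. Covers the subset of
# the format this package writes; detached headers and compressed encodings
# are out of scope.
write_nrrd <- function(arr, spacing, origin, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  type <- if (is.integer(arr)) "int" else "double"
  hdr <- c(
    "NRRD0004",
    "# Complete NRRD file format specification at:",
    "# http://teem.sourceforge.net/nrrd/format.html",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(dim(arr), collapse = " ")),
    paste0("space directions: ",
           sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   spacing[1], spacing[2], spacing[3])),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    paste0("space origin: ",
           sprintf("(%.17g,%.17g,%.17g)", origin[1], origin[2], origin[3])),
    ""
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(arr), con,
           size = if (type == "int") 4L else 8L, endian = "little")
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0) stop("truncated NRRD header in ", path, call. = FALSE)
    if (line == "") break
    if (grepl("^#", line) || grepl("^NRRD", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[trimws(kv[2])]] <- trimws(kv[3])
  }
  dimn <- as.integer(fields[["dimension"]])
  if (!identical(dimn, 3L)) {
    stop("expected a 3D NRRD payload, got dimension ", dimn, call. = FALSE)
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (!identical(fields[["encoding"]], "raw")) {
    stop("only raw NRRD encoding is supported", call. = FALSE)
  }
  type <- fields[["type"]]
  nums <- function(s) as.numeric(regmatches(s, gregexpr("-?[0-9.eE+]+", s))[[1]])
  sd <- nums(fields[["space directions"]])
  spacing <- c(sd[1], sd[5], sd[9])
  if (is.null(fields[["space directions"]]) || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop("missing or invalid voxel spacing in ", path, call. = FALSE)
  }
  origin <- if (is.null(fields[["space origin"]])) c(0, 0, 0) else
    nums(fields[["space origin"]])
  n <- prod(sizes)
  vals <- switch(type,
    "int" = readBin(con, "integer", n = n, size = 4L, endian = "little"),
    "double" = readBin(con, "double", n = n, size = 8L, endian = "little"),
    "float" = readBin(con, "double", n = n, size = 4L, endian = "little"),
    "uchar" = readBin(con, "integer", n = n, size = 1L, signed = FALSE),
    stop("unsupported NRRD type: ", type, call. = FALSE)
  )
  suv_volume(array(as.numeric(vals), sizes), spacing = spacing, origin = origin)
}

#' Read a mask file as a `voi_mask`
#'
#' @inheritParams read_volume
#' @param provenance provenance tag for the loaded contour.
#' @return A [voi_mask()].
#' @export
read_mask <- function(path, provenance = "original") {
  vol <- read_volume(path)
  voi_mask(vol$data > 0.5, spacing = vol$spacing, origin = vol$origin,
           provenance = provenance, degenerate = !any(vol$data > 0.5))
}

#' Convert activity concentration to SUV
#'
#' SUV normalizes tissue activity concentration by injected dose per body
#' weight: `SUV = activity[kBq/ml] * weight[kg] / dose[MBq]`, unit-consistent
#' because MBq/kg is kBq/g and tissue density is taken as 1 g/ml. Activity is
#' assumed already decay-corrected by the scanner.
#'
#' @param activity_kbq_per_ml 3D array of activity concentration (kBq/ml).
#' @param injected_dose_mbq injected dose in MBq; > 0.
#' @param body_weight_kg body weight in kg; > 0.
#' @param spacing voxel spacing in mm.
#' @param origin grid origin in mm.
#' @return An [suv_volume()] of body-weight SUV values.
#' @export
#' @examples
#' suv <- activity_to_suv(array(5, c(2, 2, 2)), 350, 70, spacing = c(4, 4, 4))
#' max(suv$data) # 1.0
activity_to_suv <- function(activity_kbq_per_ml, injected_dose_mbq,
                            body_weight_kg, spacing, origin = c(0, 0, 0)) {
  if (!is.numeric(injected_dose_mbq) || injected_dose_mbq <= 0) {
    stop("`injected_dose_mbq` must be > 0", call. = FALSE)
  }
  if (!is.numeric(body_weight_kg) || body_weight_kg <= 0) {
    stop("`body_weight_kg` must be > 0", call. = FALSE)
  }
  arr <- as_array3d(activity_kbq_per_ml, "activity_kbq_per_ml")
  suv_volume(arr * body_weight_kg / injected_dose_mbq,
             spacing = spacing, origin = origin)
}
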