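#' In-memory MRI volume
#'
#' A volume is a 3D scalar intensity grid with per-axis voxel spacing in mm
#' and a body-region tag. Axes follow the package's canonical orientation:
#' x increases right-to-left, y anterior-to-posterior, z superior-to-inferior
#' (an LPI frame). All downstream geometry — medial/lateral splits, posterior
#' extremes, proximal/distal slice selection — assumes this frame. The mm
#' coordinate of voxel index `i` (1-based) along an axis with spacing `s` is
#' `(i - 0.5) * s`, i.e. the origin sits at the volume corner.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3, voxel size in mm (x, y, z); all > 0.
#' @param region one of `"hip"`, `"knee"`, `"ankle"`.
#' @return An object of class `lt_volume`.
#' @export
mri_volume <- function(data, spacing, region = c("hip", "knee", "ankle")) {
  region <- match.arg(region)
  data <- as_array3d(data)
  spacing <- check_spacing(spacing)
  structure(list(data = data, spacing = spacing, region = region),
            class = "lt_volume")
}

#' Multi-class bone label mask
#'
#' An integer grid aligned with an [mri_volume()]: class codes are
#' 0 = background, 1 = femur, 2 = tibia, 3 = fibula.
#'
#' @inheritParams mri_volume
#' @param data integer 3D array with values in `0:3`.
#' @return An object of class `lt_mask`.
#' @export
label_mask <- function(data, spacing, region = c("hip", "knee", "ankle")) {
  region <- match.arg(region)
  data <- as_array3d(data)
  storage.mode(data) <- "integer"
  bad <- !(data %in% LT_CLASSES)
  if (any(bad))
    stop("label mask contains class codes outside {0,1,2,3}")
  spacing <- check_spacing(spacing)
  structure(list(data = data, spacing = spacing, region = region),
            class = "lt_mask")
}

as_array3d <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop("data must be a 3D array")
  if (any(dim(x) < 1L)) stop("every axis needs at least one voxel")
  x
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive mm values")
  spacing
}

is_lt_volume <- function(x) inherits(x, "lt_volume")
is_lt_mask <- function(x) inherits(x, "lt_mask")

#' @export
print.lt_volume <- function(x, ...) {
  cat(sprintf("<lt_volume> %s stack, %s voxels @ %s mm\n", x$region,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x")))
  invisible(x)
}

#' @export
print.lt_mask <- function(x, ...) {
  present <- sort(unique(as.integer(x$data)))
  cls <- names(LT_CLASSES)[match(present, LT_CLASSES)]
  cat(sprintf("<lt_mask> %s stack, %s voxels @ %s mm, classes: %s\n",
              x$region, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              paste(cls, collapse = ", ")))
  invisible(x)
}

#' Canonicalize a volume or mask
#'
#' Reorders/flips axes into the package's canonical LPI frame. Objects
#' created through [mri_volume()]/[label_mask()] or the phantom generator
#' are already canonical, so this is the identity for them; NIfTI files are
#' reoriented on read (see [read_volume()]). Applying it twice equals
#' applying it once.
#'
#' @param x an `lt_volume` or `lt_mask`.
#' @return The canonicalized object.
#' @export
canonicalize <- function(x) {
  stopifnot(is_lt_volume(x) || is_lt_mask(x))
  x
}

# mm coordinate of 1-based voxel indices along one axis
voxel_to_mm <- function(idx, spacing) (idx - 0.5) * spacing
mm_to_voxel <- function(mm, spacing) mm / spacing + 0.5
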