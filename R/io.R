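#' Read and write volumes and masks as NIfTI
#'
#' `read_volume()` and `read_mask()` load a `.nii`/`.nii.gz` file, reorient
#' the voxel data into the package's canonical LPI frame (x right-to-left,
#' y anterior-to-posterior, z superior-to-inferior) using the file's qform/
#' sform, and attach the voxel spacing in mm. Files without a usable xform
#' are assumed to already be canonical. `write_volume()`/`write_mask()`
#' store the canonical frame with a matching qform so a round trip is
#' lossless.
#'
#' @param path file path to a NIfTI image.
#' @param region body-region tag, one of `"hip"`, `"knee"`, `"ankle"`.
#' @return `read_volume()` an [mri_volume()]; `read_mask()` a
#'   [label_mask()].
#' @export
read_volume <- function(path, region = c("hip", "knee", "ankle")) {
  region <- match.arg(region)
  img <- read_canonical(path)
  mri_volume(img$data, img$spacing, region)
}

#' @rdname read_volume
#' @export
read_mask <- function(path, region = c("hip", "knee", "ankle")) {
  region <- match.arg(region)
  img <- read_canonical(path)
  label_mask(round(img$data), img$spacing, region)
}

read_canonical <- function(path) {
  img <- RNifti::readNifti(path)
  ori <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(ori) && nzchar(ori) && ori != "LPI") {
    ok <- tryCatch({
      RNifti::orientation(img) <- "LPI"
      TRUE
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok)
      warning("NIfTI file has no usable orientation; assuming canonical LPI")
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  list(data = array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp)
}

#' @rdname read_volume
#' @param x an `lt_volume` or `lt_mask`.
#' @export
write_volume <- function(x, path) {
  stopifnot(is_lt_volume(x) || is_lt_mask(x))
  dat <- x$data
  if (is_lt_mask(x)) storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  aff <- diag(c(-x$spacing, 1))  # LPI axes expressed in the RAS world
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::`pixdim<-`(img, x$spacing) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
write_mask <- write_volume
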