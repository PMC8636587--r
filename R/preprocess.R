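#' Resample a volume or mask to a new voxel spacing
#'
#' Grid-aligned resampling onto `round(shape * spacing / target_spacing)`
#' voxels (round-half-away-from-zero, minimum one voxel per axis). Voxel
#' centres are corner-aligned, so mm coordinates are preserved. Intensity
#' volumes are interpolated trilinearly; label masks use nearest-neighbour
#' so class codes are never mixed. The default target is the protocol's median
#' acquisition spacing of 0.6 x 0.6 x 6.5 mm.
#'
#' @param x an `lt_volume` or `lt_mask`.
#' @param target_spacing numeric length-3 target voxel size in mm.
#' @return An object of the same class as `x` on the new grid.
#' @export
lt_resample <- function(x, target_spacing = c(0.6, 0.6, 6.5)) {
  stopifnot(is_lt_volume(x) || is_lt_mask(x))
  ts <- check_spacing(target_spacing)
  d <- dim(x$data)
  new_d <- pmax(1L, as.integer(round_half_away(d * x$spacing / ts)))
  # output voxel (0-based) i maps to input coords (i + .5) * ts/ss - .5
  sc <- ts / x$spacing
  A <- cbind(diag(sc), (sc - 1) / 2)
  mode <- if (is_lt_mask(x)) 1L else 0L
  dat <- resample_affine(x$data + 0, new_d, A, mode, clamp = 1L)
  if (is_lt_mask(x)) label_mask(dat, ts, x$region)
  else mri_volume(dat, ts, x$region)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Z-score intensity normalization
#'
#' Rescales the whole grid to mean 0 and standard deviation 1 (population
#' SD). A constant volume has no scale and returns all zeros rather than
#' erroring, so degenerate synthetic inputs do not abort batch runs.
#'
#' @param volume an `lt_volume`.
#' @return The normalized `lt_volume`.
#' @export
normalize_intensity <- function(volume) {
  stopifnot(is_lt_volume(volume))
  v <- volume$data
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  volume$data <- if (s == 0) array(0, dim(v)) else (v - m) / s
  volume
}

#' Pad a volume or mask to a shape multiple
#'
#' Symmetrically zero-pads each axis to the smallest multiple of
#' `pad_multiple` that is at least the original length (the U-net needs
#' in-plane extents divisible by its cumulative pooling factor). The
#' original extents and pad offsets are kept in the `lt_pad` attribute so
#' [lt_unpad()] can map predictions back to the native grid bit-exactly.
#'
#' @param x an `lt_volume` or `lt_mask`.
#' @param pad_multiple integer length-3, each >= 1; default `c(32, 32, 1)`
#'   matches the depth-6 in-plane pooling plan (2^5) with an essentially
#'   unpooled z-axis.
#' @return Padded object carrying an `lt_pad` attribute.
#' @export
crop_or_pad <- function(x, pad_multiple = c(32L, 32L, 1L)) {
  stopifnot(is_lt_volume(x) || is_lt_mask(x))
  pm <- as.integer(pad_multiple)
  if (length(pm) != 3L || any(pm < 1L)) stop("pad_multiple must be >= 1 per axis")
  d <- dim(x$data)
  target <- ceiling(d / pm) * pm
  lo <- (target - d) %/% 2L
  out <- array(if (is_lt_mask(x)) 0L else 0, target)
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <-
    x$data
  x$data <- out
  attr(x, "lt_pad") <- list(lo = lo, native_dim = d)
  x
}

#' @rdname crop_or_pad
#' @param pad optional pad record; taken from `attr(x, "lt_pad")` when
#'   missing.
#' @export
lt_unpad <- function(x, pad = NULL) {
  stopifnot(is_lt_volume(x) || is_lt_mask(x))
  if (is.null(pad)) pad <- attr(x, "lt_pad")
  if (is.null(pad)) stop("no pad record available")
  d <- pad$native_dim
  lo <- pad$lo
  x$data <- x$data[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]),
                   lo[3] + seq_len(d[3]), drop = FALSE]
  attr(x, "lt_pad") <- NULL
  x
}

#' Split a bilateral mask into left and right limbs
#'
#' Both limbs share each acquired stack. Foreground connected components
#' (any bone class, 6-connectivity) are assigned to the left or right limb
#' by the side of their centroid relative to the volume's x midline; in the
#' canonical frame x increases right-to-left, so centroids below the
#' midline belong to the right limb. Each output keeps only its side's
#' voxels on the full grid. If every component falls on one side the other
#' output is empty and flagged (`attr(., "lt_warn")`).
#'
#' @param mask an `lt_mask` with at least one foreground voxel.
#' @return A list with elements `left` and `right`, both `lt_mask`.
#' @export
split_limbs <- function(mask) {
  stopifnot(is_lt_mask(mask))
  fg <- mask$data > 0L
  if (!any(fg)) stop("mask has no foreground voxels")
  lab <- label_components(fg)
  n <- max(lab)
  mid <- (dim(mask$data)[1] + 1) / 2
  keep_left <- array(FALSE, dim(mask$data))
  keep_right <- array(FALSE, dim(mask$data))
  for (k in seq_len(n)) {
    sel <- lab == k
    cx <- mean(((which(sel) - 1L) %% dim(mask$data)[1]) + 1L)
    if (cx < mid) keep_right[sel] <- TRUE else keep_left[sel] <- TRUE
  }
  mk <- function(keep) {
    out <- mask
    out$data[!keep] <- 0L
    if (!any(keep)) attr(out, "lt_warn") <- "no component on this side"
    out
  }
  list(left = mk(keep_left), right = mk(keep_right))
}

#' Standard preprocessing for segmentation
#'
#' Resample to the target spacing, z-score normalize, and pad to the
#' network's divisibility requirement; the returned object keeps the
#' records needed to map a predicted mask back to the native grid.
#'
#' @param volume an `lt_volume`.
#' @param target_spacing mm triple, see [lt_resample()].
#' @param pad_multiple integer triple, see [crop_or_pad()].
#' @param normalize apply [normalize_intensity()]?
#' @return Preprocessed `lt_volume` with attributes `lt_pad` and
#'   `lt_native` (native dims and spacing).
#' @export
preprocess_volume <- function(volume, target_spacing = c(0.6, 0.6, 6.5),
                              pad_multiple = c(32L, 32L, 1L),
                              normalize = TRUE) {
  stopifnot(is_lt_volume(volume))
  native <- list(dim = dim(volume$data), spacing = volume$spacing)
  out <- lt_resample(volume, target_spacing)
  if (normalize) out <- normalize_intensity(out)
  out <- crop_or_pad(out, pad_multiple)
  attr(out, "lt_native") <- native
  out
}
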