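#' Axial reference line
#'
#' A reference line lives in one axial slice: a slice index, a 2D unit
#' direction in the (x, y) plane, and one or more anchor landmarks in both
#' voxel and mm coordinates. Four kinds exist: `proximal_femoral` (femoral
#' neck axis), `distal_femoral` and `proximal_tibial` (posterior condylar
#' lines), and `distal_tibial` (tibio-fibular centroid line).
#'
#' @param kind line kind string.
#' @param slice 1-based axial slice index.
#' @param direction length-2 numeric; normalized to unit length.
#' @param anchors_mm matrix of anchor points (columns x, y, mm) on the
#'   slice.
#' @param spacing voxel spacing of the source grid.
#' @param warn optional warning flag string.
#' @return An object of class `lt_refline`.
#' @export
reference_line <- function(kind, slice, direction, anchors_mm, spacing,
                           warn = NULL) {
  n <- sqrt(sum(direction^2))
  if (n == 0) stop("reference line direction must be nonzero")
  anchors_mm <- rbind(anchors_mm)
  structure(list(kind = kind, slice = as.integer(slice),
                 direction = direction / n,
                 anchors_mm = anchors_mm,
                 anchors_vox = cbind(mm_to_voxel(anchors_mm[, 1], spacing[1]),
                                     mm_to_voxel(anchors_mm[, 2], spacing[2])),
                 warn = warn),
            class = "lt_refline")
}

#' @export
print.lt_refline <- function(x, ...) {
  cat(sprintf("<lt_refline> %s, slice %d, direction (%.3f, %.3f)%s\n",
              x$kind, x$slice, x$direction[1], x$direction[2],
              if (!is.null(x$warn)) paste0(" [", x$warn, "]") else ""))
  invisible(x)
}

# Largest connected component of one bone class; smaller fragments are
# segmentation noise and are ignored.
largest_component <- function(mask, bone) {
  code <- LT_CLASSES[[bone]]
  bin <- mask$data == code
  if (!any(bin)) stop(sprintf("missing bone: no %s voxels in %s mask",
                              bone, mask$region))
  lab <- label_components(bin)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# limb side from the component centroid relative to the grid x midline
# (canonical x increases right-to-left)
infer_side <- function(bin) {
  d <- dim(bin)
  cx <- mean(((which(bin) - 1L) %% d[1]) + 1L)
  if (cx < (d[1] + 1) / 2) "right" else "left"
}

slice_xy_mm <- function(bin, k, spacing) {
  idx <- which(bin[, , k], arr.ind = TRUE)
  if (!is.matrix(idx)) idx <- rbind(idx)
  cbind(voxel_to_mm(idx[, 1], spacing[1]), voxel_to_mm(idx[, 2], spacing[2]))
}

hull_area_mm2 <- function(xy) {
  if (nrow(xy) < 3L) return(0)
  h <- chull(xy)
  hx <- xy[h, 1]; hy <- xy[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

max_diameter_mm <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  h <- if (nrow(xy) > 3L) xy[chull(xy), , drop = FALSE] else xy
  max(stats::dist(h))
}

#' Femoral head centre
#'
#' The head centre is the centre of the largest sphere inscribed in the
#' femur mask, restricted to the proximal half of the femur's z-extent
#' (the restriction excludes distal structures while keeping a compact
#' proximal mask, whose inscribed centre sits exactly at the half
#' boundary, admissible): the location of the maximum of the anisotropic
#' 3D Euclidean distance transform. Ties are broken toward the most
#' proximal slice, then the most medial voxel. The inscribed radius
#' doubles as the head radius used by the neck-slice criterion.
#'
#' @param mask a single-limb hip `lt_mask` with a nonempty femur class.
#' @param side `"left"`, `"right"`, or `NULL` to infer from the mask's
#'   position relative to the grid midline.
#' @return List with `mm` (x, y, z mm), `vox` (1-based indices),
#'   `radius_mm` (inscribed-sphere radius), and `side`.
#' @export
femoral_head_center <- function(mask, side = NULL) {
  stopifnot(is_lt_mask(mask))
  bin <- largest_component(mask, "femur")
  side <- side %||% infer_side(bin)
  d <- dim(bin)
  zs <- range(which(apply(bin, 3, any)))
  zmax_prox <- zs[1] + (zs[2] - zs[1]) / 2
  edt2 <- edt3d_sq(bin, mask$spacing)
  edt2[, , seq_len(d[3]) > zmax_prox] <- -1
  best <- max(edt2)
  cand <- index_to_xyz(which(edt2 == best), d)
  cand <- cand[cand[, "z"] == min(cand[, "z"]), , drop = FALSE]
  medial_x <- if (side == "right") max(cand[, "x"]) else min(cand[, "x"])
  cand <- cand[cand[, "x"] == medial_x, , drop = FALSE]
  vox <- cand[1, ]
  list(mm = c(voxel_to_mm(vox[1], mask$spacing[1]),
              voxel_to_mm(vox[2], mask$spacing[2]),
              voxel_to_mm(vox[3], mask$spacing[3])),
       vox = vox, radius_mm = sqrt(best), side = side)
}

#' Proximal femoral reference line (femoral neck axis)
#'
#' Starting from the femoral head centre's slice and moving distally, the
#' first slice whose femur cross-section (the in-plane component containing
#' the head projection) has a maximum in-plane diameter of at least
#' `diam_factor` times the head diameter is selected — the most proximal
#' slice on which head, neck, and trochanter are jointly visible. The neck
#' axis is the major principal axis (second-moment eigenvector) of that
#' cross-section, oriented from the lateral end toward the head. If no
#' slice meets the criterion the slice maximizing the diameter is used and
#' flagged; a rotationally degenerate cross-section is flagged and falls
#' back to the x axis.
#'
#' @inheritParams femoral_head_center
#' @param head optional precomputed [femoral_head_center()] result.
#' @param diam_factor slice-selection multiple of the head diameter.
#' @return An `lt_refline` of kind `proximal_femoral`.
#' @export
proximal_femoral_line <- function(mask, head = NULL, side = NULL,
                                  diam_factor = 1.6) {
  stopifnot(is_lt_mask(mask))
  bin <- largest_component(mask, "femur")
  head <- head %||% femoral_head_center(mask, side)
  head_diam <- 2 * head$radius_mm
  d <- dim(bin)
  zk <- head$vox[3]:max(which(apply(bin, 3, any)))
  diam <- rep(0, length(zk))
  comp_cache <- vector("list", length(zk))
  for (i in seq_along(zk)) {
    k <- zk[i]
    if (!any(bin[, , k])) next
    sl <- array(bin[, , k], c(d[1], d[2], 1L))
    lab <- label_components(sl)[, , 1]
    hl <- lab[head$vox[1], head$vox[2]]
    if (hl == 0L) {
      # head projection off the bone: nearest in-plane component
      idx <- which(lab > 0L, arr.ind = TRUE)
      dd <- (voxel_to_mm(idx[, 1], mask$spacing[1]) - head$mm[1])^2 +
        (voxel_to_mm(idx[, 2], mask$spacing[2]) - head$mm[2])^2
      hl <- lab[idx[which.min(dd), 1], idx[which.min(dd), 2]]
    }
    sel <- lab == hl
    xy <- cbind(voxel_to_mm(which(sel, arr.ind = TRUE)[, 1], mask$spacing[1]),
                voxel_to_mm(which(sel, arr.ind = TRUE)[, 2], mask$spacing[2]))
    comp_cache[[i]] <- xy
    diam[i] <- max_diameter_mm(xy)
  }
  ok <- which(diam >= diam_factor * head_diam)
  warn <- NULL
  if (length(ok)) {
    i <- ok[1]
  } else {
    i <- which.max(diam)
    warn <- "no slice met the neck-diameter criterion; using widest slice"
  }
  xy <- comp_cache[[i]]
  ctr <- colMeans(xy)
  cov <- stats::cov(xy)
  ev <- eigen(cov, symmetric = TRUE)
  if ((ev$values[1] - ev$values[2]) / max(ev$values[1], 1e-12) < 0.02) {
    dir <- c(1, 0)
    warn <- paste(c(warn, "degenerate cross-section moments; using x axis"),
                  collapse = "; ")
  } else {
    dir <- ev$vectors[, 1]
  }
  # orient from the lateral end toward the head side
  if (sum(dir * (head$mm[1:2] - ctr)) < 0) dir <- -dir
  reference_line("proximal_femoral", zk[i], dir,
                 rbind(head$mm[1:2], ctr), mask$spacing, warn)
}

#' Condylar slice selection
#'
#' Returns the axial slice maximizing the spacing-weighted area of the 2D
#' convex hull of the bone's cross-section — the image "with the largest
#' convex bone area". Exact ties go to the more distal slice for the femur
#' and the more proximal slice for the tibia.
#'
#' @param mask a single-limb knee `lt_mask`.
#' @param bone `"femur"` or `"tibia"`.
#' @return 1-based slice index.
#' @export
select_condylar_slice <- function(mask, bone = c("femur", "tibia")) {
  bone <- match.arg(bone)
  stopifnot(is_lt_mask(mask))
  bin <- largest_component(mask, bone)
  areas <- vapply(seq_len(dim(bin)[3]), function(k) {
    if (!any(bin[, , k])) return(0)
    hull_area_mm2(slice_xy_mm(bin, k, mask$spacing))
  }, numeric(1))
  ties <- which(areas == max(areas))
  if (bone == "femur") max(ties) else min(ties)
}

#' Posterior condylar reference line
#'
#' On the selected condylar slice, the cross-section is split into medial
#' and lateral halves by the line through its centroid perpendicular to the
#' cross-section's major principal axis; the most posterior extension of
#' each half (the maximal-y voxel row) gives a condylar point, and the line
#' connects the two, oriented medial-to-lateral. For an unrotated knee the
#' principal axis is the x axis and the split is the vertical line through
#' the centroid; using the principal axis keeps the split equivariant when
#' the anatomy is rotated in-plane, where a fixed vertical split would let
#' the posterior lobe leak across the midline. The condylar point is the
#' centroid of the posterior band of the half — all voxels within
#' `posterior_band_mm` of the half's maximal y. For a rounded condyle this
#' is a sub-voxel estimate of the posterior pole that is stable under
#' in-plane rotation and robust to voxel-scale protrusions from imperfect
#' segmentations; a single maximal-y voxel (or the end of a tied row)
#' would move by half a chord width or jump onto a segmentation bump.
#'
#' @inheritParams select_condylar_slice
#' @param slice slice index; defaults to [select_condylar_slice()].
#' @param side limb side, inferred from the mask when `NULL`.
#' @param posterior_band_mm depth of the posterior band whose centroid is
#'   the condylar point; the default `NULL` uses `max(2, 2.5 * spacing_y)`
#'   mm so the band always spans several voxel rows.
#' @return An `lt_refline` of kind `distal_femoral` (femur) or
#'   `proximal_tibial` (tibia).
#' @export
posterior_condylar_line <- function(mask, bone = c("femur", "tibia"),
                                    slice = NULL, side = NULL,
                                    posterior_band_mm = NULL) {
  bone <- match.arg(bone)
  stopifnot(is_lt_mask(mask))
  bin <- largest_component(mask, bone)
  side <- side %||% infer_side(bin)
  slice <- slice %||% select_condylar_slice(mask, bone)
  posterior_band_mm <- posterior_band_mm %||% max(2, 2.5 * mask$spacing[2])
  xy <- slice_xy_mm(bin, slice, mask$spacing)
  if (nrow(xy) == 0L) stop("empty cross-section on the selected slice")
  ctr <- colMeans(xy)
  ev <- eigen(stats::cov(xy), symmetric = TRUE)
  e1 <- if ((ev$values[1] - ev$values[2]) / max(ev$values[1], 1e-12) < 0.02)
    c(1, 0) else axis_rep(ev$vectors[, 1])
  if (abs(e1[1]) < abs(e1[2]))
    stop("degenerate anatomy: cross-section elongated anteroposteriorly, not a condylar pair")
  t <- (xy[, 1] - ctr[1]) * e1[1] + (xy[, 2] - ctr[2]) * e1[2]
  halves <- list(lo = xy[t < 0, , drop = FALSE],
                 hi = xy[t > 0, , drop = FALSE])
  if (any(vapply(halves, nrow, 1L) == 0L))
    stop("degenerate anatomy: cross-section has an empty medial or lateral half")
  pick <- function(h) {
    post <- h[h[, 2] >= max(h[, 2]) - posterior_band_mm, , drop = FALSE]
    colMeans(post)
  }
  p_lo <- pick(halves$lo)
  p_hi <- pick(halves$hi)
  # canonical x increases right-to-left: medial is +x for right limbs,
  # and e1 is normalized to positive x
  if (side == "right") {
    med <- p_hi; lat <- p_lo
  } else {
    med <- p_lo; lat <- p_hi
  }
  kind <- if (bone == "femur") "distal_femoral" else "proximal_tibial"
  reference_line(kind, slice, lat - med, rbind(med, lat), mask$spacing)
}

#' Distal tibial reference line (tibio-fibular centroid line)
#'
#' Selects the most distal slice on which both the tibial and fibular
#' cross-sections reach `min_area_mm2`, and connects the two cross-section
#' centroids, oriented tibia-to-fibula. If no slice satisfies the area
#' requirement the most distal slice where both bones are present is used
#' and flagged.
#'
#' @param mask a single-limb ankle `lt_mask` with nonempty tibia and
#'   fibula classes.
#' @param min_area_mm2 minimum cross-section area per bone.
#' @return An `lt_refline` of kind `distal_tibial`.
#' @export
distal_tibial_line <- function(mask, min_area_mm2 = 25) {
  stopifnot(is_lt_mask(mask))
  tib <- largest_component(mask, "tibia")
  fib <- largest_component(mask, "fibula")
  vox_mm2 <- mask$spacing[1] * mask$spacing[2]
  a_t <- apply(tib, 3, sum) * vox_mm2
  a_f <- apply(fib, 3, sum) * vox_mm2
  ok <- which(a_t >= min_area_mm2 & a_f >= min_area_mm2)
  warn <- NULL
  if (!length(ok)) {
    ok <- which(a_t > 0 & a_f > 0)
    if (!length(ok)) stop("missing bone: tibia and fibula never share a slice")
    warn <- "no slice met the minimum-area criterion; using most distal shared slice"
  }
  k <- max(ok)
  ct <- colMeans(slice_xy_mm(tib, k, mask$spacing))
  cf <- colMeans(slice_xy_mm(fib, k, mask$spacing))
  if (all(cf == ct)) stop("degenerate anatomy: coincident centroids")
  reference_line("distal_tibial", k, cf - ct, rbind(ct, cf), mask$spacing,
                 warn)
}
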