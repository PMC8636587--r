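#' Parametric lower-limb bone phantom specification
#'
#' Defines a single-limb synthetic MRI study (hip, knee, and ankle stacks)
#' with analytically known torsion. The femur is assembled from a head
#' ball, a horizontal neck cylinder whose axial direction is rotated by
#' `femoral_torsion` degrees anterior to the condylar tangent, a greater
#' trochanter, a vertical shaft, and two equal-radius posterior condylar
#' lobes whose common posterior tangent is the distal femoral reference
#' line. The tibia mirrors this with its own condylar lobes (tangent
#' parallel to the femoral one) and shaft; at the ankle a thin fibular
#' cylinder is placed so the tibio-fibular centroid line realizes
#' `tibial_torsion` (external positive) against the proximal tibial
#' tangent. Equal-radius lobes make the posterior tangent, and hence every
#' reference line, exactly recoverable from the voxelized mask.
#'
#' Geometry defaults approximate adolescent lower-limb anatomy (mm):
#' femoral head radius 10.5, neck length 25, condylar lobe radii 13/12,
#' condylar half-separations 16/14, fibular offset 22. Grids default to
#' a torsional MRI acquisition: 29 axial slices per joint at
#' 0.6 x 0.6 x 6.5 mm with both-limb-capable field of view; the intensity
#' model is bright bone (1.0) on dark background (0.0) plus optional
#' Gaussian noise and k-space/bias-field artifacts.
#'
#' @param femoral_torsion,tibial_torsion degrees, in (-90, 90); antetorsion
#'   and external tibial torsion positive.
#' @param side `"right"` or `"left"`.
#' @param head_radius,neck_length,neck_radius,trochanter_radius,shaft_radius
#'   femoral geometry, mm.
#' @param condyle_radius_femur,condyle_radius_tibia,condyle_halfsep_femur,condyle_halfsep_tibia
#'   condylar lobe radii and half-separations, mm.
#' @param tibia_radius_ankle,fibula_radius,fibula_offset ankle geometry, mm.
#' @param spacing voxel size mm (x, y, z).
#' @param slices axial slices per stack.
#' @param inplane in-plane grid extent in voxels (square).
#' @param scale multiplier applied to every geometric parameter (radii,
#'   lengths, separations); use < 1 to fit small training patches.
#' @param noise_sd additive Gaussian intensity noise SD.
#' @param artifact optional artifact family for the intensity volumes, one
#'   of `"motion"`, `"ghosting"`, `"spiking"`, `"bias_field"`.
#' @param stack_rotation named degrees `c(hip=, knee=, ankle=)`: external
#'   in-plane rotation applied to that stack's whole construction (used for
#'   rotation-invariance and differential-rotation experiments).
#' @param seed integer seed driving noise and artifacts.
#' @return An object of class `lt_phantom_spec`.
#' @export
phantom_spec <- function(femoral_torsion = 15, tibial_torsion = 30,
                         side = c("right", "left"),
                         head_radius = 10.5, neck_length = 25,
                         neck_radius = 6.5, trochanter_radius = 9,
                         shaft_radius = 8,
                         condyle_radius_femur = 13, condyle_radius_tibia = 12,
                         condyle_halfsep_femur = 16,
                         condyle_halfsep_tibia = 14,
                         tibia_radius_ankle = 11, fibula_radius = 5,
                         fibula_offset = 22,
                         spacing = c(0.6, 0.6, 6.5), slices = 29L,
                         inplane = 256L, scale = 1,
                         noise_sd = 0, artifact = NULL,
                         stack_rotation = c(hip = 0, knee = 0, ankle = 0),
                         seed = NULL) {
  side <- match.arg(side)
  spec <- list(femoral_torsion = femoral_torsion,
               tibial_torsion = tibial_torsion, side = side,
               head_radius = head_radius, neck_length = neck_length,
               neck_radius = neck_radius,
               trochanter_radius = trochanter_radius,
               shaft_radius = shaft_radius,
               condyle_radius_femur = condyle_radius_femur,
               condyle_radius_tibia = condyle_radius_tibia,
               condyle_halfsep_femur = condyle_halfsep_femur,
               condyle_halfsep_tibia = condyle_halfsep_tibia,
               tibia_radius_ankle = tibia_radius_ankle,
               fibula_radius = fibula_radius, fibula_offset = fibula_offset,
               spacing = check_spacing(spacing), slices = as.integer(slices),
               inplane = as.integer(inplane), noise_sd = noise_sd,
               artifact = artifact,
               stack_rotation = resolve_stack_rotation(stack_rotation),
               seed = seed)
  geom <- c("head_radius", "neck_length", "neck_radius", "trochanter_radius",
            "shaft_radius", "condyle_radius_femur", "condyle_radius_tibia",
            "condyle_halfsep_femur", "condyle_halfsep_tibia",
            "tibia_radius_ankle", "fibula_radius", "fibula_offset")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive number")
  spec[geom] <- lapply(spec[geom], function(v) v * scale)
  if (any(unlist(spec[geom]) <= 0))
    stop("all geometric parameters must be positive")
  if (abs(femoral_torsion) >= 90 || abs(tibial_torsion) >= 90)
    stop("torsion angles must lie in (-90, 90) degrees")
  if (spec$slices < 8L || spec$inplane < 32L)
    stop("grid too small for the phantom anatomy")
  if (!is.null(artifact) &&
      !artifact %in% c("motion", "ghosting", "spiking", "bias_field"))
    stop("unknown artifact family: ", artifact)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(spec, class = "lt_phantom_spec")
}

resolve_stack_rotation <- function(rot) {
  out <- c(hip = 0, knee = 0, ankle = 0)
  if (is.null(names(rot)) && length(rot) == 1L) rot <- rep(rot, 3L)
  if (is.null(names(rot)) && length(rot) == 3L) names(rot) <- names(out)
  out[names(rot)] <- rot
  out
}

# external in-plane rotation for a right limb (canonical LPI frame)
rot2 <- function(v, theta_deg) {
  th <- theta_deg * pi / 180
  c(cos(th) * v[1] + sin(th) * v[2], -sin(th) * v[1] + cos(th) * v[2])
}

#' Generate a synthetic lower-limb phantom
#'
#' Rasterizes the three stacks of a [phantom_spec()] onto their voxel grids
#' (primitives evaluated at voxel centres) and returns paired intensity
#' volumes and label masks plus the analytic ground truth: head centre,
#' neck axis, condylar tangent directions, distal centroid-line direction,
#' and the constructed torsion angles. Deterministic given `spec$seed`.
#'
#' @param spec an [phantom_spec()] object.
#' @return An `lt_phantom`: list with elements `hip`, `knee`, `ankle`
#'   (each `list(volume, mask)`), `truth`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "lt_phantom_spec"))
  stacks <- list()
  truth <- list(side = spec$side,
                femoral_torsion = spec$femoral_torsion,
                tibial_torsion = spec$tibial_torsion)
  for (region in LT_REGIONS) {
    built <- build_stack(spec, region)
    truth <- c(truth, built$truth)
    vol <- built$intensity
    base_seed <- if (is.null(spec$seed)) 0 else as.numeric(spec$seed)
    stack_seed <- (base_seed * 7 + match(region, LT_REGIONS)) %% 2147483647
    if (spec$noise_sd > 0 || !is.null(spec$artifact)) {
      vol <- with_seed_(stack_seed, {
        v <- vol
        if (!is.null(spec$artifact))
          v <- apply_artifact(v, spec$artifact,
                              seed = (stack_seed + 101) %% 2147483647)
        if (spec$noise_sd > 0)
          v$data <- v$data + array(rnorm(length(v$data), sd = spec$noise_sd),
                                   dim(v$data))
        v
      })
    }
    stacks[[region]] <- list(volume = vol, mask = built$mask)
  }
  structure(c(stacks, list(truth = truth, spec = spec)),
            class = "lt_phantom")
}

# Rasterize one stack of a phantom. Right-limb geometry is constructed
# first; left limbs are the exact mirror (x -> FOV - x).
build_stack <- function(spec, region) {
  X <- spec$inplane; Y <- spec$inplane; Z <- spec$slices
  sp <- spec$spacing
  Fx <- X * sp[1]; Fy <- Y * sp[2]
  xs <- voxel_to_mm(seq_len(X), sp[1])
  ys <- voxel_to_mm(seq_len(Y), sp[2])
  zs <- voxel_to_mm(seq_len(Z), sp[3])
  centre <- c(0.25 * Fx, 0.5 * Fy)
  mirror <- spec$side == "left"
  th <- spec$stack_rotation[[region]]
  place <- function(offset) centre + rot2(offset, th)
  slice_mm <- function(k) voxel_to_mm(k, sp[3])

  prim <- list()   # each: list(kind, centre(x,y), r, ...) for midline check
  add_ball <- function(cx, cy, cz, r)
    prim[[length(prim) + 1L]] <<- list(kind = "ball", c = c(cx, cy), r = r,
                                       cz = cz)
  add_vcyl <- function(cx, cy, r, k0, k1)
    prim[[length(prim) + 1L]] <<- list(kind = "vcyl", c = c(cx, cy), r = r,
                                       k0 = k0, k1 = k1)
  add_hcyl <- function(A, B, cz, r)
    prim[[length(prim) + 1L]] <<- list(kind = "hcyl", A = A, B = B, r = r,
                                       cz = cz)

  truth <- list()
  if (region == "hip") {
    zn <- max(2L, round(0.22 * Z))
    d_n <- rot2(c(cos(spec$femoral_torsion * pi / 180),
                  -sin(spec$femoral_torsion * pi / 180)), th)
    B <- place(c(0, 0))
    H <- B + spec$neck_length * d_n
    add_ball(H[1], H[2], slice_mm(zn), spec$head_radius)
    add_hcyl(B, H, slice_mm(zn), spec$neck_radius)
    add_ball(B[1], B[2], slice_mm(zn), spec$trochanter_radius)
    add_vcyl(B[1], B[2], spec$shaft_radius, zn, round(0.93 * Z))
    truth$head_center <- c(mirror_x(H, Fx, mirror), slice_mm(zn))
    truth$neck_direction <- mirror_dir(d_n, mirror)
    bones <- list(femur = seq_along(prim))
  } else if (region == "knee") {
    zf <- max(2L, round(0.34 * Z))
    zt <- min(Z - 1L, round(0.62 * Z))
    d_c <- rot2(c(1, 0), th)
    fl <- lapply(c(-1, 1), function(s)
      place(c(s * spec$condyle_halfsep_femur, 4)))
    for (p in fl) add_ball(p[1], p[2], slice_mm(zf), spec$condyle_radius_femur)
    sh <- place(c(0, -5))
    add_vcyl(sh[1], sh[2], spec$shaft_radius, 1L, zf)
    n_femur <- length(prim)
    tl <- lapply(c(-1, 1), function(s)
      place(c(s * spec$condyle_halfsep_tibia, 4)))
    for (p in tl) add_ball(p[1], p[2], slice_mm(zt), spec$condyle_radius_tibia)
    add_vcyl(sh[1], sh[2], spec$shaft_radius, zt, round(0.97 * Z))
    truth$femoral_condylar_direction <- mirror_dir(d_c, mirror)
    truth$tibial_condylar_direction <- mirror_dir(d_c, mirror)
    truth$femoral_condylar_slice <- zf
    truth$tibial_condylar_slice <- zt
    bones <- list(femur = seq_len(n_femur),
                  tibia = (n_femur + 1L):length(prim))
  } else {
    z0 <- 2L
    z1 <- round(0.86 * Z)
    beta <- spec$tibial_torsion * pi / 180
    Tc <- place(c(0, 0))
    d_f <- rot2(c(-cos(beta), sin(beta)), th)
    Fc <- Tc + spec$fibula_offset * d_f
    add_vcyl(Tc[1], Tc[2], spec$tibia_radius_ankle, z0, z1)
    n_tibia <- length(prim)
    add_vcyl(Fc[1], Fc[2], spec$fibula_radius, z0, z1)
    truth$distal_tibiofibular_direction <- mirror_dir(d_f, mirror)
    truth$distal_slice <- z1
    bones <- list(tibia = seq_len(n_tibia),
                  fibula = (n_tibia + 1L):length(prim))
  }

  # midline / field-of-view guard on the unmirrored right-limb geometry
  for (p in prim) {
    cs <- if (p$kind == "hcyl") rbind(p$A, p$B) else rbind(p$c)
    if (max(cs[, 1]) + p$r >= Fx / 2)
      stop("phantom geometry crosses the x midline; reduce angles or sizes")
    if (min(cs[, 1]) - p$r <= 0 || min(cs[, 2]) - p$r <= 0 ||
        max(cs[, 2]) + p$r >= Fy)
      stop("phantom geometry leaves the field of view")
  }

  labels <- array(0L, c(X, Y, Z))
  for (bone in names(bones)) {
    code <- LT_CLASSES[[bone]]
    for (i in bones[[bone]]) {
      m <- rasterize_primitive(prim[[i]], xs, ys, zs, Fx, mirror)
      labels[m & labels == 0L] <- code
    }
  }
  mask <- label_mask(labels, sp, region)
  vol <- mri_volume(array(as.numeric(labels > 0L), dim(labels)), sp, region)
  list(mask = mask, intensity = vol, truth = truth)
}

mirror_x <- function(p, Fx, mirror) if (mirror) c(Fx - p[1], p[2]) else p
mirror_dir <- function(d, mirror) if (mirror) c(-d[1], d[2]) else d

rasterize_primitive <- function(p, xs, ys, zs, Fx, mirror) {
  if (p$kind == "ball") {
    c2 <- mirror_x(p$c, Fx, mirror)
    d2 <- outer(outer((xs - c2[1])^2, (ys - c2[2])^2, "+"),
                (zs - p$cz)^2, "+")
    d2 <= p$r^2
  } else if (p$kind == "vcyl") {
    c2 <- mirror_x(p$c, Fx, mirror)
    m2 <- outer((xs - c2[1])^2, (ys - c2[2])^2, "+") <= p$r^2
    arr <- array(m2, c(length(xs), length(ys), length(zs)))
    ksel <- seq_along(zs) >= p$k0 & seq_along(zs) <= p$k1
    arr[, , !ksel] <- FALSE
    arr
  } else {
    A <- mirror_x(p$A, Fx, mirror)
    B <- mirror_x(p$B, Fx, mirror)
    L <- sqrt(sum((B - A)^2))
    d <- (B - A) / L
    px <- matrix(xs - A[1], length(xs), length(ys))
    py <- matrix(ys - A[2], length(xs), length(ys), byrow = TRUE)
    t <- pmin(pmax(px * d[1] + py * d[2], 0), L)
    res2 <- (px - t * d[1])^2 + (py - t * d[2])^2
    outer(res2, (zs - p$cz)^2, "+") <= p$r^2
  }
}

#' @export
print.lt_phantom <- function(x, ...) {
  cat(sprintf(
    "<lt_phantom> %s limb, femoral %g deg / tibial %g deg, %d slices/stack\n",
    x$truth$side, x$truth$femoral_torsion, x$truth$tibial_torsion,
    x$spec$slices))
  invisible(x)
}

#' Draw a reproducible batch of random phantoms
#'
#' Specs are drawn uniformly and independently from the stated parameter
#' ranges with a seeded generator; any spec field can be ranged. Fields not
#' listed keep the [phantom_spec()] defaults.
#'
#' @param n number of phantoms (>= 1).
#' @param ranges named list; numeric fields as `c(lo, hi)`, `side` as a
#'   character vector of allowed sides.
#' @param seed integer seed.
#' @param generate rasterize each spec (set `FALSE` to get specs only).
#' @return List of length `n`; elements are `lt_phantom` objects (or
#'   `lt_phantom_spec` when `generate = FALSE`).
#' @export
phantom_batch <- function(n, ranges = list(), seed = 1L, generate = TRUE) {
  if (n < 1L) stop("n must be >= 1")
  if (length(ranges) && any(!vapply(ranges, length, 1L) %in% c(1L, 2L)))
    stop("every range must have one or two elements")
  specs <- with_seed_(seed, lapply(seq_len(n), function(i) {
    args <- lapply(ranges, function(r) {
      if (is.character(r)) sample(r, 1L)
      else if (length(r) == 1L) r
      else runif(1, r[1], r[2])
    })
    args$seed <- sample.int(2147483646L, 1L)
    do.call(phantom_spec, args)
  }))
  if (!generate) return(specs)
  lapply(specs, generate_phantom)
}

#' Segmentation-like corruption of phantom masks
#'
#' Emulates imperfect segmentations: each bone's binary image is treated as
#' an intensity channel, corrupted with Gaussian noise and (optionally) one
#' randomly chosen artifact family per stack, smoothed with a 3 x 3
#' in-plane box filter (real segmentation errors are spatially coherent,
#' not voxel-independent), thresholded at 0.5, cleaned by filling enclosed
#' holes and keeping the largest connected component, and the classes are
#' recombined. The noiseless masks are exact by construction, so this is
#' the route through which noise perturbs the landmark geometry.
#'
#' @param phantom an `lt_phantom`.
#' @param noise_sd Gaussian noise SD on the unit-intensity bone images.
#' @param artifact apply one random artifact family per stack?
#' @param seed integer seed.
#' @return List with corrupted `hip`, `knee`, `ankle` masks (`lt_mask`).
#' @export
noisy_masks <- function(phantom, noise_sd = 0.2, artifact = TRUE, seed = 1L) {
  stopifnot(inherits(phantom, "lt_phantom"))
  fams <- c("motion", "ghosting", "spiking", "bias_field")
  with_seed_(seed, {
    out <- list()
    for (region in LT_REGIONS) {
      mask <- phantom[[region]]$mask
      fam <- if (artifact) sample(fams, 1L) else NULL
      lab <- array(0L, dim(mask$data))
      for (code in sort(unique(as.integer(mask$data)))) {
        if (code == 0L) next
        img <- mri_volume(array(as.numeric(mask$data == code),
                                dim(mask$data)), mask$spacing, mask$region)
        if (!is.null(fam))
          img <- apply_artifact(img, fam, seed = sample.int(2147483646L, 1L))
        img$data <- img$data + array(rnorm(length(img$data), sd = noise_sd),
                                     dim(img$data))
        bin <- clean_binary(box_smooth_inplane(img$data) > 0.5)
        lab[bin & lab == 0L] <- code
      }
      m2 <- mask
      m2$data <- lab
      out[[region]] <- m2
    }
    out
  })
}

# 3x3 in-plane box filter (edge-normalized)
box_smooth_inplane <- function(a) {
  d <- dim(a)
  acc <- array(0, d)
  cnt <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) {
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    acc[xs - dx, ys - dy, ] <- acc[xs - dx, ys - dy, ] + a[xs, ys, ]
    cnt[xs - dx, ys - dy, ] <- cnt[xs - dx, ys - dy, ] + 1
  }
  acc / cnt
}

# fill enclosed holes, then keep the largest connected component
clean_binary <- function(bin) {
  if (!any(bin)) return(bin)
  bg <- !bin
  lab <- label_components(bg)
  border <- unique(c(lab[1, , ], lab[dim(lab)[1], , ], lab[, 1, ],
                     lab[, dim(lab)[2], ], lab[, , 1], lab[, , dim(lab)[3]]))
  border <- setdiff(border, 0L)
  bin[bg & !(lab %in% border)] <- TRUE
  lab <- label_components(bin)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}
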