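#' Signed projected angle between two axial directions
#'
#' The projected angle from `v` to `u` in the axial plane
#' (`atan2(v_x u_y - v_y u_x, u . v)`, counterclockwise positive in the
#' canonical x/y frame when viewed from superior), reduced to the interval
#' (-90, 90] degrees because reference lines are undirected up to the
#' orientation rules fixed at landmark extraction. Antisymmetric away from
#' the 90-degree wrap: `projected_axial_angle(u, v) ==
#' -projected_axial_angle(v, u)`.
#'
#' @param u,v length-2 nonzero direction vectors.
#' @return Angle in degrees in (-90, 90].
#' @export
projected_axial_angle <- function(u, v) {
  if (sum(u^2) == 0 || sum(v^2) == 0) stop("direction vectors must be nonzero")
  a <- rad2deg(atan2(v[1] * u[2] - v[2] * u[1], sum(u * v)))
  reduce_line_angle(a)
}

reduce_line_angle <- function(a) {
  a <- ((a + 90) %% 180) - 90        # into [-90, 90)
  if (a == -90) a <- 90
  a
}

# undirected line axis: representative with positive x (ties: positive y)
axis_rep <- function(d) {
  if (d[1] < 0 || (d[1] == 0 && d[2] < 0)) -d else d
}

line_dir <- function(line, side) {
  d <- line$direction
  if (side == "left") d[1] <- -d[1]   # mirror x so both sides share a scale
  axis_rep(d)
}

#' Femoral torsion from reference lines
#'
#' Signed projected angle between the femoral neck axis (proximal) and the
#' posterior condylar line (distal). Positive means antetorsion: the neck
#' axis is rotated anteriorly relative to the posterior condylar line. For
#' left limbs the x axis is mirrored before the angle is taken so both
#' sides report on the same scale.
#'
#' @param proximal an `lt_refline` of kind `proximal_femoral`.
#' @param distal an `lt_refline` of kind `distal_femoral`.
#' @param side `"left"` or `"right"`.
#' @return Torsion in degrees, antetorsion positive.
#' @export
femoral_torsion <- function(proximal, distal, side = c("right", "left")) {
  side <- match.arg(side)
  check_kind(proximal, "proximal_femoral")
  check_kind(distal, "distal_femoral")
  projected_axial_angle(line_dir(distal, side), line_dir(proximal, side))
}

#' Tibial torsion from reference lines
#'
#' Signed projected angle between the posterior tibial condylar line
#' (proximal) and the tibio-fibular centroid line (distal). Positive means
#' external torsion: the distal line is externally rotated relative to the
#' proximal condylar line. Sides are mirrored as in [femoral_torsion()].
#'
#' @param proximal an `lt_refline` of kind `proximal_tibial`.
#' @param distal an `lt_refline` of kind `distal_tibial`.
#' @inheritParams femoral_torsion
#' @return Torsion in degrees, external torsion positive.
#' @export
tibial_torsion <- function(proximal, distal, side = c("right", "left")) {
  side <- match.arg(side)
  check_kind(proximal, "proximal_tibial")
  check_kind(distal, "distal_tibial")
  projected_axial_angle(line_dir(proximal, side), line_dir(distal, side))
}

check_kind <- function(line, kind) {
  if (!inherits(line, "lt_refline") || line$kind != kind)
    stop("expected a reference line of kind ", kind)
  invisible(line)
}

#' Measure femoral and tibial torsion of one limb
#'
#' Runs the full landmark pipeline on three single-limb masks: femoral head
#' centre and neck axis on the hip stack, posterior femoral and tibial
#' condylar lines on the knee stack, tibio-fibular centroid line on the
#' ankle stack; then converts the two line pairs into signed torsion
#' angles. Any landmark warning (fallback slice selection, degenerate
#' moments) propagates into the measurement's `warnings`.
#'
#' @param hip,knee,ankle single-limb `lt_mask` objects for the respective
#'   regions.
#' @param side `"left"`, `"right"`, or `NULL` to infer from the hip mask.
#' @return An object of class `lt_torsion`: femoral and tibial torsion in
#'   degrees, side, the four reference lines, and warning flags.
#' @export
measure_limb <- function(hip, knee, ankle, side = NULL) {
  for (m in list(hip, knee, ankle))
    if (!is_lt_mask(m)) stop("measure_limb expects lt_mask inputs")
  named <- function(region, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("%s: %s", region, conditionMessage(e)), call. = FALSE))
  }
  head <- named("hip", femoral_head_center(hip, side))
  side <- side %||% head$side
  pf <- named("hip", proximal_femoral_line(hip, head = head, side = side))
  df <- named("knee", posterior_condylar_line(knee, "femur", side = side))
  pt <- named("knee", posterior_condylar_line(knee, "tibia", side = side))
  dt <- named("ankle", distal_tibial_line(ankle))
  lines <- list(proximal_femoral = pf, distal_femoral = df,
                proximal_tibial = pt, distal_tibial = dt)
  warnings <- unlist(lapply(lines, `[[`, "warn"))
  structure(list(
    femoral_torsion = femoral_torsion(pf, df, side),
    tibial_torsion = tibial_torsion(pt, dt, side),
    side = side, lines = lines,
    head_center = head,
    warnings = warnings), class = "lt_torsion")
}

#' @export
print.lt_torsion <- function(x, ...) {
  cat(sprintf("<lt_torsion> %s limb: femoral %+.1f deg, tibial %+.1f deg\n",
              x$side, x$femoral_torsion, x$tibial_torsion))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy a torsion measurement
#'
#' One row per measurement with the angles, side, the slice index of every
#' reference line, and the number of warnings.
#'
#' @param x an `lt_torsion`.
#' @param ... unused.
#' @return A tibble with one row.
#' @export
tidy.lt_torsion <- function(x, ...) {
  tibble::tibble(
    side = x$side,
    femoral_torsion = x$femoral_torsion,
    tibial_torsion = x$tibial_torsion,
    slice_proximal_femoral = x$lines$proximal_femoral$slice,
    slice_distal_femoral = x$lines$distal_femoral$slice,
    slice_proximal_tibial = x$lines$proximal_tibial$slice,
    slice_distal_tibial = x$lines$distal_tibial$slice,
    n_warnings = length(x$warnings))
}

#' @importFrom generics tidy
#' @export
generics::tidy

# full machine-readable provenance for serialization
torsion_provenance <- function(x) {
  stopifnot(inherits(x, "lt_torsion"))
  list(side = x$side,
       femoral_torsion = x$femoral_torsion,
       tibial_torsion = x$tibial_torsion,
       head_center_mm = x$head_center$mm,
       head_radius_mm = x$head_center$radius_mm,
       lines = lapply(x$lines, function(l)
         list(kind = l$kind, slice = l$slice, direction = l$direction,
              anchors_mm = l$anchors_mm,
              warn = l$warn)),
       warnings = as.list(x$warnings %||% character()))
}
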