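ball_mask <- function(center, r, d = c(40, 40, 12), spacing = c(1, 1, 2),
                      code = 1L, base = NULL) {
  lab <- if (is.null(base)) array(0L, d) else base
  xs <- (seq_len(d[1]) - 0.5) * spacing[1]
  ys <- (seq_len(d[2]) - 0.5) * spacing[2]
  zs <- (seq_len(d[3]) - 0.5) * spacing[3]
  dist2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
                 (zs - center[3])^2, "+")
  lab[dist2 <= r^2] <- code
  lab
}

test_that("femoral head centre is the inscribed-sphere centre", {
  sp <- c(1, 1, 1)
  d <- c(40, 40, 40)
  ctr <- c(14.5, 20.5, 12.5)                # a voxel centre, fully interior
  lab <- ball_mask(ctr, 8, d = d, spacing = sp)
  # attach a thin distal shaft so the proximal-third restriction matters
  lab[14:16, 20:22, 13:38] <- 1L
  m <- label_mask(lab, sp, "hip")
  h <- femoral_head_center(m)
  expect_lt(sqrt(sum((h$mm - ctr)^2)), max(sp) + 1e-9)
  expect_lt(abs(h$radius_mm - 8), 1.5)
  # a perfect isolated ball centres exactly
  iso <- label_mask(ball_mask(ctr, 6, d = d, spacing = sp), sp, "hip")
  expect_equal(femoral_head_center(iso)$mm, ctr, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(femoral_head_center(
    label_mask(array(0L, c(4, 4, 2)), sp, "hip")), "missing bone")
})

test_that("neck axis recovers the principal axis of the cross-section", {
  ph <- test_phantom(20, 30)
  pf <- proximal_femoral_line(ph$hip$mask)
  truth <- ph$truth$neck_direction
  ang <- projected_axial_angle(pf$direction, truth)
  expect_lt(abs(ang), 2)
  # axis-aligned ellipse: direction is the major axis
  lab <- array(0L, c(30, 30, 3))
  xs <- seq_len(30) - 15.5; ys <- seq_len(30) - 15.5
  ell <- outer(xs^2 / 100, ys^2 / 16, "+") <= 1
  lab[, , 2][ell] <- 1L
  m <- label_mask(lab, c(1, 1, 5), "hip")
  ln <- proximal_femoral_line(m)
  expect_lt(abs(abs(sum(ln$direction * c(1, 0))) - 1), 1e-6)
  # circular cross-section: degenerate moments flag + x-axis fallback
  lab2 <- array(0L, c(30, 30, 3))
  lab2[, , 2][outer(xs^2, ys^2, "+") <= 36] <- 1L
  ln2 <- proximal_femoral_line(label_mask(lab2, c(1, 1, 5), "hip"))
  expect_match(ln2$warn, "degenerate")
  expect_equal(abs(ln2$direction), c(1, 0), tolerance = 1e-12)
})

test_that("condylar slice selection maximizes the convex hull area", {
  # discs of radius 1, 4, 2 voxels on three slices -> middle slice wins
  lab <- array(0L, c(20, 20, 3))
  for (k in 1:3) {
    r <- c(1, 4, 2)[k]
    xs <- seq_len(20) - 10.5
    lab[, , k][outer(xs^2, xs^2, "+") <= r^2] <- 1L
  }
  m <- label_mask(lab, c(1, 1, 5), "knee")
  expect_identical(select_condylar_slice(m, "femur"), 2L)
  mt0 <- m; mt0$data[mt0$data == 1L] <- 2L
  expect_identical(select_condylar_slice(mt0, "tibia"), 2L)
  # single nonempty slice
  one <- array(0L, c(10, 10, 4)); one[4:6, 4:6, 3] <- 1L
  expect_identical(
    select_condylar_slice(label_mask(one, c(1, 1, 5), "knee"), "femur"), 3L)
  # exact ties: distal for femur, proximal for tibia
  two <- array(0L, c(10, 10, 4))
  two[4:6, 4:6, 2] <- 1L; two[4:6, 4:6, 4] <- 1L
  two[5, 5, 3] <- 1L  # keep the component connected
  mt <- label_mask(two, c(1, 1, 5), "knee")
  expect_identical(select_condylar_slice(mt, "femur"), 4L)
  mt$data[mt$data == 1L] <- 2L
  expect_identical(select_condylar_slice(mt, "tibia"), 2L)
})

test_that("posterior condylar line tracks the lobe poles", {
  # two bridged discs with known posterior poles on one slice
  lab <- array(0L, c(40, 40, 1))
  xs <- seq_len(40)
  for (cc in list(c(12, 20, 6), c(30, 22, 6))) {
    d2 <- outer((xs - cc[1])^2, (xs - cc[2])^2, "+")
    lab[, , 1][d2 <= cc[3]^2] <- 1L
  }
  lab[12:30, 17, 1] <- 1L   # anterior bridge keeps the pair connected
  m <- label_mask(lab, c(1, 1, 5), "knee")
  ln <- posterior_condylar_line(m, "femur", slice = 1L, side = "right")
  # condylar points sit on the posterior band centroids near the poles
  # (poles at voxel centres (12, 26) and (30, 28) -> mm (11.5, 25.5),
  # (29.5, 27.5)); medial (+x) anchor first for a right limb
  expect_lt(max(abs(ln$anchors_mm[1, ] - c(29.5, 27.5))), 1.6)
  expect_lt(max(abs(ln$anchors_mm[2, ] - c(11.5, 25.5))), 1.6)
  slope_true <- (27.5 - 25.5) / (29.5 - 11.5)
  slope <- ln$direction[2] / ln$direction[1]
  expect_lt(abs(slope - slope_true), 0.05)
  # symmetric cross-section -> line parallel to the x axis
  sym <- array(0L, c(40, 40, 1))
  sym[, , 1][outer((xs - 20)^2 / 144, (xs - 20)^2 / 49, "+") <= 1] <- 1L
  ls <- posterior_condylar_line(label_mask(sym, c(1, 1, 5), "knee"),
                                "femur", slice = 1L, side = "right")
  expect_lt(abs(ls$direction[2]), 1e-9)
  # a single-column (anteroposterior) cross-section is degenerate
  col1 <- array(0L, c(10, 10, 1)); col1[5, 3:8, 1] <- 1L
  expect_error(posterior_condylar_line(label_mask(col1, c(1, 1, 5), "knee"),
                                       "femur", slice = 1L, side = "right"),
               "degenerate anatomy")
})

test_that("distal tibial line connects the tibio-fibular centroids", {
  d <- c(60, 40, 6); sp <- c(1, 1, 5)
  lab <- array(0L, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  tib <- outer((xs - 20.5)^2, (ys - 20.5)^2, "+") <= 81
  fib <- outer((xs - 40.5)^2, (ys - 28.5)^2, "+") <= 16
  for (k in 1:5) { lab[, , k][tib] <- 2L; lab[, , k][fib][lab[, , k][fib] == 0L] <- 3L }
  m <- label_mask(lab, sp, "ankle")
  ln <- distal_tibial_line(m)
  expect_identical(ln$slice, 5L)
  ang_true <- atan2(8, 20)
  ang <- atan2(ln$direction[2], ln$direction[1])
  expect_lt(abs(ang - ang_true), 0.03)
  # fibula missing entirely
  m2 <- m; m2$data[m2$data == 3L] <- 0L
  expect_error(distal_tibial_line(m2), "missing bone")
  # single-voxel cross-sections: fallback slice with a warning flag
  tiny <- array(0L, c(10, 10, 3))
  tiny[3, 3, 1:2] <- 2L; tiny[7, 6, 1:2] <- 3L
  lt <- distal_tibial_line(label_mask(tiny, c(1, 1, 5), "ankle"))
  expect_identical(lt$slice, 2L)
  expect_match(lt$warn, "minimum-area")
  expect_equal(atan2(lt$direction[2], lt$direction[1]), atan2(3, 4),
               tolerance = 1e-9)
})

test_that("whole-voxel translation shifts landmarks and keeps directions", {
  ph <- test_phantom(20, 15)
  shift <- c(3L, 2L)
  shifted <- lapply(ph[c("hip", "knee", "ankle")], function(st) {
    m <- st$mask
    d <- dim(m$data)
    out <- array(0L, d)
    out[(1 + shift[1]):d[1], (1 + shift[2]):d[2], ] <-
      m$data[1:(d[1] - shift[1]), 1:(d[2] - shift[2]), ]
    m$data <- out
    m
  })
  h0 <- femoral_head_center(ph$hip$mask)
  h1 <- femoral_head_center(shifted$hip)
  expect_equal(h1$mm[1:2] - h0$mm[1:2],
               shift * ph$hip$mask$spacing[1:2], tolerance = 1e-9,
               ignore_attr = TRUE)
  l0 <- proximal_femoral_line(ph$hip$mask)
  l1 <- proximal_femoral_line(shifted$hip)
  expect_lt(abs(projected_axial_angle(l0$direction, l1$direction)), 0.2)
  c0 <- posterior_condylar_line(ph$knee$mask, "femur")
  c1 <- posterior_condylar_line(shifted$knee, "femur")
  expect_equal(c1$anchors_mm - c0$anchors_mm,
               matrix(rep(shift * 1.2, each = 2), 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(c0$direction, c1$direction, tolerance = 1e-9)
})

test_that("landmarks lie inside their bone component", {
  ph <- test_phantom(25, 40, side = "left")
  h <- femoral_head_center(ph$hip$mask)
  expect_identical(ph$hip$mask$data[h$vox[1], h$vox[2], h$vox[3]], 1L)
  dt <- distal_tibial_line(ph$ankle$mask)
  for (i in 1:2) {
    vx <- round(dt$anchors_vox[i, ])
    expect_gt(ph$ankle$mask$data[vx[1], vx[2], dt$slice], 0L)
  }
})
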