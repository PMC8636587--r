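test_that("projected axial angle matches closed forms", {
  expect_equal(projected_axial_angle(c(1, 0), c(1, 0)), 0)
  expect_equal(projected_axial_angle(c(0, 1), c(1, 0)), 90)
  expect_equal(projected_axial_angle(c(1, 1) / sqrt(2), c(1, 0)), 45)
  expect_error(projected_axial_angle(c(0, 0), c(1, 0)), "nonzero")
})

test_that("projected axial angle is antisymmetric away from the wrap", {
  set.seed(30)
  for (i in 1:50) {
    a <- runif(1, 0, 2 * pi); b <- a + runif(1, -1.4, 1.4)
    u <- c(cos(a), sin(a)); v <- c(cos(b), sin(b))
    expect_equal(projected_axial_angle(u, v),
                 -projected_axial_angle(v, u), tolerance = 1e-9)
  }
})

test_that("torsion wrappers enforce line kinds and the sign convention", {
  sp <- c(1, 1, 5)
  mk <- function(kind, dir) reference_line(kind, 1L, dir, c(0, 0), sp)
  pf <- mk("proximal_femoral", c(cos(0.35), -sin(0.35)))  # 20 deg anterior
  df <- mk("distal_femoral", c(1, 0))
  expect_equal(femoral_torsion(pf, df, "right"), 20.05, tolerance = 0.1)
  expect_equal(femoral_torsion(pf, df, "right"),
               -femoral_torsion(mk("proximal_femoral",
                                   c(cos(0.35), sin(0.35))), df, "right"),
               tolerance = 1e-9)
  # parallel lines measure zero
  expect_equal(femoral_torsion(mk("proximal_femoral", c(1, 0)), df,
                               "right"), 0)
  pt <- mk("proximal_tibial", c(1, 0))
  dt <- mk("distal_tibial", c(-cos(0.5), sin(0.5)))
  expect_equal(tibial_torsion(pt, dt, "right"), 0.5 * 180 / pi,
               tolerance = 1e-6)
  expect_error(femoral_torsion(pt, df, "right"), "proximal_femoral")
  expect_error(tibial_torsion(pf, dt, "right"), "proximal_tibial")
})

test_that("phantom torsion is recovered within a degree on both sides", {
  for (side in c("right", "left")) {
    ph <- test_phantom(20, 35, side = side)
    m <- measure_phantom(ph)
    expect_identical(m$side, side)
    expect_lt(abs(m$femoral_torsion - 20), 1)
    expect_lt(abs(m$tibial_torsion - 35), 1)
  }
})

test_that("measurement errors name the offending joint", {
  ph <- test_phantom(10, 20)
  empty_knee <- ph$knee$mask
  empty_knee$data[] <- 0L
  expect_error(measure_limb(ph$hip$mask, empty_knee, ph$ankle$mask),
               "knee")
  expect_error(measure_limb(ph$hip$mask, ph$knee$mask, "not a mask"),
               "lt_mask")
})

test_that("whole-limb axial rotation leaves torsion nearly unchanged", {
  base <- measure_phantom(test_phantom(20, 30))
  for (th in c(-10, 10)) {
    m <- measure_phantom(test_phantom(20, 30,
                                      rotation = c(hip = th, knee = th,
                                                   ankle = th)))
    expect_lt(abs(m$femoral_torsion - base$femoral_torsion), 1.5)
    expect_lt(abs(m$tibial_torsion - base$tibial_torsion), 1.5)
  }
})

test_that("rotating only the ankle shifts tibial torsion by the rotation", {
  base <- measure_phantom(test_phantom(15, 20))
  for (dlt in c(-10, 8)) {
    m <- measure_phantom(test_phantom(15, 20,
                                      rotation = c(hip = 0, knee = 0,
                                                   ankle = dlt)))
    expect_lt(abs((m$tibial_torsion - base$tibial_torsion) - dlt), 1)
    expect_lt(abs(m$femoral_torsion - base$femoral_torsion), 1)
  }
})

test_that("tidy() flattens a measurement into one provenance row", {
  m <- measure_phantom(test_phantom(20, 30))
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 1L)
  expect_identical(td$side, "right")
  expect_true(all(c("femoral_torsion", "tibial_torsion",
                    "slice_distal_tibial") %in% names(td)))
  prov <- limbtorsion:::torsion_provenance(m)
  expect_identical(length(prov$lines), 4L)
})
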