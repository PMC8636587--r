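test_that("volume and mask constructors enforce their invariants", {
  expect_error(mri_volume(array(0, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(mri_volume(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(label_mask(array(4L, c(2, 2, 2)), c(1, 1, 1)), "class codes")
  v <- mri_volume(array(1, c(2, 3, 4)), c(0.6, 0.6, 6.5), "knee")
  expect_s3_class(v, "lt_volume")
  expect_identical(canonicalize(canonicalize(v)), canonicalize(v))
})

test_that("resampling follows the shape formula and preserves content", {
  set.seed(1)
  v <- mri_volume(array(rnorm(16 * 16 * 4), c(16, 16, 4)),
                  c(0.6, 0.6, 6.5), "hip")
  same <- lt_resample(v, c(0.6, 0.6, 6.5))
  expect_identical(dim(same$data), dim(v$data))
  expect_lt(max(abs(same$data - v$data)), 1e-10)

  const <- mri_volume(array(3.7, c(8, 8, 3)), c(1.2, 1.2, 6.5), "hip")
  r <- lt_resample(const, c(0.5, 0.8, 3.1))
  expect_true(all(abs(r$data - 3.7) < 1e-10))

  v2 <- mri_volume(array(rnorm(10 * 12 * 3), c(10, 12, 3)),
                   c(1.2, 1.2, 6.5), "hip")
  r2 <- lt_resample(v2, c(0.6, 0.6, 6.5))
  expect_identical(dim(r2$data), c(20L, 24L, 3L))
})

test_that("resampling is idempotent at the target spacing", {
  set.seed(2)
  v <- mri_volume(array(rnorm(20 * 20 * 5), c(20, 20, 5)),
                  c(1.0, 1.0, 5.0), "hip")
  once <- lt_resample(v, c(0.7, 0.7, 5.0))
  twice <- lt_resample(once, c(0.7, 0.7, 5.0))
  rng <- diff(range(v$data))
  expect_lt(max(abs(once$data - twice$data)), 1e-5 * rng)
})

test_that("label resampling never introduces absent class codes", {
  set.seed(3)
  for (i in 1:5) {
    lab <- array(sample(c(0L, 0L, 1L, 3L), 8 * 8 * 4, TRUE), c(8, 8, 4))
    m <- label_mask(lab, c(1.1, 0.9, 6.5), "ankle")
    r <- lt_resample(m, c(0.6, 0.6, 3.0))
    expect_true(all(r$data %in% unique(as.integer(lab))))
  }
})

test_that("z-score normalization and its degenerate case", {
  set.seed(4)
  v <- mri_volume(array(rexp(500), c(10, 10, 5)), c(1, 1, 1), "hip")
  nv <- normalize_intensity(v)
  expect_lt(abs(mean(nv$data)), 1e-6)
  expect_lt(abs(sqrt(mean(nv$data^2)) - 1), 1e-6)
  # affine invariance
  v2 <- v; v2$data <- 3.2 * v$data - 7
  expect_lt(max(abs(normalize_intensity(v2)$data - nv$data)), 1e-9)
  # constant volume -> zeros, not an error
  cv <- normalize_intensity(mri_volume(array(5, c(3, 3, 3)), c(1, 1, 1)))
  expect_true(all(cv$data == 0))
})

test_that("crop_or_pad pads to the next multiple and round-trips", {
  m <- label_mask(array(sample(0:3, 65 * 64 * 29, TRUE), c(65, 64, 29)),
                  c(0.6, 0.6, 6.5), "hip")
  p <- crop_or_pad(m, c(32L, 32L, 1L))
  expect_identical(dim(p$data), c(96L, 64L, 29L))
  expect_identical(lt_unpad(p)$data, m$data)
  p2 <- crop_or_pad(label_mask(array(0L, c(64, 64, 29)), c(1, 1, 1)),
                    c(32L, 32L, 1L))
  expect_identical(dim(p2$data), c(64L, 64L, 29L))
})

test_that("split_limbs assigns components by the x midline", {
  lab <- array(0L, c(40, 20, 4))
  lab[6:10, 8:12, ] <- 1L    # right limb: low x in the canonical frame
  lab[30:34, 8:12, ] <- 1L   # left limb
  m <- label_mask(lab, c(1, 1, 5), "hip")
  s <- split_limbs(m)
  expect_true(all(which(s$right$data > 0, arr.ind = TRUE)[, 1] <= 10))
  expect_true(all(which(s$left$data > 0, arr.ind = TRUE)[, 1] >= 30))
  # partition: left u right = input, disjoint
  expect_identical(s$left$data + s$right$data, m$data)
  expect_false(any(s$left$data > 0 & s$right$data > 0))
  # mirrored mask swaps assignments
  mm <- m; mm$data <- m$data[40:1, , ]
  sm <- split_limbs(mm)
  expect_identical(sm$left$data[40:1, , ], s$right$data)
  # one-sided masks flag the empty side; empty masks error
  one <- m; one$data[30:34, , ] <- 0L
  expect_match(attr(split_limbs(one)$left, "lt_warn"), "no component")
  expect_error(split_limbs(label_mask(array(0L, c(4, 4, 2)), c(1, 1, 1))),
               "foreground")
})

test_that("NIfTI round trip preserves grid, spacing, and orientation", {
  set.seed(5)
  v <- mri_volume(array(rnorm(6 * 8 * 3), c(6, 8, 3)), c(0.6, 0.6, 6.5),
                  "ankle")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f, "ankle")
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$data, v$data, tolerance = 1e-6, ignore_attr = TRUE)
  m <- label_mask(array(sample(0:3, 6 * 8 * 3, TRUE), c(6, 8, 3)),
                  c(0.6, 0.6, 6.5), "ankle")
  write_mask(m, f)
  expect_identical(read_mask(f, "ankle")$data, m$data)
})
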