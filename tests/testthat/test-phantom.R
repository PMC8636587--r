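test_that("phantom specs validate their parameters", {
  expect_error(phantom_spec(femoral_torsion = 95), "-90, 90")
  expect_error(phantom_spec(head_radius = -1), "positive")
  expect_error(phantom_spec(artifact = "blur"), "unknown artifact")
  expect_error(phantom_spec(noise_sd = -0.1), "non-negative")
  expect_error(phantom_spec(scale = 0), "scale")
  # geometry that would reach past the patient midline is rejected
  expect_error(generate_phantom(phantom_spec(neck_length = 80)),
               "midline")
})

test_that("ground truth is recorded by construction and self-consistent", {
  ph <- test_phantom(20, 35)
  expect_identical(ph$truth$femoral_torsion, 20)
  expect_identical(ph$truth$tibial_torsion, 35)
  # the recorded torsions equal the closed-form angles between the
  # recorded construction directions, to machine precision
  sp <- c(1.2, 1.2, 6.5)
  pf <- reference_line("proximal_femoral", 1L, ph$truth$neck_direction,
                       c(0, 0), sp)
  df <- reference_line("distal_femoral", 1L,
                       ph$truth$femoral_condylar_direction, c(0, 0), sp)
  pt <- reference_line("proximal_tibial", 1L,
                       ph$truth$tibial_condylar_direction, c(0, 0), sp)
  dt <- reference_line("distal_tibial", 1L,
                       ph$truth$distal_tibiofibular_direction, c(0, 0), sp)
  expect_equal(femoral_torsion(pf, df, "right"), 20, tolerance = 1e-9)
  expect_equal(tibial_torsion(pt, dt, "right"), 35, tolerance = 1e-9)
  # zero torsion: all recorded directions pairwise parallel
  ph0 <- test_phantom(0, 0)
  cross <- function(u, v) abs(u[1] * v[2] - u[2] * v[1])
  expect_lt(cross(ph0$truth$neck_direction,
                  ph0$truth$femoral_condylar_direction), 1e-12)
  expect_lt(cross(ph0$truth$tibial_condylar_direction,
                  ph0$truth$distal_tibiofibular_direction), 1e-12)
})

test_that("left-limb truths are the mirror image of right-limb truths", {
  r <- test_phantom(25, 30, side = "right")
  l <- test_phantom(25, 30, side = "left")
  expect_equal(l$truth$neck_direction * c(-1, 1), r$truth$neck_direction,
               tolerance = 1e-12)
  expect_equal(l$truth$head_center[2:3], r$truth$head_center[2:3],
               tolerance = 1e-9)
})

test_that("stacks contain exactly the classes the anatomy implies", {
  ph <- test_phantom(15, 30)
  expect_identical(sort(unique(as.integer(ph$hip$mask$data))), c(0L, 1L))
  expect_identical(sort(unique(as.integer(ph$knee$mask$data))),
                   c(0L, 1L, 2L))
  expect_identical(sort(unique(as.integer(ph$ankle$mask$data))),
                   c(0L, 2L, 3L))
})

test_that("noiseless intensity thresholded at 0.5 is the foreground", {
  ph <- test_phantom(10, 20)
  for (region in c("hip", "knee", "ankle")) {
    expect_identical(ph[[region]]$volume$data > 0.5,
                     ph[[region]]$mask$data > 0L)
  }
})

test_that("phantom batches are reproducible and honour their ranges", {
  rng <- list(femoral_torsion = c(-20, 45), tibial_torsion = c(0, 45),
              side = c("right", "left"), inplane = 48L, slices = 10L,
              scale = 0.45, spacing = NULL)
  rng$spacing <- NULL
  b1 <- phantom_batch(7, rng, seed = 5, generate = FALSE)
  b2 <- phantom_batch(7, rng, seed = 5, generate = FALSE)
  expect_identical(b1, b2)
  expect_length(b1, 7L)
  for (sp in b1) {
    expect_gte(sp$femoral_torsion, -20)
    expect_lte(sp$femoral_torsion, 45)
  }
  # degenerate range pins the value
  b3 <- phantom_batch(3, modifyList(rng, list(tibial_torsion = 10)),
                      seed = 2, generate = FALSE)
  expect_true(all(vapply(b3, `[[`, 1, "tibial_torsion") == 10))
  expect_error(phantom_batch(0), ">= 1")
})

test_that("generation with a fixed seed is fully deterministic", {
  sp <- phantom_spec(12, 28, noise_sd = 0.15, artifact = "ghosting",
                     spacing = c(1.2, 1.2, 6.5), inplane = 128L, seed = 9)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  for (region in c("hip", "knee", "ankle")) {
    expect_identical(a[[region]]$volume$data, b[[region]]$volume$data)
    expect_identical(a[[region]]$mask$data, b[[region]]$mask$data)
  }
})

test_that("segmentation-like corruption stays close to the truth", {
  ph <- test_phantom(15, 30, seed = 21)
  nm1 <- noisy_masks(ph, noise_sd = 0.2, artifact = TRUE, seed = 4)
  nm2 <- noisy_masks(ph, noise_sd = 0.2, artifact = TRUE, seed = 4)
  expect_identical(nm1$hip$data, nm2$hip$data)
  d <- dice_per_class(nm1$knee, ph$knee$mask, c(femur = 1L, tibia = 2L))
  expect_true(all(d > 0.9))
})
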