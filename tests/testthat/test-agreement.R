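test_that("dice coefficient matches its definition", {
  a <- array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2))
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, !a), 0)
  b <- array(FALSE, c(2, 2, 2)); b[1:2, 1, 1] <- TRUE; b[, 2, 2] <- TRUE
  expect_equal(dice_coefficient(a, b), 0.5)  # |A|=4, |B|=4, overlap 2
  e <- array(FALSE, c(2, 2, 2))
  both <- dice_coefficient(e, e)
  expect_equal(as.numeric(both), 1)
  expect_true(attr(both, "both_empty"))
  expect_error(dice_coefficient(a, array(TRUE, c(2, 2, 1))), "shapes")
})

test_that("dice is symmetric and 1 only for identical nonempty masks", {
  set.seed(40)
  for (i in 1:20) {
    a <- array(runif(27) < 0.4, c(3, 3, 3))
    b <- array(runif(27) < 0.4, c(3, 3, 3))
    expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
    if (any(a) || any(b))
      expect_identical(dice_coefficient(a, b) == 1, identical(a, b))
  }
})

test_that("single-score ICC agrees with the ANOVA mean-squares oracle", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(4:12, 1); k <- sample(2:4, 1)
    tab <- matrix(rnorm(n * k, mean = rep(rnorm(n, sd = 2), k)), n, k)
    got <- icc_single(tab)
    # oracle: mean squares from stats::aov on the long-format table
    long <- data.frame(y = as.vector(tab),
                       subj = factor(rep(seq_len(n), k)),
                       reader = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ subj + reader, data = long))[[1]][
      , "Mean Sq"]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    icc_ref <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    expect_equal(got$icc, icc_ref, tolerance = 1e-10)
  }
})

test_that("ICC limits: perfect agreement and absent subject variance", {
  subj <- rnorm(8, sd = 3)
  perfect <- cbind(subj, subj)
  expect_equal(icc_single(perfect)$icc, 1, tolerance = 1e-12)
  # readers agree within subjects but subjects do not vary: ICC ~ 0, flagged
  set.seed(47)
  noisy <- matrix(5 + rnorm(40, sd = 0.5), 20, 2)
  res <- icc_single(noisy)
  expect_lt(abs(res$icc), 0.5)
  # exactly constant table: undefined, flagged
  const <- matrix(3, 4, 2)
  expect_true(is.na(icc_single(const)$icc))
  expect_match(icc_single(const)$flag, "zero total variance")
})

test_that("ICC is invariant to adding a constant to all cells", {
  set.seed(42)
  tab <- matrix(rnorm(20, rep(rnorm(10, sd = 2), 2)), 10, 2)
  a <- icc_single(tab); b <- icc_single(tab + 17.3)
  expect_equal(a$icc, b$icc, tolerance = 1e-10)
  expect_equal(a$ci, b$ci, tolerance = 1e-8)
})

test_that("simulated readers converge to the theoretical ICC", {
  set.seed(43)
  n <- 500; sd_subj <- 8; sd_err <- 4
  truth <- rnorm(n, 20, sd_subj)
  tab <- cbind(truth + rnorm(n, sd = sd_err), truth + rnorm(n, sd = sd_err))
  expected <- sd_subj^2 / (sd_subj^2 + sd_err^2)
  expect_lt(abs(icc_single(tab)$icc - expected), 0.05)
})

test_that("pearson correlation and its degenerate flag", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  res <- pearson_r(x, rep(2, 5))
  expect_true(is.na(res$r))
  expect_match(res$flag, "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  # affine invariance
  set.seed(44)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(pearson_r(a, b)$r, pearson_r(3 * a + 2, 0.5 * b - 1)$r,
               tolerance = 1e-12)
})

test_that("mean absolute difference uses the t interval", {
  expect_equal(mean_abs_difference(c(1, 2, 3), c(2, 3, 4))$mean, 1)
  same <- mean_abs_difference(1:5, 1:5)
  expect_equal(same$mean, 0)
  expect_equal(same$ci, c(0, 0))
  set.seed(45)
  x <- rnorm(24, 20, 5); y <- x + rnorm(24, 0, 3)
  got <- mean_abs_difference(x, y)
  d <- abs(x - y)
  ref <- mean(d) + c(-1, 1) * qt(0.975, 23) * sd(d) / sqrt(24)
  expect_equal(got$ci, ref, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(mean_abs_difference(1:3, 1:4), "lengths differ")
})

test_that("agreement_report assembles all statistics per angle", {
  set.seed(46)
  a <- data.frame(femoral_torsion = rnorm(12, 16, 8),
                  tibial_torsion = rnorm(12, 34, 6))
  b <- data.frame(femoral_torsion = a$femoral_torsion + rnorm(12, 0, 2),
                  tibial_torsion = a$tibial_torsion + rnorm(12, 0, 3))
  rep <- agreement_report(a, b)
  expect_identical(nrow(rep), 2L)
  expect_true(all(c("pearson_r", "icc", "mean_abs_diff") %in% names(rep)))
  expect_true(all(rep$icc <= 1))
  ph <- test_phantom(15, 30)
  rep2 <- agreement_report(a, b, list(ph$knee$mask), list(ph$knee$mask))
  expect_equal(unname(attr(rep2, "dice")[1:2]), c(1, 1))
})
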