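#' Sorensen-Dice coefficient
#'
#' Overlap between two binary masks, `2|A n B| / (|A| + |B|)`. When both
#' masks are empty the coefficient is defined as 1 (perfect agreement on
#' absence) and the result carries a `both_empty` attribute flag.
#'
#' @param a,b logical/binary arrays of equal shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  a <- as.logical(a); b <- as.logical(b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(structure(1, both_empty = TRUE))
  2 * sum(a & b) / (sa + sb)
}

#' Per-class Dice between two label masks
#'
#' @param pred,ref `lt_mask` objects (or integer arrays) on the same grid.
#' @param classes foreground class codes to score.
#' @return Named numeric vector of Dice coefficients.
#' @export
dice_per_class <- function(pred, ref, classes = c(femur = 1L, tibia = 2L,
                                                  fibula = 3L)) {
  pa <- if (is_lt_mask(pred)) pred$data else pred
  ra <- if (is_lt_mask(ref)) ref$data else ref
  vapply(classes, function(cl) dice_coefficient(pa == cl, ra == cl),
         numeric(1))
}

#' Single-score intraclass correlation coefficient
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC (the
#' "single scorings, not adjusted" reading), computed from the mean
#' squares of the subjects-by-readers ANOVA decomposition, with the
#' standard F-based 95 percent confidence interval. A consistency variant
#' (two-way mixed, consistency) is available behind `type`.
#'
#' @param table numeric matrix, n subjects x k readers, no missing cells,
#'   n >= 2 and k >= 2.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param conf_level confidence level for the interval.
#' @return A list: `icc`, `ci` (length-2), `type`, `flag` (NULL, or a
#'   string when the statistic is degenerate).
#' @export
icc_single <- function(table, type = c("agreement", "consistency"),
                       conf_level = 0.95) {
  type <- match.arg(type)
  table <- as.matrix(table)
  if (any(!is.finite(table))) stop("ratings table has missing cells")
  n <- nrow(table); k <- ncol(table)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 readers")
  ms <- anova_two_way(table)
  alpha <- 1 - conf_level
  if (ms$total_var == 0)
    return(list(icc = NA_real_, ci = c(NA_real_, NA_real_), type = type,
                flag = "zero total variance; ICC undefined"))
  flag <- NULL
  if (type == "agreement") {
    icc <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
    # Satterthwaite df for the F bounds (two-way random, absolute)
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (ms$msr - fl * ms$mse) /
      (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    upper <- n * (fu * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
  } else {
    icc <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    fobs <- ms$msr / ms$mse
    fl <- fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- fobs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lower <- (fl - 1) / (fl + k - 1)
    upper <- (fu - 1) / (fu + k - 1)
  }
  if (ms$msr <= ms$mse)
    flag <- "no between-subject variance beyond error; ICC near or below 0"
  list(icc = icc, ci = c(lower, upper), type = type, flag = flag)
}

# mean squares of the two-way subjects x readers decomposition
anova_two_way <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), total_var = sst)
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation with the t-transform p-value. Zero variance
#' in either vector yields `NA` with a flag instead of an error.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List: `r`, `p`, `flag`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_,
                flag = "zero variance; correlation undefined"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, flag = NULL)
}

#' Mean absolute difference with confidence interval
#'
#' Mean of `|x - y|` with a t-distribution confidence interval on the
#' absolute differences, the convention used for inter-reader differences
#' of angle measurements.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @param conf_level confidence level.
#' @return List: `mean`, `ci` (length-2).
#' @export
mean_abs_difference <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- abs(x - y)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) return(list(mean = m, ci = c(m, m)))
  half <- qt(1 - (1 - conf_level) / 2, length(d) - 1) * s / sqrt(length(d))
  list(mean = m, ci = c(m - half, m + half))
}

#' Full agreement report for two readers
#'
#' Combines the segmentation and angle agreement statistics the evaluation
#' uses: per-class Dice (when masks are given), Pearson r, single-score
#' ICC with its confidence interval, and the mean absolute difference, for
#' each angle column.
#'
#' @param angles_a,angles_b data frames with matching numeric angle
#'   columns (e.g. `femoral_torsion`, `tibial_torsion`), one row per limb.
#' @param masks_a,masks_b optional lists of `lt_mask` pairs to score with
#'   Dice.
#' @return A tibble with one row per angle column plus an optional
#'   `dice` attribute (named per-class means).
#' @export
agreement_report <- function(angles_a, angles_b, masks_a = NULL,
                             masks_b = NULL) {
  common <- intersect(names(angles_a), names(angles_b))
  common <- common[vapply(angles_a[common], is.numeric, TRUE)]
  if (!length(common)) stop("no shared numeric angle columns")
  rows <- lapply(common, function(col) {
    x <- angles_a[[col]]; y <- angles_b[[col]]
    pr <- pearson_r(x, y)
    ic <- icc_single(cbind(x, y))
    md <- mean_abs_difference(x, y)
    tibble::tibble(measure = col, n = length(x),
                   mean_abs_diff = md$mean,
                   mad_ci_low = md$ci[1], mad_ci_high = md$ci[2],
                   pearson_r = pr$r, pearson_p = pr$p,
                   icc = ic$icc, icc_ci_low = ic$ci[1],
                   icc_ci_high = ic$ci[2])
  })
  out <- do.call(rbind, rows)
  if (!is.null(masks_a)) {
    stopifnot(length(masks_a) == length(masks_b))
    dice <- rowMeans(vapply(seq_along(masks_a), function(i)
      dice_per_class(masks_a[[i]], masks_b[[i]]), numeric(3)))
    attr(out, "dice") <- dice
  }
  out
}
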