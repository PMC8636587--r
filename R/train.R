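#' Training configuration
#'
#' Optimization settings for [train_unet()]: Adam at batch size 1 with an
#' initial learning rate of 0.001, and a plateau schedule that halves the
#' learning rate whenever the moving average of the training loss (window
#' `plateau_window` iterations) fails to improve by a relative
#' `plateau_rel_tol` for `plateau_patience` consecutive iterations; the
#' rate never drops below `min_lr` and only ever decreases, each time by
#' an exact factor of 2.
#'
#' @param iterations number of training iterations (one sample each).
#' @param initial_lr initial learning rate.
#' @param batch_size samples per step (the pipeline trains at 1).
#' @param plateau_window moving-average window, iterations.
#' @param plateau_patience iterations without improvement before halving.
#' @param plateau_rel_tol relative improvement that resets the patience.
#' @param min_lr lower bound on the learning rate.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param seed integer seed for sample order and augmentation.
#' @return An object of class `lt_train_config`.
#' @export
train_config <- function(iterations = 200L, initial_lr = 1e-3,
                         batch_size = 1L, plateau_window = 50L,
                         plateau_patience = 100L, plateau_rel_tol = 1e-3,
                         min_lr = 1e-6, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, seed = 1L) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (initial_lr <= 0) stop("initial_lr must be positive")
  structure(list(iterations = as.integer(iterations),
                 initial_lr = initial_lr, batch_size = as.integer(batch_size),
                 plateau_window = as.integer(plateau_window),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_rel_tol = plateau_rel_tol, min_lr = min_lr,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 seed = as.integer(seed)), class = "lt_train_config")
}

#' Augmentation specification
#'
#' Per training sample, with probability `1 - p_artifact` no artifact is
#' applied; otherwise exactly one family is drawn uniformly from
#' `families` and applied to the intensity volume before normalization.
#'
#' @param p_artifact probability that a sample is augmented.
#' @param families artifact families to draw from (see
#'   [apply_artifact()]).
#' @param params optional parameter overrides passed to
#'   [apply_artifact()].
#' @return An object of class `lt_augment_spec`.
#' @export
augment_spec <- function(p_artifact = 0.5,
                         families = c("motion", "ghosting", "spiking",
                                      "bias_field"),
                         params = list()) {
  if (p_artifact < 0 || p_artifact > 1) stop("p_artifact must be in [0, 1]")
  structure(list(p_artifact = p_artifact, families = families,
                 params = params), class = "lt_augment_spec")
}

#' Train the segmentation U-net
#'
#' Stochastic gradient training with Adam on (volume, mask) pairs. Each
#' iteration draws one sample, optionally applies one artifact family per
#' the augmentation spec, z-score normalizes the intensities, and takes
#' one optimizer step on the combined soft-Dice + cross-entropy loss.
#' The learning rate follows the plateau-halving schedule of
#' [train_config()]. The run is fully reproducible given the config seed.
#'
#' @param model an `lt_unet` from [build_unet()].
#' @param dataset list of samples, each `list(volume = , mask = )` with an
#'   [mri_volume()] and an aligned [label_mask()] whose shapes satisfy the
#'   pooling plan.
#' @param config an [train_config()].
#' @param augment an [augment_spec()], or `NULL` for no augmentation.
#' @return List with the trained `model` and `history`, a tibble with one
#'   row per iteration (`iteration`, `loss`, `moving_avg`, `lr`, `sample`,
#'   `artifact`).
#' @export
train_unet <- function(model, dataset, config = train_config(),
                       augment = augment_spec()) {
  stopifnot(inherits(model, "lt_unet"), inherits(config, "lt_train_config"))
  if (!length(dataset)) stop("empty dataset")
  for (s in dataset)
    if (!is_lt_volume(s$volume) || !is_lt_mask(s$mask))
      stop("dataset samples must be list(volume = lt_volume, mask = lt_mask)")
  n_iter <- config$iterations
  p <- lapply(model$params, function(x) x + 0)  # unshared copies: updated in place
  mstate <- lapply(p, function(x) x * 0)
  vstate <- lapply(p, function(x) x * 0)
  lr <- config$initial_lr
  losses <- numeric(n_iter)
  hist_ma <- numeric(n_iter)
  hist_lr <- numeric(n_iter)
  hist_sample <- integer(n_iter)
  hist_art <- character(n_iter)
  best_ma <- Inf
  wait <- 0L
  with_seed_(config$seed, {
    for (it in seq_len(n_iter)) {
      si <- sample.int(length(dataset), 1L)
      smp <- dataset[[si]]
      vol <- smp$volume
      fam <- NA_character_
      if (!is.null(augment) && runif(1) < augment$p_artifact) {
        fam <- sample(augment$families, 1L)
        vol <- apply_artifact(vol, fam, seed = sample.int(2147483646L, 1L),
                              params = augment$params)
      }
      vol <- normalize_intensity(vol)
      x <- vol$data
      dim(x) <- c(dim(x), 1L)
      fw <- unet_forward(model, x, train = TRUE)
      lg <- loss_grad_logits(fw$logits, smp$mask)
      grads <- unet_backward(model, fw, lg$grad)
      # Adam update (in place on the local copies)
      b1 <- config$beta1; b2 <- config$beta2
      corr1 <- 1 - b1^it; corr2 <- 1 - b2^it
      for (nm in names(p))
        adam_step(p[[nm]], grads[[nm]], mstate[[nm]], vstate[[nm]],
                  lr, b1, b2, corr1, corr2, config$adam_eps)
      model$params <- p
      losses[it] <- lg$loss
      ma <- mean(losses[max(1L, it - config$plateau_window + 1L):it])
      hist_ma[it] <- ma
      hist_lr[it] <- lr
      hist_sample[it] <- si
      hist_art[it] <- fam
      # plateau detection once a full window is available
      if (it >= config$plateau_window) {
        if (ma < best_ma * (1 - config$plateau_rel_tol)) {
          best_ma <- ma
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= config$plateau_patience) {
            lr <- max(lr / 2, config$min_lr)
            wait <- 0L
          }
        }
      }
    }
  })
  history <- tibble::tibble(iteration = seq_len(n_iter), loss = losses,
                            moving_avg = hist_ma, lr = hist_lr,
                            sample = hist_sample, artifact = hist_art)
  class(history) <- c("lt_train_history", class(history))
  list(model = model, history = history)
}

#' Phantom training and validation sets
#'
#' Draws random phantoms on small training-patch grids (64 x 64 x 16
#' voxels at 1.5 x 1.5 x 8 mm by default, geometry scaled to fit) and
#' unrolls them into per-stack (volume, mask) samples for [train_unet()].
#' Torsion angles are drawn uniformly over the clinically relevant ranges;
#' intensities carry mild Gaussian noise.
#'
#' @param n number of phantoms (each contributes its hip, knee, and ankle
#'   stack).
#' @param seed integer seed.
#' @param ranges overrides for [phantom_batch()] ranges.
#' @param spacing,slices,inplane,scale,noise_sd grid and intensity
#'   settings passed to every spec.
#' @return List with `phantoms` (the `lt_phantom` objects) and `samples`
#'   (flat list of `list(volume, mask)`).
#' @export
phantom_training_set <- function(n, seed = 1L, ranges = list(),
                                 spacing = c(1.5, 1.5, 8), slices = 16L,
                                 inplane = 64L, scale = 0.6,
                                 noise_sd = 0.1) {
  base <- list(femoral_torsion = c(-20, 45), tibial_torsion = c(0, 45),
               side = c("right", "left"))
  ranges <- modifyList(base, ranges)
  ranges$spacing <- NULL  # fixed grid settings below
  specs <- phantom_batch(n, ranges, seed = seed, generate = FALSE)
  phantoms <- lapply(specs, function(sp) {
    sp$spacing <- check_spacing(spacing)
    sp$slices <- as.integer(slices)
    sp$inplane <- as.integer(inplane)
    geom <- c("head_radius", "neck_length", "neck_radius",
              "trochanter_radius", "shaft_radius", "condyle_radius_femur",
              "condyle_radius_tibia", "condyle_halfsep_femur",
              "condyle_halfsep_tibia", "tibia_radius_ankle",
              "fibula_radius", "fibula_offset")
    sp[geom] <- lapply(sp[geom], function(v) v * scale)
    sp$noise_sd <- noise_sd
    generate_phantom(sp)
  })
  samples <- list()
  for (ph in phantoms)
    for (region in LT_REGIONS)
      samples[[length(samples) + 1L]] <-
        list(volume = ph[[region]]$volume, mask = ph[[region]]$mask)
  list(phantoms = phantoms, samples = samples)
}

#' Mean foreground Dice of a model on phantoms
#'
#' Segments every stack of every phantom with [predict_mask()] and
#' averages the Dice coefficient over the foreground classes present in
#' each ground-truth mask.
#'
#' @param model an `lt_unet`.
#' @param phantoms list of `lt_phantom` objects.
#' @param target_spacing working spacing for [predict_mask()]; defaults
#'   to the phantoms' own spacing (no resampling).
#' @return Mean foreground Dice (scalar); per-stack values in the
#'   `per_stack` attribute.
#' @export
mean_foreground_dice <- function(model, phantoms, target_spacing = NULL) {
  scores <- c()
  for (ph in phantoms) for (region in LT_REGIONS) {
    vol <- ph[[region]]$volume
    ref <- ph[[region]]$mask
    ts <- target_spacing %||% vol$spacing
    pred <- predict_mask(model, vol, target_spacing = ts)
    present <- setdiff(unique(as.integer(ref$data)), 0L)
    d <- vapply(present, function(cl)
      dice_coefficient(pred$data == cl, ref$data == cl), numeric(1))
    scores <- c(scores, mean(d))
  }
  structure(mean(scores), per_stack = scores)
}

#' Write a training history to CSV
#'
#' @param history the history tibble returned by [train_unet()].
#' @param path output CSV path.
#' @export
write_history <- function(history, path) {
  write.csv(history, path, row.names = FALSE)
  invisible(path)
}

#' Plot a training history
#'
#' Loss, its moving average, and the learning-rate schedule against
#' iteration (requires ggplot2).
#'
#' @param object an `lt_train_history`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lt_train_history <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  iteration <- loss <- moving_avg <- lr <- NULL  # tidy-eval columns
  ggplot2::ggplot(object, ggplot2::aes(x = iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = loss), alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = moving_avg), linewidth = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = lr * max(object$loss) /
                                      max(object$lr)),
                       linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "iteration", y = "loss",
                  caption = "dashed red: learning rate (rescaled)") +
    ggplot2::theme_minimal()
}

#' @importFrom generics glance
#' @export
generics::glance

#' Summarize a training run
#'
#' @param x an `lt_train_history`.
#' @param ... unused.
#' @return One-row tibble: iterations, final loss and moving average,
#'   final learning rate, and the number of halvings.
#' @export
glance.lt_train_history <- function(x, ...) {
  tibble::tibble(iterations = nrow(x), final_loss = x$loss[nrow(x)],
                 final_moving_avg = x$moving_avg[nrow(x)],
                 final_lr = x$lr[nrow(x)],
                 n_halvings = round(log2(x$lr[1] / x$lr[nrow(x)])))
}
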