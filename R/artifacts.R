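#' MRI artifact augmentation
#'
#' Applies one of the four artifact families used to augment training data,
#' emulating common MRI degradations. All families are deterministic given
#' `seed`:
#'
#' * `motion` — weighted average of the volume with a few copies resampled
#'   under small rigid transforms (in-plane rotation up to `rot_deg`,
#'   translation up to `trans_vox` voxels), mimicking patient movement
#'   between k-space shots.
#' * `ghosting` — periodic modulation of k-space lines along one randomly
#'   chosen phase-encoding axis (every `n`-th line, DC excluded, scaled by
#'   `1 - intensity`), producing the classic fold-over ghosts.
#' * `spiking` — up to `n_spikes` isolated spikes added to k-space,
#'   producing global stripe patterns.
#' * `bias_field` — multiplication by `exp(P)/mean(exp(P))` where `P` is a
#'   random polynomial of order `order` over normalized coordinates, a
#'   smooth multiplicative field with mean one; zero-amplitude coefficients
#'   give the identity. The default coefficient amplitude yields roughly
#'   +/- 30 percent modulation over the field of view, typical of clinical
#'   field inhomogeneity.
#'
#' @param volume an [mri_volume()].
#' @param family one of `"motion"`, `"ghosting"`, `"spiking"`,
#'   `"bias_field"`.
#' @param seed integer seed.
#' @param params optional list overriding family defaults: `rot_deg` (5),
#'   `trans_vox` (2), `n_transforms` (2), `intensity` (0.3), `n_ghosts`
#'   (2:4), `n_spikes` (3), `spike_amp` (0.2), `order` (3), `coef_amp`
#'   (0.1).
#' @return The corrupted `lt_volume`.
#' @export
apply_artifact <- function(volume, family, seed = 1L, params = list()) {
  stopifnot(is_lt_volume(volume))
  if (!family %in% c("motion", "ghosting", "spiking", "bias_field"))
    stop("unknown artifact family: ", family)
  p <- modifyList(list(rot_deg = 5, trans_vox = 2, n_transforms = 2,
                       intensity = 0.3, n_ghosts = 2:4, n_spikes = 3,
                       spike_amp = 0.2, order = 3, coef_amp = 0.1), params)
  volume$data <- with_seed_(seed, switch(family,
    motion = artifact_motion(volume$data, p),
    ghosting = artifact_ghosting(volume$data, p),
    spiking = artifact_spiking(volume$data, p),
    bias_field = artifact_bias(volume$data, p)))
  volume
}

artifact_motion <- function(x, p) {
  d <- dim(x)
  acc <- x
  w <- 1
  for (i in seq_len(p$n_transforms)) {
    th <- deg2rad(runif(1, -p$rot_deg, p$rot_deg))
    tr <- runif(3, -p$trans_vox, p$trans_vox)
    cx <- (d - 1) / 2
    # output voxel -> input voxel: rotate about the grid centre, then shift
    R <- rbind(c(cos(th), -sin(th), 0),
               c(sin(th), cos(th), 0),
               c(0, 0, 1))
    off <- cx - R %*% cx + tr
    A <- cbind(R, off)
    wi <- runif(1, 0.1, 0.3)
    acc <- acc + wi * resample_affine(x, d, A, 0L)
    w <- w + wi
  }
  acc / w
}

artifact_ghosting <- function(x, p) {
  ax <- sample(1:2, 1L)                     # in-plane phase-encode axis
  n <- if (length(p$n_ghosts) > 1) sample(p$n_ghosts, 1L) else p$n_ghosts
  k <- stats::fft(x)
  idx <- seq(1L + n, dim(x)[ax], by = n)    # every n-th line, DC kept
  scale <- 1 - p$intensity
  if (ax == 1L) k[idx, , ] <- k[idx, , ] * scale
  else k[, idx, ] <- k[, idx, ] * scale
  Re(stats::fft(k, inverse = TRUE)) / length(x)
}

artifact_spiking <- function(x, p) {
  d <- dim(x)
  k <- stats::fft(x)
  n <- sample.int(p$n_spikes, 1L)
  amp <- p$spike_amp * max(Mod(k))
  for (i in seq_len(n)) {
    pos <- c(sample.int(d[1], 1L), sample.int(d[2], 1L), sample.int(d[3], 1L))
    phase <- runif(1, 0, 2 * pi)
    k[pos[1], pos[2], pos[3]] <- k[pos[1], pos[2], pos[3]] +
      amp * complex(modulus = 1, argument = phase)
  }
  Re(stats::fft(k, inverse = TRUE)) / length(x)
}

artifact_bias <- function(x, p) {
  d <- dim(x)
  cs <- lapply(d, function(n) seq(-1, 1, length.out = n))
  pow <- expand.grid(i = 0:p$order, j = 0:p$order, k = 0:p$order)
  pow <- pow[rowSums(pow) <= p$order & rowSums(pow) > 0, ]
  coef <- runif(nrow(pow), -p$coef_amp, p$coef_amp)
  P <- array(0, d)
  for (r in seq_len(nrow(pow))) {
    term <- outer(outer(cs[[1]]^pow$i[r], cs[[2]]^pow$j[r]), cs[[3]]^pow$k[r])
    P <- P + coef[r] * term
  }
  field <- exp(P)
  x * (field / mean(field))
}
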