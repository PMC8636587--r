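#' U-net configuration
#'
#' Architecture of the modified 3D U-net: an encoder–decoder with skip
#' connections at `depth` resolution levels. Each level applies two 3x3x3
#' convolutions, each followed by instance normalization (statistics per
#' sample per channel, appropriate at batch size 1) and ReLU; filter
#' counts start at `base_filters` and double with each pooling step
#' (16, 32, ..., 512 at the default depth 6). Down-sampling is by max
#' pooling; up-sampling is trilinear interpolation followed by a 1x1x1
#' convolution (fewer parameters than transposed convolutions); the final
#' 1x1x1 convolution and softmax yield per-voxel class probabilities for
#' the `classes` output channels.
#'
#' The pooling plan is anisotropic: a level pools z only while the current
#' z-extent is at least 8 (and even), otherwise it pools in-plane only —
#' a ~29-slice axial stack cannot be pooled six times along z.
#'
#' @param depth number of resolution levels (>= 2).
#' @param base_filters filters at the highest resolution (>= 1).
#' @param classes output classes (background, femur, tibia, fibula).
#' @param in_channels input image channels.
#' @return An object of class `lt_unet_config`.
#' @export
unet_config <- function(depth = 6L, base_filters = 16L, classes = 4L,
                        in_channels = 1L) {
  if (depth < 2L) stop("depth must be >= 2")
  if (base_filters < 1L) stop("base_filters must be >= 1")
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 classes = as.integer(classes),
                 in_channels = as.integer(in_channels)),
            class = "lt_unet_config")
}

#' Build (initialize) a 3D U-net
#'
#' Allocates and He-initializes all weights of the network described by
#' the config. The returned model is a plain list of parameter arrays plus
#' the config; the same model handles any input shape that satisfies the
#' pooling divisibility requirement (checked per forward pass).
#'
#' @param config an [unet_config()].
#' @param seed integer seed for the weight initialization.
#' @return An object of class `lt_unet`.
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  stopifnot(inherits(config, "lt_unet_config"))
  D <- config$depth
  f <- config$base_filters * 2^(0:(D - 1))
  params <- list()
  he <- function(k, cin, cout) {
    fan_in <- k[1] * k[2] * k[3] * cin
    array(rnorm(prod(k) * cin * cout, sd = sqrt(2 / fan_in)),
          c(k, cin, cout))
  }
  add_block <- function(prefix, cin, cout) {
    params[[paste0(prefix, "_conv1_w")]] <<- he(c(3, 3, 3), cin, cout)
    params[[paste0(prefix, "_conv1_b")]] <<- numeric(cout)
    params[[paste0(prefix, "_in1_gamma")]] <<- rep(1, cout)
    params[[paste0(prefix, "_in1_beta")]] <<- numeric(cout)
    params[[paste0(prefix, "_conv2_w")]] <<- he(c(3, 3, 3), cout, cout)
    params[[paste0(prefix, "_conv2_b")]] <<- numeric(cout)
    params[[paste0(prefix, "_in2_gamma")]] <<- rep(1, cout)
    params[[paste0(prefix, "_in2_beta")]] <<- numeric(cout)
  }
  with_seed_(seed, {
    cin <- config$in_channels
    for (k in seq_len(D)) {
      add_block(paste0("enc", k - 1), cin, f[k])
      cin <- f[k]
    }
    for (k in (D - 1):1) {
      params[[paste0("dec", k - 1, "_up_w")]] <- he(c(1, 1, 1), f[k + 1], f[k])
      params[[paste0("dec", k - 1, "_up_b")]] <- numeric(f[k])
      add_block(paste0("dec", k - 1), 2L * f[k], f[k])
    }
    params[["final_w"]] <- he(c(1, 1, 1), f[1], config$classes)
    params[["final_b"]] <- numeric(config$classes)
  })
  structure(list(config = config, params = params), class = "lt_unet")
}

#' @export
print.lt_unet <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  f <- x$config$base_filters * 2^(0:(x$config$depth - 1))
  cat(sprintf("<lt_unet> depth %d, filters %s, %d classes, %s parameters\n",
              x$config$depth, paste(f, collapse = "-"), x$config$classes,
              format(np, big.mark = ",")))
  invisible(x)
}

# Anisotropic pooling plan for a given input shape; errors name the first
# axis whose extent is not divisible by its cumulative pooling factor.
pooling_plan <- function(dim3, depth) {
  d <- dim3
  plan <- vector("list", depth - 1L)
  for (k in seq_len(depth - 1L)) {
    fz <- if (d[3] >= 8L && d[3] %% 2L == 0L) 2L else 1L
    for (ax in 1:2)
      if (d[ax] %% 2L != 0L)
        stop(sprintf(
          "%s axis length %d is not divisible by the pooling plan at level %d",
          c("x", "y", "z")[ax], dim3[ax], k))
    plan[[k]] <- c(2L, 2L, fz)
    d <- d %/% plan[[k]]
    if (any(d[1:2] < 1L))
      stop(sprintf("input too small for depth %d at level %d", depth, k))
  }
  plan
}

concat_ch <- function(a, b) {
  da <- dim(a)
  out <- array(0, c(da[1:3], da[4] + dim(b)[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(dim(b)[4])] <- b
  out
}

# One conv -> instance norm + ReLU -> conv -> instance norm + ReLU block
# (the ReLU is fused into the instance-norm kernels).
block_fw <- function(params, prefix, x, cache = NULL) {
  keep <- !is.null(cache)
  c1 <- conv3d_fw(x, params[[paste0(prefix, "_conv1_w")]],
                  params[[paste0(prefix, "_conv1_b")]])
  n1 <- instnorm_fw(c1, params[[paste0(prefix, "_in1_gamma")]],
                    params[[paste0(prefix, "_in1_beta")]], relu = TRUE)
  c2 <- conv3d_fw(n1$y, params[[paste0(prefix, "_conv2_w")]],
                  params[[paste0(prefix, "_conv2_b")]])
  n2 <- instnorm_fw(c2, params[[paste0(prefix, "_in2_gamma")]],
                    params[[paste0(prefix, "_in2_beta")]], relu = TRUE)
  if (keep) {
    cache[[prefix]] <- list(x = x, c1 = c1, n1 = n1[c("mu", "istd")],
                            r1 = n1$y, c2 = c2, n2 = n2[c("mu", "istd")])
  }
  list(y = n2$y, cache = cache)
}

block_bw <- function(params, prefix, cache, gy, grads, need_gx = TRUE) {
  cc <- cache[[prefix]]
  nb <- instnorm_bw(cc$c2, params[[paste0(prefix, "_in2_gamma")]],
                    params[[paste0(prefix, "_in2_beta")]],
                    cc$n2$mu, cc$n2$istd, gy, relu = TRUE)
  grads[[paste0(prefix, "_in2_gamma")]] <- nb$ggamma
  grads[[paste0(prefix, "_in2_beta")]] <- nb$gbeta
  cb <- conv3d_bw(cc$r1, params[[paste0(prefix, "_conv2_w")]], nb$gx)
  grads[[paste0(prefix, "_conv2_w")]] <- cb$gw
  grads[[paste0(prefix, "_conv2_b")]] <- cb$gb
  nb <- instnorm_bw(cc$c1, params[[paste0(prefix, "_in1_gamma")]],
                    params[[paste0(prefix, "_in1_beta")]],
                    cc$n1$mu, cc$n1$istd, cb$gx, relu = TRUE)
  grads[[paste0(prefix, "_in1_gamma")]] <- nb$ggamma
  grads[[paste0(prefix, "_in1_beta")]] <- nb$gbeta
  cb <- conv3d_bw(cc$x, params[[paste0(prefix, "_conv1_w")]], nb$gx,
                  need_gx = need_gx)
  grads[[paste0(prefix, "_conv1_w")]] <- cb$gw
  grads[[paste0(prefix, "_conv1_b")]] <- cb$gb
  list(gx = if (need_gx) cb$gx else NULL, grads = grads)
}

# Full forward pass; x is (X, Y, Z, in_channels). Returns logits and,
# when train = TRUE, the cache needed for the backward pass.
unet_forward <- function(model, x, train = FALSE) {
  cfg <- model$config
  p <- model$params
  D <- cfg$depth
  plan <- pooling_plan(dim(x)[1:3], D)
  cache <- if (train) list() else NULL
  skips <- vector("list", D)
  pools <- vector("list", D - 1L)
  h <- x
  for (k in seq_len(D)) {
    bf <- block_fw(p, paste0("enc", k - 1), h, cache)
    cache <- bf$cache
    skips[[k]] <- bf$y
    if (k < D) {
      pl <- maxpool3d_fw(bf$y, plan[[k]][1], plan[[k]][2], plan[[k]][3])
      pools[[k]] <- pl$idx
      h <- pl$y
    }
  }
  h <- skips[[D]]
  ups <- vector("list", D - 1L)
  for (k in (D - 1):1) {
    u <- upsample3d_fw(h, plan[[k]][1], plan[[k]][2], plan[[k]][3])
    uc <- conv3d_fw(u, p[[paste0("dec", k - 1, "_up_w")]],
                    p[[paste0("dec", k - 1, "_up_b")]])
    cat_in <- concat_ch(uc, skips[[k]])
    if (train) ups[[k]] <- u
    bf <- block_fw(p, paste0("dec", k - 1), cat_in, cache)
    cache <- bf$cache
    if (train) cache[[paste0("dec", k - 1)]]$cat_in <- cat_in
    h <- bf$y
  }
  logits <- conv3d_fw(h, p$final_w, p$final_b)
  if (train)
    list(logits = logits, cache = cache, plan = plan, pools = pools,
         ups = ups, skips_dim = lapply(skips, dim), x = x, dec_out = h)
  else list(logits = logits, plan = plan)
}

# Backward pass from d(loss)/d(logits); returns gradients for all params.
unet_backward <- function(model, fw, glogits) {
  cfg <- model$config
  p <- model$params
  D <- cfg$depth
  plan <- fw$plan
  grads <- list()
  cb <- conv3d_bw(fw$dec_out, p$final_w, glogits)
  grads$final_w <- cb$gw
  grads$final_b <- cb$gb
  gy <- cb$gx
  gskips <- vector("list", D)
  for (k in seq_len(D - 1)) {
    prefix <- paste0("dec", k - 1)
    bb <- block_bw(p, prefix, fw$cache, gy, grads)
    grads <- bb$grads
    gcat <- bb$gx
    cup <- nchan_after_up(cfg, k)  # channels out of the 1x1x1 up-conv
    guc <- gcat[, , , seq_len(cup), drop = FALSE]
    gskips[[k]] <- gcat[, , , cup + seq_len(dim(gcat)[4] - cup),
                        drop = FALSE]
    cb <- conv3d_bw(fw$ups[[k]], p[[paste0(prefix, "_up_w")]], guc)
    grads[[paste0(prefix, "_up_w")]] <- cb$gw
    grads[[paste0(prefix, "_up_b")]] <- cb$gb
    gy <- upsample3d_bw(cb$gx, plan[[k]][1], plan[[k]][2], plan[[k]][3],
                        fw$skips_dim[[k + 1]])
  }
  # encoder, deepest first: gy currently flows into the bottleneck block
  for (k in D:1) {
    g_in <- if (k == D) gy
    else {
      gp <- maxpool3d_bw(gy, fw$pools[[k]], fw$skips_dim[[k]])
      gp + gskips[[k]]
    }
    bb <- block_bw(p, paste0("enc", k - 1), fw$cache, g_in, grads,
                   need_gx = k > 1)
    grads <- bb$grads
    gy <- bb$gx
  }
  grads
}

nchan_after_up <- function(cfg, k) cfg$base_filters * 2^(k - 1)

#' Per-voxel class probabilities
#'
#' Runs the forward pass and applies the softmax over the class channel.
#'
#' @param model an `lt_unet`.
#' @param x numeric array (X, Y, Z) or (X, Y, Z, in_channels).
#' @return Array (X, Y, Z, classes) of probabilities summing to 1 per
#'   voxel.
#' @export
unet_probabilities <- function(model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  softmax_ch(unet_forward(model, x)$logits)
}

softmax_ch <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, prod(d[1:3]), d[4])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  array(e / rowSums(e), d)
}

#' Predict a label mask for a volume
#'
#' Preprocesses the volume (resample to the model's working spacing,
#' z-score normalize, pad to the pooling divisibility), runs the network,
#' takes the per-voxel argmax (ties broken toward the lower class code),
#' and maps the mask back to the native grid (unpad, nearest-neighbour
#' resample).
#'
#' @param model an `lt_unet`.
#' @param volume an [mri_volume()].
#' @param target_spacing working spacing of the network, mm.
#' @param pad_multiple divisibility required by the pooling plan.
#' @return An `lt_mask` on the native grid of `volume`.
#' @export
predict_mask <- function(model, volume, target_spacing = c(0.6, 0.6, 6.5),
                         pad_multiple = c(32L, 32L, 1L)) {
  stopifnot(inherits(model, "lt_unet"), is_lt_volume(volume))
  pre <- preprocess_volume(volume, target_spacing, pad_multiple)
  x <- pre$data
  dim(x) <- c(dim(x), 1L)
  prob <- softmax_ch(unet_forward(model, x)$logits)
  cls <- apply(matrix(prob, prod(dim(x)[1:3]), dim(prob)[4]), 1,
               which.max) - 1L
  mk <- label_mask(array(as.integer(cls), dim(x)[1:3]), pre$spacing,
                   volume$region)
  attr(mk, "lt_pad") <- attr(pre, "lt_pad")
  mk <- lt_unpad(mk)
  native <- attr(pre, "lt_native")
  sc <- native$spacing / mk$spacing
  A <- cbind(diag(sc), (sc - 1) / 2)
  label_mask(resample_affine(mk$data + 0, native$dim, A, 1L, clamp = 1L),
             native$spacing, volume$region)
}

#' Save / load a model
#'
#' Model checkpoints are stored with R's native serialization.
#'
#' @param model an `lt_unet`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "lt_unet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "lt_unet"))
  m
}
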