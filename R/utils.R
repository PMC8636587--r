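`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG seed, restoring the caller's state.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# linear index helpers for 3D arrays (1-based)
index_to_xyz <- function(i, d) {
  i0 <- i - 1L
  cbind(x = i0 %% d[1] + 1L,
        y = (i0 %/% d[1]) %% d[2] + 1L,
        z = i0 %/% (d[1] * d[2]) + 1L)
}
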