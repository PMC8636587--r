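# Shared phantom fixtures, generated in code and cached per session.
# Tests use a 128-voxel / 1.2 mm in-plane grid: half the acquisition
# resolution, which keeps voxelization error well inside the tolerances
# while making generation and measurement fast.

.phantom_cache <- new.env(parent = emptyenv())

test_phantom <- function(femoral = 15, tibial = 30, side = "right",
                         rotation = c(hip = 0, knee = 0, ankle = 0),
                         seed = 1, ...) {
  key <- paste(femoral, tibial, side, paste(rotation, collapse = ","),
               seed, ..., sep = "|")
  if (!is.null(.phantom_cache[[key]])) return(.phantom_cache[[key]])
  sp <- phantom_spec(femoral_torsion = femoral, tibial_torsion = tibial,
                     side = side, stack_rotation = rotation,
                     spacing = c(1.2, 1.2, 6.5), inplane = 128L,
                     seed = seed, ...)
  ph <- generate_phantom(sp)
  .phantom_cache[[key]] <- ph
  ph
}

measure_phantom <- function(ph) {
  measure_limb(ph$hip$mask, ph$knee$mask, ph$ankle$mask)
}

# grow a connected random blob of n_pts voxels on a W x W single-slice
# grid by seeded accretion (used by the landmark oracle tests)
random_blob_slice <- function(n_pts, W = 24L, seed = 1L) {
  set.seed(seed)
  occ <- matrix(FALSE, W, W)
  cur <- matrix(c(W %/% 2L, W %/% 2L), 1)
  occ[cur[1], cur[2]] <- TRUE
  frontier <- cur
  while (sum(occ) < n_pts && nrow(frontier) > 0) {
    i <- sample.int(nrow(frontier), 1L)
    p <- frontier[i, ]
    nb <- cbind(p[1] + c(-1L, 1L, 0L, 0L), p[2] + c(0L, 0L, -1L, 1L))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= W & nb[, 2] >= 1 & nb[, 2] <= W, ,
             drop = FALSE]
    nb <- nb[!occ[nb], drop = FALSE, ]
    if (nrow(nb) == 0L) {
      frontier <- frontier[-i, , drop = FALSE]
      next
    }
    q <- nb[sample.int(nrow(nb), 1L), ]
    occ[q[1], q[2]] <- TRUE
    frontier <- rbind(frontier, q)
  }
  occ
}
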