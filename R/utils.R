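# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# angle (degrees) between vectors and the +z axis; rows of v are vectors
angle_to_z_deg <- function(v) {
  v <- matrix(v, ncol = 3)
  nv <- sqrt(rowSums(v^2))
  acos(pmin(1, pmax(-1, v[, 3] / nv))) * 180 / pi
}
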