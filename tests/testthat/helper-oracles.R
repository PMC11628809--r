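# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Mean-torque quadrature oracle: find the first-order torque strength whose
# Boltzmann orientation average reproduces <cos^2 beta> = (1 + 4|s|)/3, then
# integrate <cos beta> numerically under that torque.
oracle_boltzmann_moment <- function(u, n) {
  num <- stats::integrate(function(x) x^n * exp(u * (x - 1)), -1, 1)$value
  den <- stats::integrate(function(x) exp(u * (x - 1)), -1, 1)$value
  num / den
}

oracle_cos_beta <- function(s_cd) {
  target <- (1 + 4 * abs(s_cd)) / 3
  u <- stats::uniroot(function(u) oracle_boltzmann_moment(u, 2) - target,
                      c(1e-6, 500))$root
  oracle_boltzmann_moment(u, 1)
}

# Closed-form OLS via the normal equations (no lm).
oracle_ols <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  res <- y - intercept - slope * x
  list(slope = slope, intercept = intercept,
       r_squared = 1 - sum(res^2) / sum((y - yb)^2))
}

# Brute-force periodic minimum distances: explicit enumeration of all 27
# periodic images, no minimum-image shortcut.
oracle_min_dist <- function(xa, xb, box) {
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  dmin <- matrix(Inf, nrow(xa), nrow(xb))
  for (s in seq_len(nrow(shifts))) {
    xb_s <- sweep(xb, 2, shifts[s, ] * box, "+")
    d2 <- outer(rowSums(xa^2), rowSums(xb_s^2), "+") - 2 * xa %*% t(xb_s)
    dmin <- pmin(dmin, sqrt(pmax(d2, 0)))
  }
  dmin
}

# Brute-force RDF bin counts on the same half-open bins [r, r + dr).
oracle_rdf_counts <- function(xa, xb, idx_a, idx_b, box, edges) {
  dmin <- oracle_min_dist(xa, xb, box)
  same <- outer(idx_a, idx_b, "==")
  d <- dmin[!same]
  d <- d[d < max(edges)]
  counts <- numeric(length(edges) - 1L)
  for (k in seq_along(counts)) {
    counts[k] <- sum(d >= edges[k] & d < edges[k + 1L])
  }
  counts
}

# Random labelled point frame (single-atom "lipids" plus protein atoms).
random_point_frame <- function(n_lipids, n_protein, box, seed) {
  with_seed_test(seed, {
    n <- n_lipids + n_protein
    coords <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                    stats::runif(n, 0, box[3]))
    atoms <- data.frame(
      resname = c(rep("LIP", n_lipids), rep("GLPG", n_protein)),
      resid = c(seq_len(n_lipids), rep(90000L, n_protein)),
      atomname = c(rep("C1", n_lipids), rep("CA", n_protein)))
    membrane_frame(coords, atoms, box)
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}
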