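#' First-order mean-torque segment projection
#'
#' Maps a segmental order parameter onto the mean projection of the chain
#' segment along the bilayer normal, `<cos(beta)>`, under the first-order
#' mean-torque model: for `s_cd <= -1/8`,
#' `<cos beta> = (1 + sqrt((-8 s_cd - 1)/3)) / 2`. For weakly ordered
#' segments (`-1/8 < s_cd < 0`) the first-order expression has no real
#' solution and the second-moment estimate
#' `<cos beta> ~ sqrt(<cos^2 beta>)` with `<cos^2 beta> = (1 + 4|s_cd|)/3`
#' is used instead. Note the two branches do not join continuously at
#' `s_cd = -1/8` (0.5 versus sqrt(0.5)); fluid-phase methylene orders sit
#' well inside the first-order branch, so the fallback only affects the most
#' disordered chain ends.
#'
#' @param s_cd segmental order parameter(s), in `[-0.5, 0)`.
#' @return `<cos beta>` in `(0, 1]`, same length as `s_cd`.
#' @examples
#' cos_beta_first_order(-0.5)   # 1: all-trans limit
#' cos_beta_first_order(-0.125) # 0.5: branch boundary
#' @export
cos_beta_first_order <- function(s_cd) {
  s_cd <- as.numeric(s_cd)
  if (any(!is.finite(s_cd)) || any(s_cd >= 0) || any(s_cd < -0.5 - 1e-12)) {
    stop("s_cd must lie in [-0.5, 0)", call. = FALSE)
  }
  out <- numeric(length(s_cd))
  first <- s_cd <= -0.125
  out[first] <- 0.5 * (1 + sqrt(pmax(0, (-8 * s_cd[first] - 1) / 3)))
  out[!first] <- sqrt((1 + 4 * abs(s_cd[!first])) / 3)
  out
}

#' Projected acyl chain length from an order profile
#'
#' Sums the per-segment projected travel along the bilayer normal:
#' `l_c = sum_i l_cc * <cos beta_i>` with the projected repeat
#' `l_cc = 1.27` angstrom per segment (half the 2.54 angstrom all-trans
#' two-carbon repeat). The terminal methyl contributes one segment using its
#' chain-referenced order parameter (the threefold methyl-rotation reduction
#' is already removed at the spectral layer, so no further geometric factor
#' applies). In the all-trans limit (every `s_cd = -0.5`) the result is
#' exactly `1.27 * segment_count`.
#'
#' @param profile an [order_profile()].
#' @param l_cc projected segment repeat, angstrom.
#' @return An object of class `chain_length_result`: list with `l_c`
#'   (angstrom), `cos_beta` (per segment), `model_order`, `segment_count`.
#' @export
projected_chain_length <- function(profile, l_cc = 1.27) {
  stopifnot(inherits(profile, "order_profile"))
  if (nrow(profile) == 0L) stop("empty profile", call. = FALSE)
  s <- profile$s_cd
  s[s == 0] <- -1e-6 # fully isotropic segments carry (numerically) zero order
  cb <- cos_beta_first_order(s)
  structure(list(l_c = l_cc * sum(cb), cos_beta = cb,
                 model_order = "first_order",
                 segment_count = length(cb),
                 carbon_index = profile$carbon_index),
            class = "chain_length_result")
}

#' @export
print.chain_length_result <- function(x, ...) {
  cat(sprintf("<chain_length_result> l_c = %.3f A over %d segments (first-order mean torque)\n",
              x$l_c, x$segment_count))
  invisible(x)
}

#' Fit a leaflet-thickness versus cholesterol linear model
#'
#' Ordinary least squares of projected chain length on cholesterol content,
#' the regression used to map a sample's measured cholesterol level onto its
#' leaflet thickness.
#'
#' @param cholesterol cholesterol content, mol %.
#' @param l_c projected chain length, angstrom.
#' @return An object of class `thickness_model` wrapping the `lm` fit, with
#'   elements `slope` (angstrom per mol %), `intercept` (angstrom),
#'   `r_squared`, `n_points`.
#' @examples
#' m <- fit_thickness_model(c(0, 10, 20, 30), 9.7 + 0.06 * c(0, 10, 20, 30))
#' predict(m, 15)
#' @export
fit_thickness_model <- function(cholesterol, l_c) {
  cholesterol <- as.numeric(cholesterol)
  l_c <- as.numeric(l_c)
  if (length(cholesterol) != length(l_c) || length(l_c) < 2L) {
    stop("need >= 2 (cholesterol, l_c) points", call. = FALSE)
  }
  if (length(unique(cholesterol)) < 2L) {
    stop("all cholesterol values identical; slope is unidentifiable", call. = FALSE)
  }
  fit <- stats::lm(l_c ~ cholesterol)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((l_c - mean(l_c))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_points = length(l_c),
                 fit = fit),
            class = "thickness_model")
}

#' @export
print.thickness_model <- function(x, ...) {
  cat(sprintf("<thickness_model> l_c = %.4f + %.4f * chol (A vs mol %%), r^2 = %.4f, n = %d\n",
              x$intercept, x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.thickness_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @rdname fit_thickness_model
#' @param object a `thickness_model`.
#' @param cholesterol_new cholesterol content(s), mol %, at which to predict.
#' @param ... unused.
#' @export
predict.thickness_model <- function(object, cholesterol_new, ...) {
  object$intercept + object$slope * as.numeric(cholesterol_new)
}
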