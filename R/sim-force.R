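#' Simulation parameters for synthetic force curves
#'
#' Defaults encode the experimental conditions of the AFM protocol the
#' package targets: 1.5 um of piezo travel per approach (sampled at 600
#' points, i.e. one second of data at 1.5 um/s), true contact at 80% of the
#' travel so that the post-contact travel (~300 nm) yields maximal
#' indentations in the 200-300 nm range, a cylindrical tip of radius 1 um,
#' incompressible-sample Poisson ratio 0.5, a 0.1 N/m cantilever and 10 pN
#' of Gaussian force noise. The curve is quasi-static: the approach rate
#' maps to sample spacing only.
#'
#' @param E_true true Young's modulus, Pa.
#' @param a cylinder (flat punch) radius, m.
#' @param v Poisson ratio, in `[0, 0.5]`.
#' @param k cantilever spring constant, N/m.
#' @param z_c_true true contact position, m (within the ramp).
#' @param ramp_extent total piezo travel, m.
#' @param n_samples number of samples (>= 50), uniform in piezo position.
#' @param sigma_F standard deviation of Gaussian force noise, N.
#' @param baseline_slope baseline force drift per metre of piezo travel, N/m
#'   (applied over the whole curve, emulating thermal drift).
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return A validated parameter list of class `curve_sim_params`.
#' @export
curve_sim_params <- function(E_true = 623, a = 1e-6, v = 0.5, k = 0.1,
                             z_c_true = 1.2e-6, ramp_extent = 1.5e-6,
                             n_samples = 600L, sigma_F = 1e-11,
                             baseline_slope = 0, seed = NULL) {
  .check_scalar(E_true, "E_true", lower = 0, strict_lower = TRUE)
  .check_scalar(a, "a", lower = 0, strict_lower = TRUE)
  .check_scalar(v, "v", lower = 0, upper = 0.5 + 1e-12)
  .check_scalar(k, "k", lower = 0, strict_lower = TRUE)
  .check_scalar(z_c_true, "z_c_true", lower = 0)
  .check_scalar(ramp_extent, "ramp_extent", lower = 0, strict_lower = TRUE)
  .check_scalar(sigma_F, "sigma_F", lower = 0)
  .check_scalar(baseline_slope, "baseline_slope")
  n_samples <- as.integer(n_samples)
  if (n_samples < 50L) stop("'n_samples' must be >= 50", call. = FALSE)
  if (z_c_true >= ramp_extent) {
    stop("'z_c_true' must lie inside the ramp", call. = FALSE)
  }
  structure(list(E_true = E_true, a = a, v = v, k = k, z_c_true = z_c_true,
                 ramp_extent = ramp_extent, n_samples = n_samples,
                 sigma_F = sigma_F, baseline_slope = baseline_slope,
                 seed = seed),
            class = "curve_sim_params")
}

#' Generate a synthetic force curve with known ground truth
#'
#' Simulates the approach segment of a flat-punch indentation. Past the true
#' contact point the cantilever deflection solves the self-consistency
#' relation `k * delta = C * ((z - z_c) - delta)` with
#' `C = 2 a E / (1 - v^2)` (the indentation is the piezo displacement minus
#' the deflection); for this linear contact model the fixed point has the
#' exact closed form `delta = C * (z - z_c) / (k + C)`, which is what is
#' evaluated. Before contact the deflection is the (possibly drifting)
#' baseline. Gaussian force noise of SD `sigma_F` is added as deflection
#' noise `sigma_F / k` over the whole curve.
#'
#' The returned curve carries a `truth` attribute (`E`, `z_c`, `sigma_F`,
#' `a`, `v`) for parameter-recovery testing.
#'
#' @param p a [curve_sim_params()] object.
#' @return A [force_curve()].
#' @examples
#' fc <- generate_force_curve(curve_sim_params(sigma_F = 0))
#' fit <- fit_young_modulus(fc, indenter_geometry(a = 1e-6, v = 0.5))
#' fit$E # recovers 623 Pa
#' @export
generate_force_curve <- function(p) {
  if (!inherits(p, "curve_sim_params")) p <- do.call(curve_sim_params, p)
  if (!is.null(p$seed)) set.seed(p$seed)
  z <- seq(0, p$ramp_extent, length.out = p$n_samples)
  C <- 2 * p$a * p$E_true / (1 - p$v^2)
  dz <- pmax(z - p$z_c_true, 0)
  defl_elastic <- C * dz / (p$k + C)
  drift <- p$baseline_slope * (z - z[1]) / p$k
  noise <- if (p$sigma_F > 0) rnorm(p$n_samples, 0, p$sigma_F / p$k) else 0
  fc <- force_curve(z, defl_elastic + drift + noise, p$k)
  attr(fc, "truth") <- list(E = p$E_true, z_c = p$z_c_true,
                            sigma_F = p$sigma_F, a = p$a, v = p$v)
  fc
}
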