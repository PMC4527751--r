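#' Indenter geometry for the flat-punch Hertz model
#'
#' @param a cylinder radius in metres. Not printed on most tip data sheets
#'   for specialty flat punches, so it is a mandatory analysis input; the
#'   1 um default triggers a warning when relied upon implicitly.
#' @param v Poisson ratio of the sample; 0.5 for incompressible soft cells.
#' @return A list of class `indenter_geometry`.
#' @export
indenter_geometry <- function(a = 1e-6, v = 0.5) {
  .check_scalar(a, "a", lower = 0, strict_lower = TRUE)
  .check_scalar(v, "v", lower = 0, upper = 0.5 + 1e-12)
  structure(list(a = a, v = v), class = "indenter_geometry")
}

#' Flat-punch Hertz force
#'
#' For a cylindrical tip of radius `a` indenting a linear-elastic half-space
#' of Young's modulus `E` and Poisson ratio `v` to depth `d`, the applied
#' force is `F = 2 a E / (1 - v^2) * d` (linear in depth, unlike the
#' spherical or conical variants).
#'
#' @param E Young's modulus, Pa.
#' @param geom an [indenter_geometry()].
#' @param d indentation depth(s), m; must be non-negative.
#' @return Force(s) in newtons.
#' @examples
#' hertz_force(623, indenter_geometry(a = 1e-6, v = 0.5), 250e-9) # 4.153e-10 N
#' @export
hertz_force <- function(E, geom, d) {
  stopifnot(inherits(geom, "indenter_geometry"))
  .check_finite(E, "E")
  .check_finite(d, "d")
  if (any(d < 0)) stop("indentation depth 'd' must be >= 0", call. = FALSE)
  2 * geom$a * E / (1 - geom$v^2) * d
}

# Effective noise scale used for both contact detection and the RMSD
# stopping rule. On noiseless (synthetic) curves the sample SD is zero, so a
# floor keeps both rules well defined: 1e-7 of the force scale sits safely
# above the sqrt(eps) ~ 1e-8 cancellation noise of the incremental RSS
# update while staying ~5 orders of magnitude below any real instrument
# noise, plus a tiny absolute term for all-zero curves.
#' @noRd
.sigma_eff <- function(sigma_F, force) {
  max(sigma_F, 1e-7 * max(abs(force)), 1e-18)
}

#' Estimate baseline force noise of a curve
#'
#' The first `baseline_fraction` of samples (the non-contact approach) is
#' detrended by an ordinary least-squares line in `z`; the noise is the
#' standard deviation of the force residuals `k * (deflection - line)`.
#' The fitted line also serves downstream as the baseline that is
#' subtracted from the whole curve before any force is computed, which makes
#' the analysis insensitive to constant deflection offsets and linear drift.
#'
#' @param curve a [force_curve()].
#' @param baseline_fraction fraction of leading samples assumed to be
#'   contact-free, in `(0, 0.5]`.
#' @return A list of class `noise_estimate` with `sigma_F` (N), `window`
#'   (first/last index used) and `coef` (intercept/slope of the deflection
#'   baseline in metres vs `z`).
#' @export
estimate_noise <- function(curve, baseline_fraction = 0.3) {
  stopifnot(inherits(curve, "force_curve"))
  .check_scalar(baseline_fraction, "baseline_fraction", lower = 0, upper = 0.5,
                strict_lower = TRUE)
  n <- length(curve$z)
  m <- floor(n * baseline_fraction)
  if (m < 10L) stop("baseline window has fewer than 10 samples", call. = FALSE)
  idx <- seq_len(m)
  fit <- stats::lm.fit(cbind(1, curve$z[idx]), curve$deflection[idx])
  structure(list(sigma_F = stats::sd(fit$residuals) * curve$k,
                 window = c(1L, m),
                 coef = unname(fit$coefficients)),
            class = "noise_estimate")
}

# Baseline-subtracted force over the whole curve, N.
#' @noRd
.baseline_force <- function(curve, noise) {
  curve$k * (curve$deflection - (noise$coef[1] + noise$coef[2] * curve$z))
}

#' Detect the experimental contact point from the curve noise
#'
#' Returns the piezo position of the first sample whose baseline-subtracted
#' force reaches `threshold_factor` times the baseline noise and that is
#' followed by `guard` samples which all remain at or above the threshold.
#' The guard rejects isolated noise spikes (a single >= 3 sigma outlier
#' occurs with probability ~0.13% per sample); requiring sustained
#' exceedance rather than strict monotone growth keeps the rule usable on
#' noisy data while skipping transient spikes all the same.
#'
#' This crossing sits systematically *after* the true mechanical contact, by
#' roughly `3 sigma` divided by the post-contact force slope -- which is
#' precisely why [fit_young_modulus()] re-examines candidate contact points
#' up to 50 nm on either side of it.
#'
#' @param curve a [force_curve()].
#' @param noise a [estimate_noise()] result for the same curve.
#' @param threshold_factor multiple of the noise SD defining contact
#'   (default 3).
#' @param guard number of subsequent samples that must stay above the
#'   threshold (default 5).
#' @return A list with `index`, `z` (m) and `threshold` (N).
#' @export
find_contact_point <- function(curve, noise, threshold_factor = 3, guard = 5L) {
  stopifnot(inherits(curve, "force_curve"), inherits(noise, "noise_estimate"))
  force <- .baseline_force(curve, noise)
  thr <- threshold_factor * .sigma_eff(noise$sigma_F, force)
  n <- length(force)
  for (i in which(force >= thr)) {
    ahead <- i:min(n, i + guard)
    if (all(force[ahead] >= thr)) {
      return(list(index = i, z = curve$z[i], threshold = thr))
    }
  }
  stop("no contact: force never sustainably exceeds ",
       format(thr, digits = 3), " N", call. = FALSE)
}

#' Fit the Hertz model at one candidate contact point
#'
#' For a candidate contact position `z_c`, the per-sample indentation is
#' `d_i = (z_i - z_c) - (defl_i - baseline_i)` for samples past `z_c`,
#' clipped at zero. Starting from `min_window` samples, the fit window grows
#' one sample at a time; at each size the modulus is the least-squares slope
#' through the origin,
#' `E = (sum F_i d_i / sum d_i^2) * (1 - v^2) / (2 a)`, and the RMSD of the
#' fitted forces is recorded. Growth stops at the last window whose RMSD is
#' still within three times the experimental noise; that window's `E`,
#' size and RMSD are returned. A candidate whose very first window already
#' violates the rule (or with too few samples past it) is infeasible.
#'
#' @param curve a [force_curve()].
#' @param z_c candidate contact position, m (inside the curve range).
#' @param geom an [indenter_geometry()].
#' @param noise a [estimate_noise()] result.
#' @param min_window minimum fit-window size, samples.
#' @param rmsd_factor stopping multiple of the noise SD (default 3).
#' @return A list with `E` (Pa), `n_points`, `rmsd` (N), `d_max` (m) and
#'   `feasible`; infeasible candidates have `feasible = FALSE` and `NA`
#'   results.
#' @export
fit_window_at_candidate <- function(curve, z_c, geom, noise,
                                    min_window = 10L, rmsd_factor = 3) {
  stopifnot(inherits(curve, "force_curve"), inherits(geom, "indenter_geometry"),
            inherits(noise, "noise_estimate"))
  infeasible <- list(E = NA_real_, n_points = NA_integer_, rmsd = NA_real_,
                     d_max = NA_real_, feasible = FALSE)
  if (z_c < min(curve$z) || z_c > max(curve$z)) return(infeasible)
  defl0 <- curve$deflection - (noise$coef[1] + noise$coef[2] * curve$z)
  post <- which(curve$z > z_c)
  if (length(post) < min_window) return(infeasible)
  d <- (curve$z[post] - z_c) - defl0[post]
  d[d < 0] <- 0
  force <- curve$k * defl0[post]

  cfd <- cumsum(force * d)
  cd2 <- cumsum(d * d)
  cf2 <- cumsum(force * force)
  w <- seq.int(min_window, length(post))
  slope <- ifelse(cd2[w] > 0, cfd[w] / cd2[w], 0)
  rss <- pmax(cf2[w] - slope * cfd[w], 0)
  rmsd <- sqrt(rss / w)

  tol <- rmsd_factor * .sigma_eff(noise$sigma_F, force)
  ok <- rmsd <= tol
  if (!ok[1]) return(infeasible)
  stop_at <- if (all(ok)) length(w) else which(!ok)[1] - 1L
  n_acc <- w[stop_at]
  list(E = max(0, slope[stop_at]) * (1 - geom$v^2) / (2 * geom$a),
       n_points = n_acc,
       rmsd = rmsd[stop_at],
       d_max = max(d[seq_len(n_acc)]),
       feasible = TRUE)
}

#' Fit the Young's modulus of a force curve
#'
#' Full curve analysis: baseline-noise estimation, experimental contact
#' point at three times the noise, then a grid of candidate contact points
#' spanning `grid_halfwidth` before and after it in `grid_step` increments
#' (inclusive of the experimental point itself; 21 candidates with the
#' defaults). Every candidate is fitted with [fit_window_at_candidate()];
#' the accepted fit is the feasible candidate with the most data points,
#' ties broken by lowest RMSD, then by proximity to the experimental contact
#' point, then by grid order. The complete per-candidate grid is returned
#' for audit.
#'
#' @param curve a [force_curve()].
#' @param geom an [indenter_geometry()]. If omitted, the 1 um default radius
#'   is used with a warning, since the tip radius is an instrument property
#'   that should come from metadata.
#' @param min_window minimum fit-window size, samples.
#' @param baseline_fraction passed to [estimate_noise()].
#' @param grid_halfwidth half-width of the candidate grid, m (default 50 nm).
#' @param grid_step candidate spacing, m (default 5 nm).
#' @param threshold_factor,guard passed to [find_contact_point()].
#' @param rmsd_factor stopping multiple for [fit_window_at_candidate()].
#' @return An object of class `hertz_fit`: `E` (Pa), `z_c` (m), `n_points`,
#'   `rmsd` (N), `d_max` (m), `z_exp` (experimental contact, m), `sigma_F`
#'   (N), and `candidate_grid` (data frame of all candidates).
#' @examples
#' fc <- generate_force_curve(curve_sim_params(E_true = 1366, seed = 7))
#' fit_young_modulus(fc, indenter_geometry())
#' @export
fit_young_modulus <- function(curve, geom = NULL, min_window = 10L,
                              baseline_fraction = 0.3,
                              grid_halfwidth = 50e-9, grid_step = 5e-9,
                              threshold_factor = 3, guard = 5L,
                              rmsd_factor = 3) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(geom)) {
    warning("indenter radius not supplied; defaulting to a = 1 um",
            call. = FALSE)
    geom <- indenter_geometry()
  }
  noise <- estimate_noise(curve, baseline_fraction)
  cp <- find_contact_point(curve, noise, threshold_factor, guard)

  offsets <- seq(-grid_halfwidth, grid_halfwidth, by = grid_step)
  cand_z <- cp$z + offsets
  rows <- lapply(cand_z, function(zc) {
    f <- fit_window_at_candidate(curve, zc, geom, noise,
                                 min_window = min_window,
                                 rmsd_factor = rmsd_factor)
    data.frame(z_c = zc, E = f$E, n_points = f$n_points, rmsd = f$rmsd,
               d_max = f$d_max, feasible = f$feasible)
  })
  grid <- do.call(rbind, rows)

  feas <- which(grid$feasible)
  if (length(feas) == 0L) {
    stop("unfittable curve: no feasible contact-point candidate", call. = FALSE)
  }
  ord <- feas[order(-grid$n_points[feas], grid$rmsd[feas],
                    abs(grid$z_c[feas] - cp$z))]
  best <- ord[1L]
  structure(list(E = grid$E[best], z_c = grid$z_c[best],
                 n_points = grid$n_points[best], rmsd = grid$rmsd[best],
                 d_max = grid$d_max[best], z_exp = cp$z,
                 sigma_F = noise$sigma_F, candidate_grid = grid),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf(paste0("<hertz_fit> E = %.4g Pa  (z_c = %.4g m, %d points, ",
                     "rmsd = %.3g N, d_max = %.3g m)\n"),
              x$E, x$z_c, x$n_points, x$rmsd, x$d_max))
  invisible(x)
}
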