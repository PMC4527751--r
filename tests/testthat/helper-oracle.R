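# Independent brute-force re-implementation of the force-curve analysis,
# used as the oracle for selection-equivalence tests. It enumerates every
# candidate and every window size explicitly, fits each window through the
# origin via QR (stats::lm.fit) rather than the closed-form slope, and
# re-derives baseline, noise and contact detection with its own code. The
# numerical contract it shares with the package (3x-noise rules plus the
# documented noise floor max(sigma, 1e-7 * max|F|, 1e-18)) is part of the
# method, not of the implementation.

oracle_sigma_eff <- function(sigma, force) {
  max(sigma, 1e-7 * max(abs(force)), 1e-18)
}

oracle_fit <- function(curve, geom, min_window = 10L, baseline_fraction = 0.3,
                       halfwidth = 50e-9, step = 5e-9, guard = 5L) {
  n <- length(curve$z)
  idx <- seq_len(floor(n * baseline_fraction))
  base_fit <- stats::lm(curve$deflection[idx] ~ curve$z[idx])
  b <- unname(coef(base_fit))
  defl0 <- curve$deflection - (b[1] + b[2] * curve$z)
  force <- curve$k * defl0
  sigma <- sd(residuals(base_fit)) * curve$k

  # contact: first sustained 3-sigma exceedance
  thr <- 3 * oracle_sigma_eff(sigma, force)
  i_exp <- NA_integer_
  for (i in seq_len(n)) {
    if (force[i] >= thr && all(force[i:min(n, i + guard)] >= thr)) {
      i_exp <- i
      break
    }
  }
  if (is.na(i_exp)) stop("oracle: no contact")
  z_exp <- curve$z[i_exp]

  cands <- z_exp + seq(-halfwidth, halfwidth, by = step)
  res <- data.frame(cand = seq_along(cands), z_c = cands, E = NA_real_,
                    n_points = NA_integer_, rmsd = NA_real_, feasible = FALSE)
  for (ci in seq_along(cands)) {
    zc <- cands[ci]
    if (zc < min(curve$z) || zc > max(curve$z)) next
    post <- which(curve$z > zc)
    if (length(post) < min_window) next
    d <- (curve$z[post] - zc) - defl0[post]
    d <- pmax(d, 0)
    f <- force[post]
    tol <- 3 * oracle_sigma_eff(sigma, f)
    best <- NULL
    for (w in min_window:length(post)) {
      dw <- d[1:w]
      if (all(dw == 0)) {
        slope <- 0
        resid <- f[1:w]
      } else {
        qr_fit <- stats::lm.fit(matrix(dw, ncol = 1), f[1:w])
        slope <- unname(qr_fit$coefficients[1])
        resid <- qr_fit$residuals
      }
      rmsd <- sqrt(mean(resid^2))
      if (rmsd > tol) break
      best <- list(E = max(0, slope) * (1 - geom$v^2) / (2 * geom$a),
                   n_points = w, rmsd = rmsd)
    }
    if (!is.null(best)) {
      res$E[ci] <- best$E
      res$n_points[ci] <- best$n_points
      res$rmsd[ci] <- best$rmsd
      res$feasible[ci] <- TRUE
    }
  }
  feas <- res[res$feasible, ]
  if (nrow(feas) == 0L) stop("oracle: unfittable")
  feas <- feas[order(-feas$n_points, feas$rmsd, abs(feas$z_c - z_exp)), ]
  list(E = feas$E[1], z_c = feas$z_c[1], n_points = feas$n_points[1],
       rmsd = feas$rmsd[1], z_exp = z_exp, grid = res)
}

# Random curve parameters used by equivalence/property tests. Moduli span
# the soft-cell range, contact position and noise vary around the protocol
# defaults.
random_curve_params <- function(seed) {
  set.seed(seed)
  E <- exp(runif(1, log(200), log(5000)))
  zc <- runif(1, 1.1e-6, 1.3e-6)
  sig <- runif(1, 5e-12, 3e-11)
  curve_sim_params(E_true = E, z_c_true = zc, sigma_F = sig,
                   seed = seed + 1L)
}

# Noise level of acceptance-style recovery experiments: 5% of the noiseless
# curve's maximal baseline-subtracted force under the same conditions.
noise_5pct <- function(E_true) {
  fc0 <- generate_force_curve(curve_sim_params(E_true = E_true, sigma_F = 0))
  ns <- estimate_noise(fc0)
  f <- fc0$k * (fc0$deflection - (ns$coef[1] + ns$coef[2] * fc0$z))
  0.05 * max(f)
}
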