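# Force-curve analysis: noise estimation, contact detection, Hertz fits.

make_flat_curve <- function(n = 600, k = 0.1, deflection = rep(0, n)) {
  force_curve(seq(0, 1.5e-6, length.out = n), deflection, k)
}

test_that("baseline noise estimation detrends and recovers injected noise", {
  expect_equal(estimate_noise(make_flat_curve())$sigma_F, 0)

  # pure tilt, no noise: detrending must null it out
  n <- 600
  z <- seq(0, 1.5e-6, length.out = n)
  tilted <- force_curve(z, 2e-3 * z, 0.1)
  expect_lt(estimate_noise(tilted)$sigma_F, 1e-18)

  # injected 10 pN on a 500-sample baseline window: SD chi-distributed,
  # 3 relative SDs of the sample SD ~ 3/sqrt(2*499) ~ 9.5% < 1.5 pN band
  set.seed(11)
  k <- 0.02
  n <- 1700 # baseline_fraction 0.3 -> 510-sample window
  z <- seq(0, 4e-6, length.out = n)
  noisy <- force_curve(z, rnorm(n, 0, 1e-11 / k), k)
  expect_equal(estimate_noise(noisy, 0.3)$sigma_F, 1e-11, tolerance = 0.15)

  expect_error(estimate_noise(make_flat_curve(), 0.6), "baseline_fraction")
  expect_error(estimate_noise(make_flat_curve(n = 60), 0.1), "fewer than 10")
})

test_that("contact detection finds a constructed crossing and skips spikes", {
  n <- 600
  k <- 0.1
  z <- seq(0, 1.5e-6, length.out = n)
  ramp <- pmax(seq_len(n) - 400L, 0) * 1e-12 / k # force ramp from sample 401
  fc <- force_curve(z, ramp, k)
  ns <- estimate_noise(fc)
  cp <- find_contact_point(fc, ns)
  expect_identical(cp$index, 401L)
  expect_identical(cp$z, z[401])

  # all-baseline curve: no contact
  expect_error(find_contact_point(make_flat_curve(),
                                  estimate_noise(make_flat_curve())),
               "no contact")

  # a 5-sample spike above threshold must be skipped in favor of the later
  # sustained contact; verified against a brute-force scan
  spiked <- ramp
  spiked[300:304] <- 5e-10 / k
  fc2 <- force_curve(z, spiked, k)
  ns2 <- estimate_noise(fc2)
  cp2 <- find_contact_point(fc2, ns2)
  expect_gt(cp2$index, 304L)
  force <- fc2$k * (fc2$deflection - (ns2$coef[1] + ns2$coef[2] * fc2$z))
  thr <- cp2$threshold
  brute <- NA_integer_
  for (i in seq_len(n)) {
    if (force[i] >= thr && all(force[i:min(n, i + 5L)] >= thr)) {
      brute <- i
      break
    }
  }
  expect_identical(cp2$index, brute)
})

test_that("flat-punch force law is linear with the printed coefficient", {
  geom <- indenter_geometry(a = 1e-6, v = 0.5)
  expect_identical(hertz_force(623, geom, 0), 0)
  expect_equal(hertz_force(623, geom, 250e-9), 4.15333e-10, tolerance = 1e-5)
  d <- c(50, 150, 250) * 1e-9
  expect_equal(hertz_force(1246, geom, d), 2 * hertz_force(623, geom, d))
  expect_error(hertz_force(623, geom, -1e-9), "must be >= 0")
})

test_that("single-candidate fits are exact at truth and biased off-truth", {
  p <- curve_sim_params(E_true = 1000, sigma_F = 0)
  fc <- generate_force_curve(p)
  geom <- indenter_geometry(a = p$a, v = p$v)
  ns <- estimate_noise(fc)

  at_truth <- fit_window_at_candidate(fc, p$z_c_true, geom, ns)
  expect_true(at_truth$feasible)
  expect_equal(at_truth$E, 1000, tolerance = 1e-6)
  expect_identical(at_truth$n_points, sum(fc$z > p$z_c_true))

  # candidate displaced +50 nm (late): indentation underestimated, E biased
  # high; sign checked against the brute-force oracle refit. Noise makes the
  # displaced candidate feasible under the 3-sigma stopping rule.
  pn <- curve_sim_params(E_true = 1000, sigma_F = 3.5e-11, seed = 14L)
  fcl <- generate_force_curve(pn)
  nsl <- estimate_noise(fcl)
  late <- fit_window_at_candidate(fcl, pn$z_c_true + 50e-9, geom, nsl)
  expect_true(late$feasible)
  expect_gt(late$E, 1000)
  # independent brute-force refit at the same displaced candidate
  defl0 <- fcl$deflection - (nsl$coef[1] + nsl$coef[2] * fcl$z)
  post <- which(fcl$z > pn$z_c_true + 50e-9)
  d <- pmax((fcl$z[post] - (pn$z_c_true + 50e-9)) - defl0[post], 0)
  refit <- stats::lm.fit(matrix(d, ncol = 1), fcl$k * defl0[post])
  E_refit <- unname(refit$coefficients[1]) * (1 - geom$v^2) / (2 * geom$a)
  expect_gt(E_refit, 1000)

  # with noise, any accepted window satisfies the stopping rule
  fcn <- generate_force_curve(curve_sim_params(E_true = 1000, sigma_F = 2e-11,
                                               seed = 3L))
  nsn <- estimate_noise(fcn)
  noisy <- fit_window_at_candidate(fcn, 1.2e-6, geom, nsn)
  expect_true(noisy$feasible)
  expect_lte(noisy$rmsd, 3 * nsn$sigma_F)

  # too few samples past the candidate: infeasible, not fatal
  edge <- fit_window_at_candidate(fc, max(fc$z) - 1e-9, geom, ns)
  expect_false(edge$feasible)
})

test_that("full fits are exact when the grid contains the true contact", {
  # 301 samples over 1.5 um puts the sample spacing at exactly 5 nm, so the
  # candidate grid around the detected contact provably contains the true
  # contact point; the noiseless fit there keeps every post-contact sample
  p <- curve_sim_params(E_true = 623, sigma_F = 0, n_samples = 301)
  fc <- generate_force_curve(p)
  fit <- fit_young_modulus(fc, indenter_geometry())
  expect_s3_class(fit, "hertz_fit")
  expect_equal(fit$E, 623, tolerance = 1e-6)
  expect_equal(fit$z_c, p$z_c_true, tolerance = 1e-12)
  expect_identical(fit$n_points, sum(fc$z > p$z_c_true))
  expect_equal(nrow(fit$candidate_grid), 21L)
  expect_true(all(c("z_c", "E", "n_points", "rmsd", "feasible") %in%
                    names(fit$candidate_grid)))
  expect_warning(fit_young_modulus(fc), "radius")
})

test_that("grid selection matches the brute-force oracle on random curves", {
  geom <- indenter_geometry()
  for (s in 1:8) {
    fc <- generate_force_curve(random_curve_params(600 + s))
    fit <- fit_young_modulus(fc, geom)
    orc <- oracle_fit(fc, geom)
    expect_identical(fit$n_points, orc$n_points)
    expect_identical(fit$z_c, orc$z_c)
    expect_equal(fit$E, orc$E, tolerance = 1e-9)
  }
})

test_that("the modulus estimator is linear in force and translation invariant", {
  geom <- indenter_geometry()
  p <- curve_sim_params(E_true = 900, sigma_F = 1.5e-11, seed = 21L)
  fc <- generate_force_curve(p)
  fit <- fit_young_modulus(fc, geom)

  c_scale <- 3.7 # forces scale by c when k does, deflection fixed
  scaled <- force_curve(fc$z, fc$deflection, fc$k * c_scale)
  fit_s <- fit_young_modulus(scaled, geom)
  expect_identical(fit_s$n_points, fit$n_points)
  expect_equal(fit_s$E / fit$E, c_scale, tolerance = 1e-12)

  p0 <- curve_sim_params(E_true = 900, sigma_F = 0, n_samples = 301)
  fc0 <- generate_force_curve(p0)
  fit0 <- fit_young_modulus(fc0, geom)
  shift <- 0.7e-6
  moved <- force_curve(fc0$z + shift, fc0$deflection, fc0$k)
  fit_m <- fit_young_modulus(moved, geom)
  expect_equal(fit_m$z_c - fit0$z_c, shift, tolerance = 1e-12)
  expect_equal(fit_m$E, fit0$E, tolerance = 1e-9)
})

test_that("cell height is the contact-point difference in nm", {
  # identical surfaces: zero height, zero spread over noiseless triplicates
  dish_p <- curve_sim_params(E_true = 1e6, z_c_true = 1.2e-6, sigma_F = 0)
  dish <- replicate(3, generate_force_curve(dish_p), simplify = FALSE)
  same <- compute_cell_height(dish, dish)
  expect_equal(same$height_nm, 0, tolerance = 1e-9)
  expect_equal(sd(same$cell_z_c_all), 0)

  # constructed pair: cell contact 1869 nm before the dish contact
  cell_p <- curve_sim_params(E_true = 623, z_c_true = 1.2e-6, sigma_F = 0)
  dish_far <- curve_sim_params(E_true = 1e6, z_c_true = 1.2e-6 + 1869e-9,
                               ramp_extent = 3.5e-6, n_samples = 600,
                               sigma_F = 0)
  cells <- replicate(3, generate_force_curve(cell_p), simplify = FALSE)
  dishes <- replicate(3, generate_force_curve(dish_far), simplify = FALSE)
  h <- compute_cell_height(cells, dishes)
  spacing_nm <- max(diff(dishes[[1]]$z)) * 1e9
  expect_lt(abs(h$height_nm - 1869), spacing_nm)
  expect_false(h$flagged)

  # swapped surfaces: negative height flagged and folded back
  expect_warning(sw <- compute_cell_height(dishes, cells), "negative height")
  expect_true(sw$flagged)
  expect_equal(sw$height_nm, h$height_nm, tolerance = 1e-9)
})

test_that("rigidity time courses are expressed as percent of the -5 min control", {
  expect_equal(rigidity_pct_change(623, 623), 100)
  expect_equal(rigidity_pct_change(623, 1315), 211.075, tolerance = 1e-4)
  expect_equal(rigidity_pct_change(623, 0), 0)
  expect_equal(rigidity_pct_change(500, c(250, 1000)), c(50, 200))
  expect_error(rigidity_pct_change(0, 100), "E_pre")
  expect_error(rigidity_pct_change(-5, 100), "E_pre")
})
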