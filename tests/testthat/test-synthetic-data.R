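# Generators: model exactness at zero noise, determinism, validation.

test_that("noiseless force curves lie exactly on the flat-punch model", {
  p <- curve_sim_params(E_true = 623, sigma_F = 0, baseline_slope = 0)
  fc <- generate_force_curve(p)
  geom <- indenter_geometry(a = p$a, v = p$v)

  pre <- fc$z < p$z_c_true
  expect_equal(fc$deflection[pre], rep(0, sum(pre)))

  post <- which(fc$z > p$z_c_true)
  d <- (fc$z[post] - p$z_c_true) - fc$deflection[post]
  expect_equal(fc$k * fc$deflection[post], hertz_force(p$E_true, geom, d),
               tolerance = 1e-9)
  # indentations reach the instrument-typical 200-300 nm range
  expect_gt(max(d), 200e-9)
  expect_lt(max(d), 320e-9)
})

test_that("force-curve generation is seed-deterministic and validated", {
  p <- curve_sim_params(sigma_F = 2e-11, seed = 42L)
  fc1 <- generate_force_curve(p)
  fc2 <- generate_force_curve(p)
  expect_identical(fc1$deflection, fc2$deflection)
  fc3 <- generate_force_curve(curve_sim_params(sigma_F = 2e-11, seed = 43L))
  expect_false(identical(fc1$deflection, fc3$deflection))

  expect_error(curve_sim_params(E_true = -5), "E_true")
  expect_error(curve_sim_params(E_true = NaN), "E_true")
  expect_error(curve_sim_params(v = 0.7), "v")
  expect_error(curve_sim_params(n_samples = 20), "n_samples")
  expect_error(curve_sim_params(z_c_true = 2e-6, ramp_extent = 1.5e-6),
               "inside the ramp")
})

test_that("zero-noise calcium experiments round-trip through calibration", {
  p <- calcium_sim_params(noise_sd = 0, seed = 1L)
  tr <- generate_calcium_experiment(p)
  truth <- attr(tr, "truth")
  ca <- calibrate_calcium(compute_ratio(tr), p$cal)
  expect_lt(max(abs(ca - truth$course_nM)), 1e-9)

  seg <- segment_phases(tr$t_s, p$sched)
  m <- extract_calcium_metrics(ca, tr$t_s, seg)
  expect_equal(m$basal, 68.2, tolerance = 1e-12)
  expect_equal(m$basal, truth$basal, tolerance = 1e-12)
  expect_equal(m$release, truth$release, tolerance = 1e-9)
  expect_equal(m$entry, truth$entry, tolerance = 1e-9)
})

test_that("calcium generator rejects a release peak below basal and is deterministic", {
  expect_error(calcium_sim_params(basal_nM = 100, release_peak_nM = 50),
               "release_peak")
  p <- calcium_sim_params(seed = 9L)
  expect_identical(generate_calcium_experiment(p)$F340,
                   generate_calcium_experiment(p)$F340)
})

test_that("micrograph ground truth equals the rendered blob signal", {
  blank <- generate_micrograph(image_sim_params(shape = c(32, 32),
                                                background_amplitude = 120))
  expect_identical(attr(blank, "truth")$blob_sum, 0)

  one <- image_sim_params(shape = c(64, 64), blob_centers = c(31, 31),
                          blob_amplitudes = 5000, blob_sigma = 3)
  img <- generate_micrograph(one)
  expect_identical(sum(img$pixels), attr(img, "truth")$blob_sum)

  p <- image_sim_params(shape = c(48, 48), blob_centers = c(20, 25),
                        blob_amplitudes = 900, noise_max = 30, seed = 5L)
  expect_identical(generate_micrograph(p)$pixels, generate_micrograph(p)$pixels)
  expect_error(image_sim_params(shape = c(32, 32), blob_centers = c(40, 10),
                                blob_amplitudes = 10),
               "inside the image")
})

test_that("Cq tables encode fold changes exactly at zero noise", {
  tab <- generate_qpcr_table(c(SM22a = 1), n_samples = 4, noise_sd = 0)
  nrq <- qpcr_relative_expression(tab)
  expect_equal(nrq$NRQ, rep(1, nrow(nrq)), tolerance = 1e-12)

  tab2 <- generate_qpcr_table(c(SM22a = 2), n_samples = 3, noise_sd = 0)
  cq <- tapply(tab2$Cq[tab2$gene == "SM22a"],
               tab2$condition[tab2$gene == "SM22a"], unique)
  expect_equal(unname(cq["control"] - cq["treated"]), 1) # log2 identity
  refs <- tab2[tab2$is_reference, ]
  expect_equal(length(unique(round(tapply(refs$Cq, refs$gene, sd), 12))), 1)

  expect_error(generate_qpcr_table(c(SM22a = 2), reference_genes = character(0)),
               "reference gene")
})
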