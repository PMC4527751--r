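# Micrograph quantification: background removal, noise regions, density.

test_that("background removal nulls flat images and keeps output non-negative", {
  flat <- quant_image(matrix(500, 64, 64))
  out <- remove_background(flat, 20)
  expect_true(all(out$pixels == 0))

  p <- image_sim_params(shape = c(96, 96), blob_centers = c(47, 47),
                        blob_amplitudes = 20000, blob_sigma = 2,
                        background_amplitude = 800, noise_max = 25, seed = 8L)
  img <- generate_micrograph(p)
  out2 <- remove_background(img, 30)
  expect_gte(min(out2$pixels), 0)

  expect_warning(big <- remove_background(flat, 1000), "global minimum")
  expect_true(all(big$pixels == 0))
})

test_that("narrow blobs survive background removal within 5% integrated signal", {
  p <- image_sim_params(shape = c(96, 96), blob_centers = c(47, 47),
                        blob_amplitudes = 20000, blob_sigma = 2,
                        background_amplitude = 800, noise_max = 0)
  img <- generate_micrograph(p)
  truth <- attr(img, "truth")$blob_sum
  cleaned <- remove_background(img, 30)
  dens <- integrated_density(cleaned, threshold_policy(40))
  expect_lt(abs(dens$density - truth) / truth, 0.05)
})

test_that("white-noise summaries describe the requested region", {
  px <- matrix(0, 40, 40)
  img <- quant_image(px)
  expect_identical(estimate_white_noise(img, c(0, 0, 10, 10))$max, 0)

  set.seed(3)
  px[11:20, 21:30] <- sample(0:40, 100, replace = TRUE)
  px[15, 25] <- 40 # pin the maximum
  img2 <- quant_image(px)
  nz <- estimate_white_noise(img2, c(20, 10, 10, 10)) # x=col 20, y=row 10
  expect_identical(nz$max, 40)
  expect_identical(nz$n, 100L)
  expect_identical(estimate_white_noise(img2, c(20, 10, 10, 10))$sd, nz$sd)

  expect_error(estimate_white_noise(img2, c(38, 0, 10, 2)), "outside")
  expect_error(estimate_white_noise(img2, c(0, 0, 0, 5)), "region")
})

test_that("integrated density is a strict-cutoff sum with exact additivity", {
  im <- quant_image(matrix(c(35, 40, 41, 100), 2, 2), channel = "eGFP")
  d <- integrated_density(im)
  expect_identical(d$density, 141)
  expect_identical(d$count, 2L)
  expect_identical(d$cutoff, 40)

  low <- quant_image(matrix(c(1, 5, 40, 40), 2, 2))
  expect_identical(integrated_density(low, threshold_policy(40))$density, 0)

  # additive over a tiling, exactly
  p <- image_sim_params(shape = c(64, 64), blob_centers = rbind(c(15, 20),
                                                                c(40, 50)),
                        blob_amplitudes = c(3000, 1500), noise_max = 35,
                        seed = 12L)
  img <- generate_micrograph(p)
  pol <- threshold_policy(40, "eGFP")
  whole <- integrated_density(img, pol)$density
  tiles <- c(integrated_density(quant_image(img$pixels[1:32, 1:64]), pol)$density,
             integrated_density(quant_image(img$pixels[33:64, 1:64]), pol)$density)
  expect_identical(sum(tiles), whole)

  # raising the cutoff never increases density
  cuts <- c(0, 20, 40, 100, 400)
  dens <- vapply(cuts, function(ct)
    integrated_density(img, threshold_policy(ct))$density, numeric(1))
  expect_true(all(diff(dens) <= 0))

  # channel defaults
  expect_identical(threshold_policy(channel = "eGFP")$grey_cutoff, 40)
  expect_identical(threshold_policy(channel = "TexasRed")$grey_cutoff, 100)
  expect_error(threshold_policy(channel = "other"), "cutoff")
})

test_that("16-bit TIFF round trip preserves grey values", {
  p <- image_sim_params(shape = c(32, 32), blob_centers = c(15, 15),
                        blob_amplitudes = 40000, noise_max = 100, seed = 2L)
  img <- generate_micrograph(p)
  path <- tempfile(fileext = ".tif")
  write_quant_image(img, path)
  back <- read_quant_image(path, bit_depth = 16)
  expect_equal(back$pixels, img$pixels)
  unlink(path)
})
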