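#' Simulation parameters for synthetic micrographs
#'
#' A synthetic micrograph is a constant smooth background plus isotropic
#' Gaussian blobs (cell-like bright objects) plus bounded white noise drawn
#' uniformly on `[0, noise_max]` -- uniform rather than Gaussian so that the
#' noise has a well-defined *maximum* grey value, matching how fixed
#' white-noise cutoffs are used downstream.
#'
#' @param shape image size as `c(rows, cols)`.
#' @param blob_centers matrix with one `c(row, col)` 0-based center per row,
#'   or `NULL` for a blob-free image.
#' @param blob_amplitudes peak grey value of each blob.
#' @param blob_sigma Gaussian width of the blobs, pixels.
#' @param background_amplitude constant background grey value.
#' @param noise_max upper bound of the uniform white noise, grey values.
#' @param bit_depth 8 or 16.
#' @param seed integer RNG seed or `NULL`.
#' @return A list of class `image_sim_params`.
#' @export
image_sim_params <- function(shape = c(128L, 128L), blob_centers = NULL,
                             blob_amplitudes = NULL, blob_sigma = 3,
                             background_amplitude = 0, noise_max = 0,
                             bit_depth = 16L, seed = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) {
    stop("'shape' must be c(rows, cols)", call. = FALSE)
  }
  if (!is.null(blob_centers)) {
    blob_centers <- rbind(blob_centers)
    if (ncol(blob_centers) != 2L) {
      stop("'blob_centers' must have two columns (row, col)", call. = FALSE)
    }
    if (any(blob_centers < 0) || any(blob_centers[, 1] >= shape[1]) ||
        any(blob_centers[, 2] >= shape[2])) {
      stop("blob centers must lie inside the image", call. = FALSE)
    }
    if (is.null(blob_amplitudes) ||
        length(blob_amplitudes) != nrow(blob_centers)) {
      stop("need one amplitude per blob", call. = FALSE)
    }
    .check_finite(blob_amplitudes, "blob_amplitudes")
  }
  .check_scalar(blob_sigma, "blob_sigma", lower = 0, strict_lower = TRUE)
  .check_scalar(background_amplitude, "background_amplitude", lower = 0)
  .check_scalar(noise_max, "noise_max", lower = 0)
  maxval <- 2^as.integer(bit_depth) - 1
  if (background_amplitude > maxval || noise_max > maxval ||
      (!is.null(blob_amplitudes) && any(blob_amplitudes > maxval))) {
    stop("grey values must fit the bit depth", call. = FALSE)
  }
  structure(list(shape = shape, blob_centers = blob_centers,
                 blob_amplitudes = blob_amplitudes, blob_sigma = blob_sigma,
                 background_amplitude = background_amplitude,
                 noise_max = noise_max, bit_depth = as.integer(bit_depth),
                 seed = seed),
            class = "image_sim_params")
}

#' Generate a synthetic micrograph with known integrated blob signal
#'
#' The ground truth stored in the `truth` attribute is the integrated grey
#' value of the quantized blob component alone (no background, no noise),
#' i.e. exactly the signal an ideal background-removal plus integration
#' pipeline should report.
#'
#' @param p an [image_sim_params()].
#' @return A [quant_image()] with a `truth` attribute
#'   (`blob_sum`, `blob_raster`).
#' @export
generate_micrograph <- function(p) {
  stopifnot(inherits(p, "image_sim_params"))
  if (!is.null(p$seed)) set.seed(p$seed)
  rows <- p$shape[1]; cols <- p$shape[2]
  blob <- matrix(0, rows, cols)
  if (!is.null(p$blob_centers)) {
    rr <- matrix(0:(rows - 1), rows, cols)
    cc <- matrix(0:(cols - 1), rows, cols, byrow = TRUE)
    for (i in seq_len(nrow(p$blob_centers))) {
      r2 <- (rr - p$blob_centers[i, 1])^2 + (cc - p$blob_centers[i, 2])^2
      blob <- blob + p$blob_amplitudes[i] * exp(-r2 / (2 * p$blob_sigma^2))
    }
  }
  blob <- round(blob)
  noise <- if (p$noise_max > 0) {
    matrix(round(runif(rows * cols, 0, p$noise_max)), rows, cols)
  } else 0
  maxval <- 2^p$bit_depth - 1
  px <- pmin(blob + p$background_amplitude + noise, maxval)
  img <- quant_image(px, bit_depth = p$bit_depth, channel = "other")
  attr(img, "truth") <- list(blob_sum = sum(blob), blob_raster = blob)
  img
}
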