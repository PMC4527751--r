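#' Greyscale quantification image
#'
#' A plain greyscale raster (row-major matrix, origin top-left, 0-based
#' pixel coordinates in all region arguments) with its bit depth and an
#' acquisition-channel tag used to pick the default white-noise cutoff.
#'
#' @param pixels numeric matrix of grey values.
#' @param bit_depth 8 or 16.
#' @param channel one of `"eGFP"`, `"TexasRed"`, `"other"`.
#' @return An object of class `quant_image`.
#' @export
quant_image <- function(pixels, bit_depth = 16L, channel = "other") {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop("'pixels' must be a non-empty matrix", call. = FALSE)
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16",
                                       call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 2^bit_depth - 1) {
    stop("grey values outside the bit-depth range", call. = FALSE)
  }
  channel <- match.arg(channel, c("eGFP", "TexasRed", "other"))
  structure(list(pixels = pixels, bit_depth = bit_depth, channel = channel),
            class = "quant_image")
}

#' @export
print.quant_image <- function(x, ...) {
  cat(sprintf("<quant_image> %dx%d px, %d-bit, channel %s, grey %g..%g\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$channel,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Threshold policy for positive-fluorescence pixels
#'
#' Pixels are positive when strictly above the cutoff, so that white noise
#' whose *maximum* grey value equals the cutoff is removed entirely. The
#' channel defaults are 40 for eGFP and 100 for Texas Red.
#'
#' @param grey_cutoff grey-value cutoff; if `NULL`, taken from the channel.
#' @param channel channel tag used for the default cutoff.
#' @return A list of class `threshold_policy`.
#' @export
threshold_policy <- function(grey_cutoff = NULL, channel = "other") {
  channel <- match.arg(channel, c("eGFP", "TexasRed", "other"))
  if (is.null(grey_cutoff)) {
    grey_cutoff <- switch(channel, eGFP = 40, TexasRed = 100,
                          stop("no default cutoff for channel 'other'; ",
                               "supply 'grey_cutoff'", call. = FALSE))
  }
  .check_scalar(grey_cutoff, "grey_cutoff", lower = 0)
  structure(list(grey_cutoff = grey_cutoff, channel = channel),
            class = "threshold_policy")
}

#' Rolling-ball style background removal
#'
#' Estimates the smooth background as the greyscale morphological opening of
#' the image with a disc structuring element of the given radius (the
#' flat-disc approximation of the classic rolling-ball algorithm; for
#' backgrounds varying slowly relative to the radius the two agree to within
#' the local background curvature) and subtracts it. The output is
#' non-negative by construction and a flat image maps to zero. If the radius
#' exceeds both image dimensions nothing can roll, so the background
#' degenerates to the global minimum (with a warning).
#'
#' @param img a [quant_image()].
#' @param radius_px structuring-element radius in pixels (>= 1).
#' @return A background-subtracted [quant_image()].
#' @export
remove_background <- function(img, radius_px = 1000) {
  stopifnot(inherits(img, "quant_image"))
  .check_scalar(radius_px, "radius_px", lower = 1)
  px <- img$pixels
  if (radius_px >= nrow(px) && radius_px >= ncol(px)) {
    warning("radius exceeds both image dimensions; ",
            "subtracting the global minimum", call. = FALSE)
    bg <- min(px)
  } else {
    # EBImage grayscale morphology clamps to [0, 1]; rescale around it
    scale <- max(px, 1)
    kern <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
    bg <- EBImage::opening(px / scale, kern) * scale
  }
  out <- pmax(px - bg, 0)
  quant_image(out, bit_depth = img$bit_depth, channel = img$channel)
}

#' White-noise summary of a fluorescence-free region
#'
#' @param img a [quant_image()].
#' @param region region as `c(x, y, w, h)` in 0-based pixel coordinates
#'   (`x` = column, `y` = row, origin top-left).
#' @return A list with `max`, `sd` and `n` of the grey values in the region.
#' @export
estimate_white_noise <- function(img, region) {
  stopifnot(inherits(img, "quant_image"))
  .check_finite(region, "region")
  if (length(region) != 4L) stop("'region' must be c(x, y, w, h)", call. = FALSE)
  x <- region[1]; y <- region[2]; w <- region[3]; h <- region[4]
  if (w < 1 || h < 1 || x < 0 || y < 0 ||
      x + w > ncol(img$pixels) || y + h > nrow(img$pixels)) {
    stop("region overlaps no pixels or extends outside the image",
         call. = FALSE)
  }
  vals <- img$pixels[(y + 1):(y + h), (x + 1):(x + w)]
  list(max = max(vals), sd = if (length(vals) > 1L) stats::sd(vals) else 0,
       n = length(vals))
}

#' Integrated density of positive-fluorescence pixels
#'
#' Sums the grey values of pixels strictly greater than the cutoff of the
#' policy (to be applied to a background-removed image). Exact integer
#' arithmetic at 8/16-bit depth makes the density additive over any
#' partition of the image.
#'
#' @param img a [quant_image()].
#' @param policy a [threshold_policy()]; defaults to the image channel's
#'   standard cutoff.
#' @return A list with `density` (grey-value x pixels), `count` (number of
#'   positive pixels) and `cutoff`.
#' @examples
#' im <- quant_image(matrix(c(35, 40, 41, 100), 2), channel = "eGFP")
#' integrated_density(im) # density 141, count 2
#' @export
integrated_density <- function(img, policy = NULL) {
  stopifnot(inherits(img, "quant_image"))
  if (is.null(policy)) policy <- threshold_policy(channel = img$channel)
  stopifnot(inherits(policy, "threshold_policy"))
  pos <- img$pixels > policy$grey_cutoff
  list(density = sum(img$pixels[pos]), count = sum(pos),
       cutoff = policy$grey_cutoff)
}

#' Read a greyscale image as a quantification image
#'
#' TIFF and PNG are supported. Multi-channel rasters are reduced by
#' extracting a single named channel plane (never a luminance mix, which
#' would alter grey statistics).
#'
#' @param path image file (`.tif`, `.tiff` or `.png`).
#' @param bit_depth bit depth the integer grey values are scaled to.
#' @param channel channel tag for [quant_image()].
#' @param plane which plane to extract when the file has several (1 = first).
#' @return A [quant_image()].
#' @export
read_quant_image <- function(path, bit_depth = 16L, channel = "other",
                             plane = 1L) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(raw)) == 3L) raw <- raw[, , plane]
  quant_image(round(raw * (2^bit_depth - 1)), bit_depth = bit_depth,
              channel = channel)
}

#' Write a quantification image to 16-bit (or 8-bit) TIFF
#'
#' @param img a [quant_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_quant_image <- function(img, path) {
  stopifnot(inherits(img, "quant_image"))
  tiff::writeTIFF(img$pixels / (2^img$bit_depth - 1), path,
                  bits.per.sample = img$bit_depth)
  invisible(path)
}
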