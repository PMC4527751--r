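#' Cell height from paired substrate and cell contact points
#'
#' The tip, approaching along increasing `z`, touches the apical cell
#' surface before it would touch the dish, so the cell contact point sits at
#' a smaller piezo position than the substrate contact point of nearby bare
#' dish curves. Height is the difference of the mean contact positions,
#' `mean(dish z_c) - mean(cell z_c)`, reported in nanometres. A negative
#' value after this orientation convention indicates inconsistent inputs; it
#' is returned as the absolute value with a warning and `flagged = TRUE`.
#'
#' @param cell_curves list of [force_curve()]s on the cell.
#' @param dish_curves list of [force_curve()]s on the bare dish.
#' @param baseline_fraction,threshold_factor,guard contact-detection
#'   settings, see [find_contact_point()].
#' @return A list of class `cell_height` with `height_nm`, `cell_z_c` and
#'   `dish_z_c` (means, m), the per-curve contact positions and `flagged`.
#' @export
compute_cell_height <- function(cell_curves, dish_curves,
                                baseline_fraction = 0.3,
                                threshold_factor = 3, guard = 5L) {
  contact_z <- function(curves, what) {
    if (length(curves) < 1L) stop("need at least one ", what, " curve",
                                  call. = FALSE)
    vapply(curves, function(fc) {
      noise <- estimate_noise(fc, baseline_fraction)
      find_contact_point(fc, noise, threshold_factor, guard)$z
    }, numeric(1))
  }
  zc_cell <- contact_z(cell_curves, "cell")
  zc_dish <- contact_z(dish_curves, "dish")
  height_nm <- (mean(zc_dish) - mean(zc_cell)) * 1e9
  flagged <- FALSE
  if (height_nm < 0) {
    warning("negative height after orientation normalization; ",
            "reporting absolute value", call. = FALSE)
    height_nm <- abs(height_nm)
    flagged <- TRUE
  }
  structure(list(height_nm = height_nm,
                 cell_z_c = mean(zc_cell), dish_z_c = mean(zc_dish),
                 cell_z_c_all = zc_cell, dish_z_c_all = zc_dish,
                 flagged = flagged),
            class = "cell_height")
}

#' @export
print.cell_height <- function(x, ...) {
  cat(sprintf("<cell_height> %.1f nm (cell z_c %.4g m, dish z_c %.4g m)%s\n",
              x$height_nm, x$cell_z_c, x$dish_z_c,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Rigidity time course as percent of the pre-stimulation control
#'
#' Expresses post-stimulation Young's moduli relative to the modulus
#' measured before stimulation (the -5 min control), on the ratio
#' convention: `100 * E_post / E_pre`. An unchanged cell reads 100%.
#'
#' @param E_pre pre-stimulation modulus, Pa (> 0).
#' @param E_post vector of post-stimulation moduli, Pa (one per timepoint,
#'   e.g. +5 and +10 min).
#' @return Named numeric vector of percent changes (names taken from
#'   `E_post` if present).
#' @examples
#' rigidity_pct_change(623, c(`+5min` = 1315)) # ~211% as in control cells
#' @export
rigidity_pct_change <- function(E_pre, E_post) {
  .check_scalar(E_pre, "E_pre")
  .check_finite(E_post, "E_post")
  if (E_pre <= 0) stop("'E_pre' must be > 0", call. = FALSE)
  if (any(E_post < 0)) stop("'E_post' must be >= 0", call. = FALSE)
  100 * E_post / E_pre
}
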