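#' Force-curve container
#'
#' A force curve is the approach segment of an AFM indentation experiment:
#' piezo position `z` (metres, strictly increasing toward the sample) paired
#' with measured cantilever deflection (metres), plus the calibrated spring
#' constant `k` (N/m). Forces are always derived downstream as
#' `k * (deflection - baseline)`, after the baseline line has been fitted on
#' the non-contact region; the raw deflection is stored untouched.
#'
#' @param z numeric vector of piezo positions in metres, strictly monotone
#'   increasing along the approach direction (toward the sample).
#' @param deflection numeric vector of cantilever deflections in metres, same
#'   length as `z`.
#' @param k calibrated cantilever spring constant in N/m.
#' @return An object of class `force_curve`: a list with elements `z`,
#'   `deflection` and `k`.
#' @examples
#' p <- curve_sim_params(E_true = 623, sigma_F = 0, seed = 1)
#' fc <- generate_force_curve(p)
#' fc
#' @export
force_curve <- function(z, deflection, k) {
  .check_finite(z, "z")
  .check_finite(deflection, "deflection")
  .check_scalar(k, "k", lower = 0, strict_lower = TRUE)
  if (length(z) != length(deflection)) {
    stop("'z' and 'deflection' must have equal length", call. = FALSE)
  }
  if (length(z) < 50L) {
    stop("a force curve needs at least 50 samples", call. = FALSE)
  }
  dz <- diff(z)
  if (any(dz <= 0)) {
    if (all(dz < 0)) {
      # instrument exported the opposite approach convention; re-orient
      z <- rev(z)
      deflection <- rev(deflection)
    } else {
      stop("'z' must be strictly monotone", call. = FALSE)
    }
  }
  structure(list(z = as.numeric(z), deflection = as.numeric(deflection),
                 k = as.numeric(k)),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d samples, z %.3g..%.3g m, k = %g N/m\n",
              length(x$z), min(x$z), max(x$z), x$k))
  tr <- attr(x, "truth")
  if (!is.null(tr)) {
    cat(sprintf("  synthetic truth: E = %g Pa, z_c = %g m\n", tr$E, tr$z_c))
  }
  invisible(x)
}

#' Read / write force curves as two-column TSV with a JSON sidecar
#'
#' The on-disk dialect is a headered TSV (`z_m`, `deflection_m`) plus an
#' optional `<file>.json` sidecar holding instrument metadata (`k`, indenter
#' radius `a`, Poisson ratio `v`, seed and simulation truth when the curve is
#' synthetic). `read_force_curve()` takes `k` from the sidecar unless
#' supplied explicitly.
#'
#' @param curve a [force_curve()].
#' @param path file path for the TSV; the sidecar is written next to it.
#' @param meta named list merged into the sidecar (e.g. `a`, `v`).
#' @return `write_force_curve()` returns `path` invisibly;
#'   `read_force_curve()` returns a [force_curve()].
#' @export
write_force_curve <- function(curve, path, meta = list()) {
  stopifnot(inherits(curve, "force_curve"))
  df <- data.frame(z_m = curve$z, deflection_m = curve$deflection)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- c(list(k = curve$k), meta)
  tr <- attr(curve, "truth")
  if (!is.null(tr)) side$truth <- tr
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_force_curve
#' @param k spring constant in N/m; overrides the sidecar value.
#' @export
read_force_curve <- function(path, k = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("z_m", "deflection_m") %in% names(df))) {
    stop("expected columns 'z_m' and 'deflection_m' in ", path, call. = FALSE)
  }
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  if (is.null(k)) k <- side$k
  if (is.null(k)) stop("spring constant 'k' not supplied and no sidecar found",
                       call. = FALSE)
  fc <- force_curve(df$z_m, df$deflection_m, as.numeric(k))
  if (!is.null(side$truth)) {
    attr(fc, "truth") <- lapply(side$truth, as.numeric)
  }
  fc
}
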