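#' Mean and standard error per condition
#'
#' @param values numeric vector.
#' @param condition condition label per value.
#' @return A data frame with `condition`, `n`, `mean`, `sem` (SD / sqrt(n);
#'   0 for a single value), ordered by condition label.
#' @examples
#' summarize_groups(c(1, 2, 3), rep("ctl", 3)) # mean 2, sem 0.5774
#' @export
summarize_groups <- function(values, condition) {
  .check_finite(values, "values")
  condition <- as.character(condition)
  if (length(values) != length(condition)) {
    stop("'values' and 'condition' must have equal length", call. = FALSE)
  }
  labs <- sort(unique(condition))
  out <- do.call(rbind, lapply(labs, function(l) {
    v <- values[condition == l]
    data.frame(condition = l, n = length(v), mean = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0)
  }))
  rownames(out) <- NULL
  out
}

# Fill defaults into a pipeline config, recording every defaulted physical
# constant for the manifest.
#' @noRd
.config_defaults <- function(config) {
  defaulted <- character(0)
  take <- function(x, default, label) {
    if (is.null(x)) {
      defaulted <<- c(defaulted, sprintf("%s = %s", label,
                                         format(default, digits = 6)))
      default
    } else x
  }
  afm <- config$afm
  if (is.null(afm$radius_um)) {
    stop("config error: afm.radius_um (cylindrical tip radius, um) is ",
         "required; set it from the tip data sheet", call. = FALSE)
  }
  afm$poisson <- take(afm$poisson, 0.5, "afm.poisson")
  afm$grid_nm <- take(afm$grid_nm, 50, "afm.grid_nm")
  afm$step_nm <- take(afm$step_nm, 5, "afm.step_nm")
  afm$min_window <- take(afm$min_window, 10, "afm.min_window")
  cv <- config$curve
  cv$k_N_per_m <- take(cv$k_N_per_m, 0.1, "curve.k_N_per_m")
  cv$sigma_F_N <- take(cv$sigma_F_N, 1e-11, "curve.sigma_F_N")
  cv$ramp_extent_m <- take(cv$ramp_extent_m, 1.5e-6, "curve.ramp_extent_m")
  cv$z_c_m <- take(cv$z_c_m, 1.2e-6, "curve.z_c_m")
  cv$n_samples <- take(cv$n_samples, 600, "curve.n_samples")
  config$afm <- afm
  config$curve <- cv
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  attr(config, "defaulted") <- defaulted
  config
}

#' Run the simulate / fit / summarize pipeline from a config
#'
#' Reads a YAML config (or takes an equivalent list), simulates force curves
#' for each configured condition, fits every curve with
#' [fit_young_modulus()], summarizes the recovered moduli per condition and
#' writes `fits.csv`, `summary.csv` and a `manifest.json` recording package
#' and R versions, the seed, all parameters and every defaulted constant.
#' Identical config and seed give byte-identical outputs.
#'
#' Config schema (YAML):
#' \preformatted{
#' seed: 1
#' outdir: results
#' afm:
#'   radius_um: 1.0      # required
#'   poisson: 0.5
#' conditions:
#'   - label: PBS
#'     E_true_Pa: 623
#'     n_curves: 10
#' curve:
#'   k_N_per_m: 0.1
#'   sigma_F_N: 1.0e-11
#' }
#'
#' @param config path to a YAML config file, or the config as a list.
#' @param seed optional seed overriding the config seed.
#' @return Invisibly, a list with `fits` and `summary` data frames and the
#'   `manifest` list; side effect: CSV/JSON files under `outdir`.
#' @export
run_pipeline <- function(config, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a YAML path or a list",
                             call. = FALSE)
  if (is.null(config$conditions) || length(config$conditions) == 0L) {
    stop("config error: at least one entry under 'conditions' is required",
         call. = FALSE)
  }
  config <- .config_defaults(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  outdir <- if (is.null(config$outdir)) "." else config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  geom <- indenter_geometry(a = config$afm$radius_um * 1e-6,
                            v = config$afm$poisson)
  warnings_log <- character(0)
  fits <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[[ci]]
    if (is.null(cond$E_true_Pa) || is.null(cond$label)) {
      stop("config error: each condition needs 'label' and 'E_true_Pa'",
           call. = FALSE)
    }
    n_curves <- if (is.null(cond$n_curves)) 10L else as.integer(cond$n_curves)
    for (j in seq_len(n_curves)) {
      p <- curve_sim_params(E_true = cond$E_true_Pa,
                            a = geom$a, v = geom$v,
                            k = config$curve$k_N_per_m,
                            z_c_true = config$curve$z_c_m,
                            ramp_extent = config$curve$ramp_extent_m,
                            n_samples = config$curve$n_samples,
                            sigma_F = config$curve$sigma_F_N,
                            seed = config$seed + 1000L * ci + j)
      fc <- generate_force_curve(p)
      fit <- withCallingHandlers(
        fit_young_modulus(fc, geom,
                          min_window = config$afm$min_window,
                          grid_halfwidth = config$afm$grid_nm * 1e-9,
                          grid_step = config$afm$step_nm * 1e-9),
        warning = function(w) {
          warnings_log <<- c(warnings_log, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      fits[[length(fits) + 1L]] <- data.frame(
        condition = cond$label, curve = sprintf("%s_%03d", cond$label, j),
        E_Pa = fit$E, z_c_m = fit$z_c, n_points = fit$n_points,
        rmsd_N = fit$rmsd)
    }
  }
  fits <- do.call(rbind, fits)
  summary_df <- summarize_groups(fits$E_Pa, fits$condition)
  names(summary_df) <- c("condition", "n", "mean_E_Pa", "sem_E_Pa")

  utils::write.csv(fits, file.path(outdir, "fits.csv"), row.names = FALSE)
  utils::write.csv(summary_df, file.path(outdir, "summary.csv"),
                   row.names = FALSE)
  manifest <- list(package = "vsmcq",
                   version = as.character(utils::packageVersion("vsmcq")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = config$seed,
                   parameters = config[c("afm", "curve", "conditions")],
                   defaulted_constants = as.list(attr(config, "defaulted")),
                   warnings = as.list(unique(warnings_log)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fits = fits, summary = summary_df, manifest = manifest))
}
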