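#' Simulation parameters for a synthetic calcium experiment
#'
#' Defaults emulate the control (vehicle-treated) condition of the
#' vasopressin protocol: basal free calcium 68.2 nM, a store-release
#' transient of ~60.6 nM amplitude, and a re-addition plateau ~12.6 nM above
#' the pre-re-addition level, over the standard 60/60/180/150 s phase
#' schedule. The transient shape is a linear rise over `rise_s` seconds
#' followed by a single-exponential decay back toward basal with time
#' constant `tau_decay` (the decay brings the signal back to baseline well
#' within the stimulation window, as the protocol requires before calcium
#' is re-added).
#'
#' @param basal_nM basal free calcium, nM.
#' @param release_peak_nM peak concentration during stimulation, nM; must
#'   exceed `basal_nM`.
#' @param entry_plateau_nM plateau concentration after calcium re-addition,
#'   nM.
#' @param tau_decay decay time constant of the release transient, s.
#' @param sched a [phase_schedule()].
#' @param cal a [calibration_params()] used to invert intensities.
#' @param noise_sd Gaussian noise SD added to the ratio (ratio units).
#' @param dt sampling interval, s.
#' @param rise_s linear rise time of the transient, s.
#' @param F380_0 constant 380 nm intensity used for the synthetic channels.
#' @param seed integer RNG seed or `NULL`.
#' @return A list of class `calcium_sim_params`.
#' @export
calcium_sim_params <- function(basal_nM = 68.2, release_peak_nM = 128.8,
                               entry_plateau_nM = 80.8, tau_decay = 30,
                               sched = phase_schedule(),
                               cal = calibration_params(),
                               noise_sd = 0.002, dt = 1, rise_s = 5,
                               F380_0 = 1000, seed = NULL) {
  .check_scalar(basal_nM, "basal_nM", lower = 0)
  .check_scalar(release_peak_nM, "release_peak_nM", lower = 0)
  .check_scalar(entry_plateau_nM, "entry_plateau_nM", lower = 0)
  .check_scalar(tau_decay, "tau_decay", lower = 0, strict_lower = TRUE)
  .check_scalar(noise_sd, "noise_sd", lower = 0)
  .check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  .check_scalar(rise_s, "rise_s", lower = 0, strict_lower = TRUE)
  .check_scalar(F380_0, "F380_0", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(sched, "phase_schedule"), inherits(cal, "calibration_params"))
  if (release_peak_nM < basal_nM) {
    stop("'release_peak_nM' must not be below 'basal_nM'", call. = FALSE)
  }
  structure(list(basal_nM = basal_nM, release_peak_nM = release_peak_nM,
                 entry_plateau_nM = entry_plateau_nM, tau_decay = tau_decay,
                 sched = sched, cal = cal, noise_sd = noise_sd, dt = dt,
                 rise_s = rise_s, F380_0 = F380_0, seed = seed),
            class = "calcium_sim_params")
}

# Piecewise concentration course, nM, at times t (seconds from trace start).
#' @noRd
.calcium_course <- function(p, t) {
  b <- cumsum(unclass(p$sched))
  ca <- rep(p$basal_nM, length(t))
  stim <- t >= b[2] & t < b[3]
  ts <- t[stim] - b[2]
  amp <- p$release_peak_nM - p$basal_nM
  ca[stim] <- ifelse(ts <= p$rise_s,
                     p$basal_nM + amp * ts / p$rise_s,
                     p$basal_nM + amp * exp(-(ts - p$rise_s) / p$tau_decay))
  ca[t >= b[3]] <- p$entry_plateau_nM
  ca
}

#' Generate a synthetic Fura-2 calcium experiment with known ground truth
#'
#' Builds the piecewise concentration course, inverts the calibration
#' equation to a ratio series (`R = (Rmin + x Rmax) / (1 + x)` with
#' `x = Ca / (Kd beta)`), adds Gaussian ratio noise, and emits paired
#' intensity channels `F340 = R * F380_0`, `F380 = F380_0`. At zero noise,
#' [compute_ratio()] followed by [calibrate_calcium()] reproduces the course
#' exactly.
#'
#' The `truth` attribute holds the noiseless course and the basal, release
#' and entry values obtained by applying [extract_calcium_metrics()]
#' arithmetic to that course, i.e. the exact targets for recovery tests.
#'
#' @param p a [calcium_sim_params()].
#' @return A data frame with columns `t_s`, `F340`, `F380`, carrying a
#'   `truth` attribute.
#' @export
generate_calcium_experiment <- function(p) {
  stopifnot(inherits(p, "calcium_sim_params"))
  if (!is.null(p$seed)) set.seed(p$seed)
  total <- sum(unclass(p$sched))
  t <- seq(0, total - p$dt, by = p$dt)
  ca <- .calcium_course(p, t)

  x <- ca / (p$cal$Kd * p$cal$beta)
  R <- (p$cal$Rmin + x * p$cal$Rmax) / (1 + x)
  if (p$noise_sd > 0) R <- R + rnorm(length(R), 0, p$noise_sd)

  trace <- data.frame(t_s = t, F340 = R * p$F380_0, F380 = p$F380_0)
  seg <- segment_phases(t, p$sched)
  attr(trace, "truth") <- c(extract_calcium_metrics(ca, t, seg),
                            list(course_nM = ca))
  trace
}
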