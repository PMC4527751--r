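#' Fura-2 calibration constants
#'
#' Parameters of the ratiometric saturation equation
#' `[Ca] = Kd * beta * (R - Rmin) / (Rmax - R)`, where `R` is the
#' background-corrected 340/380 nm excitation ratio, `Rmin`/`Rmax` are the
#' limiting ratios at zero and saturating calcium, and `beta` is the ratio
#' of the 380 nm fluorescence at zero vs saturating calcium. The defaults
#' (`Kd` 224 nM at room temperature, `Rmin` 0.8, `Rmax` 8, `beta` 10) are
#' literature-typical values; a real analysis should supply the constants
#' determined on the instrument in a saturating-calcium calibration.
#'
#' @param Kd Fura-2 dissociation constant, nM.
#' @param Rmin,Rmax limiting ratios (dimensionless), `Rmin < Rmax`.
#' @param beta F380(zero Ca)/F380(saturating Ca), dimensionless.
#' @return A list of class `calibration_params`.
#' @export
calibration_params <- function(Kd = 224, Rmin = 0.8, Rmax = 8, beta = 10) {
  .check_scalar(Kd, "Kd", lower = 0, strict_lower = TRUE)
  .check_scalar(Rmin, "Rmin")
  .check_scalar(Rmax, "Rmax")
  .check_scalar(beta, "beta", lower = 0, strict_lower = TRUE)
  if (Rmin >= Rmax) stop("'Rmin' must be < 'Rmax'", call. = FALSE)
  structure(list(Kd = Kd, Rmin = Rmin, Rmax = Rmax, beta = beta),
            class = "calibration_params")
}

#' 340/380 excitation ratio of a paired fluorescence trace
#'
#' @param trace data frame with columns `t_s`, `F340`, `F380`
#'   (background-corrected intensities).
#' @return Numeric ratio series `F340 / F380`; samples with `F380 <= 0` are
#'   masked as `NA` with a warning.
#' @export
compute_ratio <- function(trace) {
  stopifnot(is.data.frame(trace), all(c("F340", "F380") %in% names(trace)))
  R <- trace$F340 / trace$F380
  bad <- !is.finite(trace$F380) | trace$F380 <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with non-positive F380 masked", call. = FALSE)
    R[bad] <- NA_real_
  }
  R
}

#' Calibrate a ratio series to free calcium concentration
#'
#' Applies `[Ca] = Kd * beta * (R - Rmin) / (Rmax - R)` in nM. Ratios at or
#' above `Rmax` (saturated indicator) and below `Rmin` are masked as `NA`
#' rather than clipped, because clipping silently biases window means.
#'
#' @param R numeric ratio series (may contain `NA`).
#' @param cal a [calibration_params()].
#' @return Calcium concentrations, nM.
#' @examples
#' calibrate_calcium(4.4, calibration_params(Kd = 224, Rmin = 0.8,
#'                                           Rmax = 8, beta = 10)) # 2240 nM
#' @export
calibrate_calcium <- function(R, cal = calibration_params()) {
  stopifnot(inherits(cal, "calibration_params"))
  out_of_range <- !is.na(R) & (R >= cal$Rmax | R < cal$Rmin)
  if (any(out_of_range)) {
    warning(sum(out_of_range), " ratio sample(s) outside [Rmin, Rmax) masked",
            call. = FALSE)
  }
  ca <- cal$Kd * cal$beta * (R - cal$Rmin) / (cal$Rmax - R)
  ca[out_of_range] <- NA_real_
  ca
}

#' Phase schedule of the calcium protocol
#'
#' The four-phase protocol: stabilization in normal buffer, a calcium-free
#' baseline (extracellular calcium chelated), agonist stimulation reading
#' out store release, and calcium re-addition reading out entry. Default
#' durations 60, 60, 180 and 150 s.
#'
#' @param stabilization,ca_free_baseline,stimulation,reentry durations, s.
#' @return A named numeric vector of class `phase_schedule`.
#' @export
phase_schedule <- function(stabilization = 60, ca_free_baseline = 60,
                           stimulation = 180, reentry = 150) {
  sched <- c(stabilization = stabilization, ca_free_baseline = ca_free_baseline,
             stimulation = stimulation, reentry = reentry)
  .check_finite(sched, "phase durations")
  if (any(sched <= 0)) stop("all phase durations must be > 0", call. = FALSE)
  structure(sched, class = "phase_schedule")
}

#' Segment a trace into the four protocol phases
#'
#' Phase boundaries are the cumulative schedule times measured from the
#' first sample; phase `i` covers `[b_{i-1}, b_i)`. Stimulus onset is the
#' start of the third window.
#'
#' @param t sample times, s.
#' @param sched a [phase_schedule()].
#' @return A list with `phase` (integer label per sample, 1-4), `boundaries`
#'   (cumulative end times, s) and `windows` (list of index vectors).
#' @export
segment_phases <- function(t, sched = phase_schedule()) {
  stopifnot(inherits(sched, "phase_schedule"))
  .check_finite(t, "t")
  bounds <- cumsum(unclass(sched))
  t0 <- t - t[1]
  dt <- if (length(t) > 1L) stats::median(diff(t)) else 0
  if (max(t0) + dt < bounds[4]) {
    stop("trace shorter than the phase schedule", call. = FALSE)
  }
  phase <- findInterval(t0, c(0, bounds[-4]))
  phase[phase > 4L] <- 4L
  list(phase = as.integer(phase), boundaries = unname(bounds),
       windows = lapply(1:4, function(i) which(phase == i)))
}

#' Extract basal, release and entry metrics from a calibrated trace
#'
#' * `basal`: mean over the tail (last `basal_tail` s) of the calcium-free
#'   baseline window, avoiding the medium-switch artifact at its start.
#' * `release`: maximum during the stimulation window minus `basal`
#'   (store-release amplitude).
#' * `entry`: mean over the tail (last `entry_tail` s) of the re-addition
#'   window minus the mean over the last `pre_tail` s of the stimulation
#'   window (entry amplitude above the immediately preceding level).
#'
#' `release` and `entry` are differences and therefore invariant to
#' constant offsets of the whole trace; `basal` shifts with such offsets.
#'
#' @param ca calibrated calcium series, nM.
#' @param t sample times, s.
#' @param seg a [segment_phases()] result for `t`.
#' @param basal_tail,entry_tail,pre_tail window tails, s.
#' @return A list with `basal`, `release` and `entry`, nM.
#' @export
extract_calcium_metrics <- function(ca, t, seg, basal_tail = 20,
                                    entry_tail = 30, pre_tail = 20) {
  stopifnot(length(ca) == length(t))
  tail_idx <- function(win, tail_s) {
    if (length(win) == 0L) stop("empty phase window", call. = FALSE)
    win[t[win] > t[win[length(win)]] - tail_s]
  }
  basal <- mean(ca[tail_idx(seg$windows[[2]], basal_tail)], na.rm = TRUE)
  stim <- seg$windows[[3]]
  if (length(stim) == 0L || length(seg$windows[[4]]) == 0L) {
    stop("empty phase window", call. = FALSE)
  }
  release <- max(ca[stim], na.rm = TRUE) - basal
  pre <- mean(ca[tail_idx(stim, pre_tail)], na.rm = TRUE)
  plateau <- mean(ca[tail_idx(seg$windows[[4]], entry_tail)], na.rm = TRUE)
  list(basal = basal, release = release, entry = plateau - pre)
}

#' Read a paired fluorescence trace from CSV
#'
#' Expects columns `t_s`, `F340`, `F380` and optionally `roi_id`.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_ratio_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_s", "F340", "F380")
  if (!all(need %in% names(df))) {
    stop("expected columns ", paste(need, collapse = ", "), " in ", path,
         call. = FALSE)
  }
  df
}
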