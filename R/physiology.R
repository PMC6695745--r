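# Criterion measures from oxygen-consumption traces: resting and standing VO2,
# net VO2, MET, and the Froude-type dimensionless equivalent speed.

#' Convert speed from km/h to m/s
#' @param v_kmh speed in km/h.
#' @export
kmh_to_ms <- function(v_kmh) v_kmh / 3.6

#' Resting energy expenditure from a seated-rest VO2 trace
#'
#' The trace is linearly resampled to a regular 5-s grid, smoothed with a
#' centered 2-min moving average, and the minimum of the smoothed series over
#' all positions with a complete window is returned. The minimum-of-means rule
#' is robust against fidgeting and settling at the start of the rest period.
#'
#' @param time_s sample times in seconds, strictly increasing.
#' @param vo2 gross VO2 in mL/min, parallel to `time_s`.
#' @param window moving-average window in seconds (default 120).
#' @param grid resampling grid step in seconds (default 5).
#' @return resting VO2 in mL/min.
#' @export
compute_ree <- function(time_s, vo2, window = 120, grid = 5) {
  stopifnot(length(time_s) == length(vo2), all(diff(time_s) > 0))
  span <- time_s[length(time_s)] - time_s[1]
  if (span < window) stop("rest trace shorter than the moving-average window")
  tg <- seq(time_s[1], time_s[length(time_s)], by = grid)
  vg <- approx(time_s, vo2, xout = tg)$y
  k <- round(window / grid) + 1  # centered window spanning exactly `window` s
  if (k > length(vg)) stop("rest trace shorter than the moving-average window")
  cs <- cumsum(c(0, vg))
  means <- (cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]) / k
  min(means)
}

#' Metabolic equivalent of task
#'
#' `MET = VO2gross / VO2rest`, dimensionless. Seated rest is 1 MET by
#' construction.
#'
#' @param vo2_gross gross VO2 during activity, mL/min.
#' @param vo2_rest resting VO2, mL/min, positive.
#' @export
compute_met <- function(vo2_gross, vo2_rest) {
  if (any(vo2_rest <= 0)) stop("vo2_rest must be positive")
  vo2_gross / vo2_rest
}

#' Mass-specific net oxygen consumption
#'
#' `VO2net = (VO2gross - VO2stand) / weight` in mL/min/kg. Subtracting the
#' standing rather than the resting value isolates the energy requirement of
#' dynamic movement, which is what a body-worn accelerometer captures.
#' Sub-standing activities yield negative values; these are retained and
#' flagged via the `"sub_standing"` attribute, never clamped, so downstream
#' calibration code can decide exclusion explicitly.
#'
#' @param vo2_gross gross VO2, mL/min.
#' @param vo2_stand standing VO2, mL/min.
#' @param weight body weight in kg, positive.
#' @return VO2net in mL/min/kg with logical attribute `sub_standing`.
#' @export
compute_vo2net <- function(vo2_gross, vo2_stand, weight) {
  if (any(weight <= 0)) stop("weight must be positive")
  out <- (vo2_gross - vo2_stand) / weight
  attr(out, "sub_standing") <- out < 0
  out
}

#' Equivalent (dimensionless) speed
#'
#' `Speed_eq = V^2 / (g * h)` with `V` the absolute speed in m/s, `g = 9.81`
#' m/s^2 and `h` body height in m - a Froude-type number. Equal values mark
#' kinematically equivalent locomotion across body sizes: a shorter person
#' reaches a given `Speed_eq` at a lower absolute speed.
#'
#' @param v_ms absolute speed in m/s, non-negative.
#' @param height_m body height in m, positive.
#' @export
compute_speed_eq <- function(v_ms, height_m) {
  if (any(height_m <= 0)) stop("height must be positive")
  if (any(v_ms < 0)) stop("speed must be non-negative")
  v_ms^2 / (9.81 * height_m)
}

#' Criterion values for one subject's treadmill session
#'
#' Applies the steady-state window to a labelled VO2 trace: resting VO2 from
#' the 20-min rest via [compute_ree()], standing VO2 from the stand stage
#' window, then per locomotion stage gross VO2, MET, VO2net and equivalent
#' speed.
#'
#' @param vo2_trace data frame with columns `time_s`, `vo2_ml_min`, `stage`
#'   (`rest`, `stand`, `walk3`, `walk4`, `walk5`, `walk6`, `run8`, `run10`).
#' @param stage_starts named numeric vector of stage start times (s) for the
#'   non-rest stages.
#' @param height_m,weight_kg subject anthropometry.
#' @return data frame with one row per non-rest stage: `stage`, `speed_kmh`,
#'   `speed_eq`, `vo2_gross`, `vo2_net`, `met`, `sub_standing`, plus
#'   attributes `vo2_rest` and `vo2_stand` (mL/min).
#' @export
compute_criterion_values <- function(vo2_trace, stage_starts, height_m, weight_kg) {
  stopifnot(all(c("time_s", "vo2_ml_min", "stage") %in% names(vo2_trace)))
  rest <- vo2_trace[vo2_trace$stage == "rest", ]
  if (nrow(rest) == 0) stop("trace has no rest stage")
  vo2_rest <- compute_ree(rest$time_s, rest$vo2_ml_min)

  stages <- names(stage_speeds_kmh())
  gross <- vapply(stages, function(s) {
    part <- vo2_trace[vo2_trace$stage == s, ]
    if (nrow(part) == 0) return(NA_real_)
    calibration_window(part$time_s, part$vo2_ml_min, stage_starts[[s]])
  }, numeric(1))
  vo2_stand <- gross[["stand"]]
  vo2_net <- compute_vo2net(gross, vo2_stand, weight_kg)
  speeds <- stage_speeds_kmh()
  out <- data.frame(
    stage = stages,
    speed_kmh = speeds,
    speed_eq = compute_speed_eq(kmh_to_ms(speeds), height_m),
    vo2_gross = as.numeric(gross),
    vo2_net = as.numeric(vo2_net),
    met = compute_met(as.numeric(gross), vo2_rest),
    sub_standing = as.logical(attr(vo2_net, "sub_standing")),
    row.names = NULL)
  attr(out, "vo2_rest") <- vo2_rest
  attr(out, "vo2_stand") <- vo2_stand
  out
}

#' Treadmill protocol stages and speeds
#'
#' The calibration protocol: 4 min standing, walking at 3-6 km/h and running
#' at 8 and 10 km/h, 4 min per stage. Speeds are stored in km/h as printed in
#' protocol descriptions and converted with [kmh_to_ms()] where needed.
#' @return named numeric vector of stage speeds in km/h (stand = 0).
#' @export
stage_speeds_kmh <- function() {
  c(stand = 0, walk3 = 3, walk4 = 4, walk5 = 5, walk6 = 6, run8 = 8, run10 = 10)
}
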