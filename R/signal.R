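# Raw-signal processing chain: resample -> truncate -> band-pass -> epoch
# aggregation. The chain order follows the device-matching convention: data are
# first brought to the 30 Hz / +-6 g envelope of the target device class, then
# filtered to the 0.29-10 Hz movement band, then aggregated to mg per epoch.

#' Resample a recording to a lower rate
#'
#' Anti-aliased down-sampling: a zero-phase Butterworth low-pass (order 8,
#' cut-off `0.45 * target_rate`) removes content above the new Nyquist
#' frequency, then the signal is evaluated on the target grid by cubic-spline
#' interpolation. Constants are preserved exactly and pass-band amplitudes to
#' well within 1 %. Upsampling is refused.
#'
#' @param rec a [triaxial_recording()].
#' @param target_rate new rate in Hz, `<= rec$sample_rate`.
#' @return resampled `triaxial_recording`.
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "triaxial_recording"))
  if (target_rate > rec$sample_rate)
    stop("upsampling not supported: target_rate exceeds the source rate")
  if (target_rate == rec$sample_rate) return(rec)
  n <- n_samples(rec)
  t_src <- (seq_len(n) - 1) / rec$sample_rate
  t_new <- seq(0, t_src[n], by = 1 / target_rate)
  aa <- butter_design(8, 0.45 * target_rate, fs = rec$sample_rate, type = "low")
  res <- lapply(rec[c("x", "y", "z")], function(ax) {
    filt <- filtfilt(aa, ax)
    splinefun(t_src, filt, method = "natural")(t_new)
  })
  triaxial_recording(res$x, res$y, res$z, sample_rate = target_rate,
                     start_time = rec$start_time, subject_id = rec$subject_id,
                     placement = rec$placement)
}

#' Truncate (clip) a recording to a symmetric acceleration range
#'
#' Clips every axis sample into `[-limit, +limit]` g, emulating the narrower
#' dynamic range of the device class the calibration targets.
#'
#' @param rec a [triaxial_recording()].
#' @param limit positive clip limit in g (default 6).
#' @return clipped `triaxial_recording`.
#' @export
truncate_recording <- function(rec, limit = 6) {
  stopifnot(inherits(rec, "triaxial_recording"), limit > 0)
  for (ax in c("x", "y", "z")) rec[[ax]] <- pmin(pmax(rec[[ax]], -limit), limit)
  rec
}

#' Band-pass filter a recording
#'
#' Each axis is filtered independently with a zero-phase (forward-backward)
#' Butterworth band-pass. The default band 0.29-10 Hz retains the frequency
#' content informative of human movement intensity while rejecting the static
#' gravity component and high-frequency noise.
#'
#' @param rec a [triaxial_recording()].
#' @param low,high band edges in Hz, `0 < low < high < rate/2`.
#' @param order total band-pass filter order (even; default 4).
#' @return filtered `triaxial_recording` (zero-mean axes).
#' @export
bandpass_recording <- function(rec, low = 0.29, high = 10, order = 4) {
  stopifnot(inherits(rec, "triaxial_recording"))
  if (!(0 < low && low < high)) stop("need 0 < low < high")
  if (high >= rec$sample_rate / 2)
    stop("invalid band: high edge must be below the Nyquist frequency")
  f <- butter_design(order, c(low, high), fs = rec$sample_rate, type = "band")
  for (ax in c("x", "y", "z")) rec[[ax]] <- filtfilt(f, rec[[ax]])
  rec
}

# mean over complete epochs of a per-sample series; trailing partial dropped
epoch_means <- function(v, samples_per_epoch) {
  n_ep <- floor(length(v) / samples_per_epoch)
  if (n_ep == 0) return(numeric(0))
  colMeans(matrix(v[seq_len(n_ep * samples_per_epoch)], nrow = samples_per_epoch))
}

#' Aggregate a filtered recording to mg per epoch
#'
#' The intensity metric: per sample the Euclidean norm of the band-pass
#' filtered triaxial signal, averaged within each epoch and expressed in
#' milli-g. The recording must already be truncated and band-pass filtered;
#' a trailing partial epoch is dropped, never padded.
#'
#' @param rec a band-pass filtered [triaxial_recording()].
#' @param epoch_length epoch length in seconds (default 3).
#' @return an [epoch_series()] of mg values.
#' @export
epoch_mg <- function(rec, epoch_length = 3) {
  stopifnot(inherits(rec, "triaxial_recording"))
  spe <- round(epoch_length * rec$sample_rate)
  if (spe < 2) stop("epoch shorter than 2 samples at this sample rate")
  nrm <- sqrt(rec$x^2 + rec$y^2 + rec$z^2)
  epoch_series(1000 * epoch_means(nrm, spe), epoch_length,
               start_time = rec$start_time, subject_id = rec$subject_id)
}

#' Aggregate a raw recording to ENMO per epoch
#'
#' Comparison metric: Euclidean Norm Minus One. Per sample,
#' `max(||(x,y,z)|| - 1, 0)` on the unfiltered gravity-including signal;
#' epoch value is the mean, in mg. Because negative lobes are discarded,
#' ENMO is not equivalent across movement frequencies, which is why the
#' band-pass mg metric is preferred; ENMO is provided for comparison only.
#'
#' @param rec a raw (resampled, unfiltered) [triaxial_recording()].
#' @param epoch_length epoch length in seconds (default 3).
#' @return an [epoch_series()] of ENMO values in mg.
#' @export
epoch_enmo <- function(rec, epoch_length = 3) {
  stopifnot(inherits(rec, "triaxial_recording"))
  spe <- round(epoch_length * rec$sample_rate)
  if (spe < 2) stop("epoch shorter than 2 samples at this sample rate")
  enmo <- pmax(sqrt(rec$x^2 + rec$y^2 + rec$z^2) - 1, 0)
  epoch_series(1000 * epoch_means(enmo, spe), epoch_length,
               start_time = rec$start_time, subject_id = rec$subject_id)
}

#' Steady-state calibration window mean
#'
#' Averages a measured series over the steady-state window of a constant-load
#' stage: one minute captured between stage-relative minutes 2:45 and 3:45,
#' i.e. stage-relative time in `[165, 225)` seconds. Works for any sampled
#' quantity (epoch mg, binned VO2).
#'
#' @param time_s sample/epoch times in seconds (same clock as `stage_start`).
#' @param values measured values parallel to `time_s`.
#' @param stage_start stage start time in seconds.
#' @param stage_duration optional stage duration in seconds; if given, the
#'   stage must last at least 225 s or an error is raised.
#' @return mean of the values inside the window.
#' @export
calibration_window <- function(time_s, values, stage_start, stage_duration = NULL) {
  stopifnot(length(time_s) == length(values))
  if (!is.null(stage_duration) && stage_duration < 225)
    stop("calibration window [165, 225) s extends beyond the stage")
  idx <- time_s - stage_start >= 165 & time_s - stage_start < 225
  if (!any(idx)) stop("no samples inside the calibration window")
  mean(values[idx])
}
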