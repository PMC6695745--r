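# Core containers: raw triaxial recordings and aggregated epoch series.

#' Construct a triaxial recording
#'
#' A validated container for raw triaxial acceleration. Axes are stored in
#' units of g; the device convention (e.g. 100 Hz, +-8 g range at the hip or
#' thigh) is carried as metadata.
#'
#' @param x,y,z numeric acceleration per axis, in g; equal length, no missing
#'   samples (gaps must be declared as non-wear upstream, never silent).
#' @param sample_rate sampling rate in Hz, positive.
#' @param start_time recording start, `POSIXct` (local wall clock).
#' @param subject_id subject identifier.
#' @param placement `"hip"` or `"thigh"`.
#' @return object of class `triaxial_recording`.
#' @export
triaxial_recording <- function(x, y, z, sample_rate,
                               start_time = as.POSIXct("2020-01-01 00:00:00", tz = "UTC"),
                               subject_id = "S1", placement = c("hip", "thigh")) {
  placement <- match.arg(placement)
  if (!(length(x) == length(y) && length(y) == length(z)))
    stop("axes must have equal length")
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("recording contains missing samples; declare gaps as non-wear instead")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive scalar (Hz)")
  structure(
    list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
         sample_rate = sample_rate, start_time = start_time,
         subject_id = subject_id, placement = placement),
    class = "triaxial_recording")
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf("<triaxial_recording> subject %s, %s, %g Hz, %d samples (%.1f s)\n",
              x$subject_id, x$placement, x$sample_rate, length(x$x),
              length(x$x) / x$sample_rate))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec a `triaxial_recording`.
#' @export
n_samples <- function(rec) length(rec$x)

#' Construct an epoch series
#'
#' Per-epoch physical-activity intensity in milli-g with a parallel wear flag.
#' Epoch start times are explicit so that subsetting (night exclusion, day
#' splitting) keeps the series consistent.
#'
#' @param intensity non-negative mg values, one per epoch.
#' @param epoch_length epoch length in seconds, in `[1, 60]`.
#' @param start_time start of the first epoch (`POSIXct`), used to derive
#'   per-epoch times when `time` is not given.
#' @param wear logical wear flag per epoch (default all `TRUE`).
#' @param time optional explicit epoch start times (`POSIXct`).
#' @param subject_id subject identifier.
#' @return object of class `epoch_series`.
#' @export
epoch_series <- function(intensity, epoch_length,
                         start_time = as.POSIXct("2020-01-01 00:00:00", tz = "UTC"),
                         wear = NULL, time = NULL, subject_id = "S1") {
  if (!is.numeric(epoch_length) || epoch_length < 1 || epoch_length > 60)
    stop("epoch_length must be in [1, 60] seconds")
  if (any(intensity < 0)) stop("intensity values must be >= 0 (mg)")
  n <- length(intensity)
  if (is.null(wear)) wear <- rep(TRUE, n)
  if (length(wear) != n) stop("wear must parallel intensity")
  if (is.null(time)) time <- start_time + epoch_length * (seq_len(n) - 1)
  if (length(time) != n) stop("time must parallel intensity")
  structure(
    list(intensity = as.numeric(intensity), wear = as.logical(wear),
         time = time, epoch_length = epoch_length,
         start_time = time[1][n > 0], subject_id = subject_id),
    class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> subject %s, %d epochs x %g s, %.1f%% wear\n",
              x$subject_id, length(x$intensity), x$epoch_length,
              if (length(x$wear)) 100 * mean(x$wear) else NA_real_))
  invisible(x)
}

# subset an epoch series by logical/integer index, keeping fields parallel
subset_epochs <- function(series, idx) {
  epoch_series(series$intensity[idx], series$epoch_length,
               wear = series$wear[idx], time = series$time[idx],
               subject_id = series$subject_id)
}
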