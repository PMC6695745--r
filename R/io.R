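# File formats, run configuration and the two study pipelines. CSV is the
# canonical interchange; device binary containers are out of scope.

#' Default run configuration
#'
#' The processing settings of the analysis: 0.29-10 Hz band, 30 Hz working
#' rate, +-6 g truncation, 3-s epochs, MET cut-points 1.5/3.0/6.0/9.0,
#' night window 23:00-06:00 and a 720-min valid-day rule.
#'
#' @param overrides named list merged over the defaults.
#' @return a `run_config` list.
#' @export
default_run_config <- function(overrides = list()) {
  cfg <- list(
    filter_band = c(0.29, 10),   # Hz
    filter_order = 4,
    target_rate = 30,            # Hz
    clip_g = 6,                  # g
    epoch_s = 3,                 # s
    met_cutpoints = default_met_cutpoints(),
    anchor_weight = 1000,
    grid_step_mg = 1,
    nonwear_min = 60,            # min
    nonwear_sd_mg = 3,           # mg
    night = c(23, 6),            # hours, half-open [23, 6)
    valid_day_min = 720,         # min
    min_valid_days = 1,
    seed = NULL)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with any subset of the [default_run_config()] fields.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # named scalar objects come back as lists; flatten them to named vectors
  raw <- lapply(raw, function(x)
    if (is.list(x) && length(x) &&
        all(vapply(x, function(e) is.atomic(e) && length(e) == 1, logical(1))))
      unlist(x) else x)
  default_run_config(raw)
}

#' Write a run configuration to JSON
#' @param cfg a `run_config`.
#' @param path output path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(jsonify(unclass(cfg)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

# named atomic vectors as JSON objects (jsonlite would drop the names)
jsonify <- function(x) {
  if (is.list(x)) lapply(x, jsonify)
  else if (is.atomic(x) && !is.null(names(x))) as.list(x)
  else x
}

# provenance block embedded in run reports
provenance <- function(cfg) {
  list(package = "accelcal",
       version = as.character(utils::packageVersion("accelcal")),
       config = unclass(cfg))
}

#' Read raw triaxial acceleration from CSV
#'
#' Expected header `time,x,y,z`; the time column is either ISO-8601
#' timestamps or elapsed seconds; accelerations are in g. The sample rate is
#' inferred from the timestamps and cross-checked against `sample_rate` when
#' given (must agree within 1 %). Gaps and missing samples are errors: gaps
#' must be declared as non-wear upstream, not silently bridged.
#'
#' @param path CSV path.
#' @param sample_rate expected rate in Hz (optional).
#' @param subject_id,placement recording metadata.
#' @return a [triaxial_recording()].
#' @export
read_raw_csv <- function(path, sample_rate = NULL, subject_id = "S1",
                         placement = "hip") {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time", "x", "y", "z") %in% names(d)))
  bad <- which(!is.finite(d$x) | !is.finite(d$y) | !is.finite(d$z))
  if (length(bad))
    stop("non-finite samples at rows: ", paste(head(bad, 5), collapse = ", "))
  tm <- suppressWarnings(as.numeric(d$time))
  if (anyNA(tm)) {
    tt <- as.POSIXct(d$time, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    start <- tt[1]; tm <- as.numeric(tt) - as.numeric(tt[1])
  } else {
    start <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC") + tm[1]
    tm <- tm - tm[1]
  }
  dt <- diff(tm)
  med <- stats::median(dt)
  gaps <- which(dt > 1.5 * med)
  if (length(gaps))
    stop("gap(s) in recording after t = ",
         paste(sprintf("%.3f s", tm[gaps]), collapse = ", "),
         "; declare gaps as non-wear")
  inferred <- 1 / med
  if (!is.null(sample_rate) && abs(inferred - sample_rate) / sample_rate > 0.01)
    stop(sprintf("sample-rate mismatch: inferred %.3f Hz vs declared %g Hz",
                 inferred, sample_rate))
  triaxial_recording(d$x, d$y, d$z,
                     sample_rate = if (is.null(sample_rate)) inferred else sample_rate,
                     start_time = start, subject_id = subject_id,
                     placement = placement)
}

#' Write raw triaxial acceleration to CSV (elapsed-seconds time column)
#' @param rec a [triaxial_recording()].
#' @param path output path.
#' @export
write_raw_csv <- function(rec, path) {
  tm <- (seq_len(n_samples(rec)) - 1) / rec$sample_rate
  write.csv(data.frame(time = tm, x = rec$x, y = rec$y, z = rec$z),
            path, row.names = FALSE)
  invisible(path)
}

#' Write an epoch series to CSV (`epoch_start,mg,wear`)
#' @param series an [epoch_series()].
#' @param path output path.
#' @export
write_epoch_csv <- function(series, path) {
  write.csv(data.frame(epoch_start = format(series$time, "%Y-%m-%dT%H:%M:%S"),
                       mg = series$intensity, wear = series$wear),
            path, row.names = FALSE)
  invisible(path)
}

#' Read an epoch series from CSV
#' @param path CSV with columns `epoch_start`, `mg`, `wear` (optional
#'   `nonwear` override column).
#' @param epoch_length epoch length in seconds.
#' @param subject_id subject identifier.
#' @export
read_epoch_csv <- function(path, epoch_length = 3, subject_id = "S1") {
  d <- read.csv(path, stringsAsFactors = FALSE)
  tt <- as.POSIXct(d$epoch_start, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  s <- epoch_series(d$mg, epoch_length, time = tt,
                    wear = if ("wear" %in% names(d)) d$wear else NULL,
                    subject_id = subject_id)
  if ("nonwear" %in% names(d)) s$declared_nonwear <- as.logical(d$nonwear)
  s
}

#' Write a cut-point table
#'
#' JSON for machines (cut-points, criterion cut-points, provenance) or a
#' wide CSV shaped like the published table (rows = level, columns =
#' age group x method) with an R-squared row per placement.
#'
#' @param table a `cutpoint_table`.
#' @param path output path; format chosen by extension (`.json` or `.csv`).
#' @param cfg optional `run_config` for provenance in JSON output.
#' @export
write_cutpoint_table <- function(table, path, cfg = NULL) {
  if (grepl("\\.json$", path)) {
    payload <- list(cutpoints = as.data.frame(table),
                    vo2net_cutpoints = jsonify(attr(table, "vo2net_cutpoints")),
                    met_cutpoints = jsonify(attr(table, "met_cutpoints")),
                    complete = attr(table, "complete"),
                    errors = attr(table, "errors"))
    if (!is.null(cfg)) payload$provenance <- provenance(cfg)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    wide <- NULL
    for (p in unique(table$placement)) {
      sub <- table[table$placement == p, ]
      cells <- split(sub, list(sub$age_group, sub$method))
      block <- data.frame(placement = p, level = c("LPA", "MPA", "VPA", "VVPA"))
      for (nm in names(cells)) {
        cell <- cells[[nm]]
        block[[nm]] <- cell$mg[match(block$level, cell$level)]
      }
      r2 <- data.frame(placement = p, level = "R2")
      for (nm in names(cells)) r2[[nm]] <- round(cells[[nm]]$r_squared[1], 2)
      wide <- rbind(wide, block, r2)
    }
    write.csv(wide, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a cut-point table from JSON
#' @param path JSON written by [write_cutpoint_table()].
#' @export
read_cutpoint_table <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- payload$cutpoints
  structure(tab, class = c("cutpoint_table", "data.frame"),
            vo2net_cutpoints = unlist(payload$vo2net_cutpoints),
            met_cutpoints = unlist(payload$met_cutpoints),
            complete = isTRUE(payload$complete),
            errors = unlist(payload$errors))
}

#' Process one raw recording to an epoch mg series
#'
#' The full signal chain in protocol order: resample to the working rate,
#' truncate to the clip range, band-pass filter, aggregate to mg epochs.
#'
#' @param rec a [triaxial_recording()].
#' @param cfg a [default_run_config()].
#' @return an [epoch_series()].
#' @export
process_recording <- function(rec, cfg = default_run_config()) {
  rec <- resample_recording(rec, cfg$target_rate)
  rec <- truncate_recording(rec, cfg$clip_g)
  rec <- bandpass_recording(rec, cfg$filter_band[1], cfg$filter_band[2],
                            order = cfg$filter_order)
  epoch_mg(rec, cfg$epoch_s)
}

#' Run the calibration pipeline on lab sessions
#'
#' For each subject: criterion values from the VO2 trace (REE, standing VO2,
#' per-stage VO2net and MET in the steady-state window) and the stage mg from
#' the processed hip and thigh recordings; then the full cut-point
#' calibration. Subjects with missing stages are excluded with a warning.
#'
#' @param sessions list of lab sessions (as from [simulate_lab_session()]:
#'   `hip`, `thigh`, `vo2`, `stage_starts`).
#' @param cohort subject data frame (`subject_id`, `age_group`, `height_m`,
#'   `weight_kg`).
#' @param cfg a [default_run_config()].
#' @return list as from [calibrate_cutpoints()], plus `points` and
#'   `provenance`.
#' @export
run_calibration_pipeline <- function(sessions, cohort, cfg = default_run_config()) {
  points <- list()
  for (ses in sessions) {
    s <- cohort[cohort$subject_id == ses$subject_id, ]
    if (nrow(s) != 1) {
      warning("no metadata for subject ", ses$subject_id, "; excluded")
      next
    }
    crit <- tryCatch(
      compute_criterion_values(ses$vo2, ses$stage_starts, s$height_m, s$weight_kg),
      error = function(e) {
        warning("subject ", ses$subject_id, " excluded: ", conditionMessage(e))
        NULL
      })
    if (is.null(crit) || anyNA(crit$vo2_gross)) {
      if (!is.null(crit)) warning("subject ", ses$subject_id,
                                  " excluded: missing stage data")
      next
    }
    for (p in c("hip", "thigh")) {
      ep <- process_recording(ses[[p]], cfg)
      t_ep <- (seq_along(ep$intensity) - 1) * ep$epoch_length
      mg <- vapply(crit$stage, function(st)
        calibration_window(t_ep, ep$intensity, ses$stage_starts[[st]]),
        numeric(1))
      points[[length(points) + 1]] <- data.frame(
        subject_id = s$subject_id, age_group = s$age_group, placement = p,
        stage = crit$stage, speed_kmh = crit$speed_kmh,
        speed_eq = crit$speed_eq, mg = unname(mg),
        vo2_net = crit$vo2_net, met = crit$met)
    }
  }
  if (!length(points)) stop("no usable calibration sessions")
  points <- do.call(rbind, points)
  out <- calibrate_cutpoints(points, cfg$met_cutpoints,
                             anchor_weight = cfg$anchor_weight,
                             grid_step = cfg$grid_step_mg)
  out$points <- points
  out$provenance <- provenance(cfg)
  out
}

#' Run the free-living pipeline
#'
#' Per subject: non-wear detection, night-window exclusion, classification
#' under both calibration methods with the age-appropriate cut-points, and
#' per-day summaries; then group summaries per method. Subjects without
#' metadata are excluded with a warning.
#'
#' @param series_list named list of [epoch_series()] (names = subject ids).
#' @param subjects data frame with `subject_id` and `age`.
#' @param table a `cutpoint_table`.
#' @param cfg a [default_run_config()].
#' @param placement cut-point placement to apply (default `"hip"`).
#' @return list with `days` (per method) and `summary` (per method,
#'   Table-2-shaped), plus `provenance`.
#' @export
run_freeliving_pipeline <- function(series_list, subjects, table,
                                    cfg = default_run_config(),
                                    placement = "hip") {
  days <- list(vo2net = list(), met = list())
  used <- character(0)
  for (sid in names(series_list)) {
    meta <- subjects[subjects$subject_id == sid, ]
    if (nrow(meta) != 1) {
      warning("no metadata for subject ", sid, "; excluded")
      next
    }
    ser <- detect_nonwear(series_list[[sid]], min_bout = cfg$nonwear_min,
                          sd_limit = cfg$nonwear_sd_mg)
    ser <- exclude_night(ser, cfg$night[1], cfg$night[2])
    grp <- cutpoint_group(meta$age)
    for (m in c("vo2net", "met")) {
      cp <- cutpoints_for(table, placement, grp, m)
      lv <- classify_epochs(ser, cp)
      days[[m]][[sid]] <- summarize_days(ser, lv, valid_min = cfg$valid_day_min)
    }
    used <- c(used, sid)
  }
  if (!length(used)) {
    warning("no usable subjects; returning empty summary")
    return(list(days = NULL, summary = NULL, provenance = provenance(cfg)))
  }
  days <- lapply(days, function(d) do.call(rbind, c(d, list(make.row.names = FALSE))))
  summary <- lapply(days, summarize_group, subjects = subjects,
                    min_valid_days = cfg$min_valid_days)
  list(days = days, summary = summary, provenance = provenance(cfg))
}
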