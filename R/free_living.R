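# Free-living classification: non-wear detection, night-window exclusion,
# epoch classification against mg cut-points, and per-day / per-group
# time-in-intensity summaries.

#' Map age to the cut-point calibration group
#'
#' Free-living participants younger than 13 use the children's cut-points,
#' 13-16 the adolescents', 17 and older the adults'.
#' @param age age in years.
#' @return character vector in `children`, `adolescents`, `adults`.
#' @export
cutpoint_group <- function(age) {
  ifelse(age < 13, "children", ifelse(age <= 16, "adolescents", "adults"))
}

#' Map age to the reporting age category
#'
#' Children < 13, adolescents 13-16, younger adults 17-49, older adults >= 50.
#' @param age age in years.
#' @export
age_category <- function(age) {
  factor(ifelse(age < 13, "children",
         ifelse(age <= 16, "adolescents",
         ifelse(age < 50, "adults_young", "adults_old"))),
         levels = c("children", "adolescents", "adults_young", "adults_old"))
}

#' Detect non-wear epochs
#'
#' An idle-flag substitute for CSV inputs: epochs inside any run of at least
#' `min_bout` minutes in which the signal is still are flagged non-wear.
#' Stillness is judged per epoch from the raw recording when available (all
#' axes' within-epoch standard deviation below `sd_limit` mg) and from the
#' epoch intensity otherwise (below `sd_limit` mg). An explicit
#' `declared_nonwear` flag on the series (e.g. a device idle column) takes
#' precedence over detection.
#'
#' @param series an [epoch_series()].
#' @param raw optional matching [triaxial_recording()] (band-pass filtered or
#'   raw; only within-epoch variability is used).
#' @param min_bout minimum still-run length in minutes (default 60).
#' @param sd_limit stillness threshold in mg (default 3).
#' @return the series with `wear` updated (`FALSE` inside non-wear runs).
#' @export
detect_nonwear <- function(series, raw = NULL, min_bout = 60, sd_limit = 3) {
  stopifnot(inherits(series, "epoch_series"))
  if (!is.null(series$declared_nonwear)) {
    series$wear <- !series$declared_nonwear
    return(series)
  }
  n <- length(series$intensity)
  if (!is.null(raw)) {
    spe <- round(series$epoch_length * raw$sample_rate)
    n_ep <- min(n, floor(n_samples(raw) / spe))
    axsd <- sapply(raw[c("x", "y", "z")], function(ax) {
      m <- matrix(ax[seq_len(n_ep * spe)], nrow = spe)
      sqrt(pmax(colMeans(m^2) - colMeans(m)^2, 0) * spe / (spe - 1))
    })
    still <- rep(FALSE, n)
    still[seq_len(n_ep)] <- apply(axsd * 1000, 1, max) < sd_limit
  } else {
    still <- series$intensity < sd_limit
  }
  min_epochs <- ceiling(min_bout * 60 / series$epoch_length)
  r <- rle(still)
  nonwear <- rep(r$values & r$lengths >= min_epochs, r$lengths)
  series$wear <- series$wear & !nonwear
  series
}

#' Exclude the night window
#'
#' Removes epochs whose start time falls in the half-open window
#' [23:00, 06:00): recordings during sleep hours are not analysed because
#' wear habits during sleep differ systematically between age groups.
#'
#' @param series an [epoch_series()] with local timestamps.
#' @param night_start,night_end window bounds as hours (defaults 23 and 6).
#' @return the series without night epochs.
#' @export
exclude_night <- function(series, night_start = 23, night_end = 6) {
  stopifnot(inherits(series, "epoch_series"))
  lt <- as.POSIXlt(series$time)
  hod <- lt$hour + lt$min / 60 + lt$sec / 3600
  night <- hod >= night_start | hod < night_end
  subset_epochs(series, !night)
}

#' Classify epochs into intensity levels
#'
#' Assigns to each wear epoch the highest level whose mg cut-point is reached
#' (intervals closed on the left: `mg >= cut-point` means that level); epochs
#' below the LPA cut-point are sedentary.
#'
#' @param series an [epoch_series()].
#' @param cutpoints named mg thresholds `c(LPA=, MPA=, VPA=, VVPA=)`,
#'   strictly increasing.
#' @return ordered factor of levels `SED < LPA < MPA < VPA < VVPA`, parallel
#'   to the epochs.
#' @export
classify_epochs <- function(series, cutpoints) {
  stopifnot(inherits(series, "epoch_series"))
  cp <- cutpoints[c("LPA", "MPA", "VPA", "VVPA")]
  if (anyNA(cp) || any(diff(cp) <= 0))
    stop("cut-points must be a complete, strictly increasing LPA..VVPA vector")
  lev <- intensity_levels()
  factor(lev[findInterval(series$intensity, cp) + 1], levels = lev, ordered = TRUE)
}

#' Summarize classified epochs into wear days
#'
#' Splits the series by calendar day and tallies wear minutes per intensity
#' level. A day is valid with at least `valid_min` minutes of wear time.
#' Non-wear epochs contribute to neither numerator nor denominator.
#'
#' @param series an [epoch_series()] (night already excluded if desired).
#' @param levels classification from [classify_epochs()], parallel to epochs.
#' @param valid_min valid-day wear threshold in minutes (default 720).
#' @return data frame with one row per day: `subject_id`, `date`,
#'   `wear_min`, `sed_min` .. `vvpa_min`, `mvpa_min`, `valid`.
#' @export
summarize_days <- function(series, levels, valid_min = 720) {
  stopifnot(inherits(series, "epoch_series"),
            length(levels) == length(series$intensity))
  ep_min <- series$epoch_length / 60
  date <- format(series$time, "%Y-%m-%d")
  lv <- intensity_levels()
  out <- lapply(split(seq_along(date), date), function(idx) {
    w <- idx[series$wear[idx]]
    mins <- vapply(lv, function(l) sum(levels[w] == l) * ep_min, numeric(1))
    data.frame(subject_id = series$subject_id, date = date[idx[1]],
               wear_min = length(w) * ep_min,
               sed_min = mins[["SED"]], lpa_min = mins[["LPA"]],
               mpa_min = mins[["MPA"]], vpa_min = mins[["VPA"]],
               vvpa_min = mins[["VVPA"]],
               mvpa_min = mins[["MPA"]] + mins[["VPA"]] + mins[["VVPA"]],
               valid = length(w) * ep_min >= valid_min)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Moderate-and-vigorous minutes
#'
#' MVPA = MPA + VPA + VVPA. Accepts a named vector or a data frame carrying
#' `mpa_min`, `vpa_min`, `vvpa_min` (or `MPA`, `VPA`, `VVPA`).
#' @param x named numeric vector or data frame.
#' @export
mvpa_minutes <- function(x) {
  if (is.data.frame(x)) {
    nm <- if ("mpa_min" %in% names(x)) c("mpa_min", "vpa_min", "vvpa_min")
          else c("MPA", "VPA", "VVPA")
    return(rowSums(x[nm]))
  }
  sum(x[c("MPA", "VPA", "VVPA")])
}

#' Group summary of daily time in intensity levels
#'
#' Per subject, valid days are averaged; subjects are then aggregated by age
#' category into mean (SD) daily minutes and percent of wear time per level,
#' plus MVPA. Subjects without any valid day are excluded with a warning.
#'
#' @param days per-day summaries from [summarize_days()] (rows for all
#'   subjects combined).
#' @param subjects data frame with `subject_id` and `age` (years).
#' @param min_valid_days minimum valid days to include a subject (default 1).
#' @return data frame with one row per age category x level (plus MVPA):
#'   `n`, `mean_min`, `sd_min`, `mean_pct`, `sd_pct`.
#' @export
summarize_group <- function(days, subjects, min_valid_days = 1) {
  stopifnot(all(c("subject_id", "age") %in% names(subjects)))
  days <- days[days$valid, , drop = FALSE]
  cols <- c("sed_min", "lpa_min", "mpa_min", "vpa_min", "vvpa_min", "mvpa_min")
  per_subj <- lapply(split(days, days$subject_id), function(d) {
    if (nrow(d) < min_valid_days) return(NULL)
    mins <- colMeans(d[c("wear_min", cols)])
    data.frame(subject_id = d$subject_id[1], t(mins))
  })
  per_subj <- Filter(Negate(is.null), per_subj)
  excluded <- setdiff(unique(subjects$subject_id), names(per_subj))
  if (length(excluded))
    warning("subjects without enough valid days were excluded: ",
            paste(excluded, collapse = ", "))
  per_subj <- do.call(rbind, per_subj)
  if (is.null(per_subj)) stop("no subject has a valid day")
  per_subj <- merge(per_subj, subjects[c("subject_id", "age")], by = "subject_id")
  per_subj$category <- age_category(per_subj$age)

  rows <- list()
  for (cat in levels(per_subj$category)) {
    sub <- per_subj[per_subj$category == cat, , drop = FALSE]
    if (nrow(sub) == 0) next
    for (col in cols) {
      lev <- toupper(sub("_min$", "", col))
      pct <- 100 * sub[[col]] / sub$wear_min
      rows[[length(rows) + 1]] <- data.frame(
        age_category = cat, level = lev, n = nrow(sub),
        mean_min = mean(sub[[col]]), sd_min = sd_or_zero(sub[[col]]),
        mean_pct = mean(pct), sd_pct = sd_or_zero(pct))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

sd_or_zero <- function(x) if (length(x) < 2) 0 else sd(x)
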