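# Seeded synthetic-data generator: treadmill calibration sessions and
# free-living weeks with closed-form ground truth.
#
# Generating model (the "stated world" the pipeline is tested against):
#   * VO2net per kg is a single shared power curve of equivalent speed,
#     f(se) = vo2_coef * se^vo2_exp, identical across age groups - encoding
#     the age-equivalence of VO2net at equal Speed_eq as generator truth.
#     Because children are shorter, equal absolute speed means higher se and
#     therefore higher VO2net in children.
#   * Hip mg is a single shared power curve of absolute speed (total
#     mechanical work); thigh mg is the hip curve inflated by a group factor,
#     largest in children (internal work of moving the limbs).
#   * MET follows from VO2net and group resting physiology:
#     MET = (stand + f(se)) / ree per kg, so younger groups show lower MET at
#     equal speed despite equal or higher effort.
# Group differences are all config parameters, never hard-coded, so null
# configs with no group difference are available for falsification tests.

#' Default generator configuration
#'
#' The defaults encode the calibration-study protocol (10 subjects per age
#' group; seated rest, stand, walks at 3-6 km/h, runs at 8 and 10 km/h) and
#' dispersion chosen to reproduce the published calibration fit quality
#' (R^2 ~ 0.96-0.98). Two constants are tuned analytically at config-build
#' time: the VO2net curve coefficient (adults walking at 5.6 km/h reach
#' 5.0 MET) and the hip mg coefficient (the adult hip moderate cut-point
#' lands at 167 mg). Free-living occupancy defaults are the published
#' age-category activity splits.
#'
#' @param seed integer seed (mandatory for any simulation).
#' @param overrides named list merged over the defaults (one level deep).
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed, overrides = list()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    lab_n = c(children = 10, adolescents = 10, adults = 10),
    groups = list(
      children    = list(age_range = c(9, 11),  height_mean = 1.45, height_sd = 0.07,
                         weight_mean = 36, weight_sd = 5,  ree_kg = 5.5),
      adolescents = list(age_range = c(14, 16), height_mean = 1.70, height_sd = 0.08,
                         weight_mean = 60, weight_sd = 8,  ree_kg = 4.3),
      adults      = list(age_range = c(23, 44), height_mean = 1.75, height_sd = 0.09,
                         weight_mean = 75, weight_sd = 10, ree_kg = 3.5)),
    stand_ratio = 1.25,        # standing VO2 as multiple of resting VO2
    vo2_exp = 1.15,            # curvature of f(se)
    adult_met_at_walk = 5.0,   # anchor: adult MET at 5.6 km/h
    anchor_walk_kmh = 5.6,
    mg_exp = 2.88,             # curvature of the shared hip mg-speed curve
    adult_hip_mpa_mg = 167,    # anchor: adult hip MPA cut-point (mg)
    thigh_mult = c(children = 1.89, adolescents = 1.75, adults = 1.63),
    stand_mg = 2,              # residual mg while standing still
    subject_econ_sdlog = 0.04, # between-subject movement economy
    subject_mg_sdlog = 0.03,   # between-subject accelerometer level
    subject_ree_sdlog = 0.05,  # between-subject resting metabolism
    mg_stage_cv = 0.03,        # within-stage mg measurement noise (direct mode)
    vo2net_meas_cv = 0.08,     # proportional VO2net point noise, direct mode
    vo2_trace_cv = 0.06,       # proportional raw VO2 trace noise
    vo2_tau = 30,              # s, mono-exponential VO2 kinetics
    sample_rate = 100,
    free_living = list(
      n = c(children = 12, adolescents = 12, adults_young = 12, adults_old = 12),
      age_ranges = list(children = c(4, 12), adolescents = c(13, 16),
                        adults_young = c(21, 49), adults_old = c(50, 67)),
      days = 7, epoch_s = 3,
      occupancy = rbind(   # SED, LPA, MPA, VPA, VVPA shares of wear time
        children     = c(64.8, 14.0, 15.1, 4.6, 1.5) / 100,
        adolescents  = c(77.1, 11.7,  9.7, 1.1, 0.4) / 100,
        adults_young = c(81.0, 11.7,  7.0, 0.2, 0.1) / 100,
        adults_old   = c(80.5, 12.5,  6.8, 0.2, 0.0) / 100),
      dwell_min = c(SED = 6, LPA = 1.5, MPA = 1.5, VPA = 0.75, VVPA = 0.5),
      transition = NULL,       # default derived from occupancy / dwell
      nonwear_prob = 0.3, nonwear_dur_min = c(60, 150),
      nonwear_window_h = c(8, 20),
      vvpa_top_mult = 1.35, sed_floor_mg = 4,
      start = as.POSIXct("2020-03-02 00:00:00", tz = "UTC"))
  )
  for (nm in names(overrides)) {
    if (nm %in% c("groups", "free_living") && is.list(overrides[[nm]])) {
      for (sub in names(overrides[[nm]])) cfg[[nm]][[sub]] <- overrides[[nm]][[sub]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }

  # analytic anchors (depend only on canonical group parameters)
  ad <- cfg$groups$adults
  se_anchor <- compute_speed_eq(kmh_to_ms(cfg$anchor_walk_kmh), ad$height_mean)
  f_anchor <- ad$ree_kg * (cfg$adult_met_at_walk - cfg$stand_ratio)
  cfg$vo2_coef <- f_anchor / se_anchor^cfg$vo2_exp
  vo2net_mpa <- ad$ree_kg * (3.0 - cfg$stand_ratio)
  se_mpa <- (vo2net_mpa / cfg$vo2_coef)^(1 / cfg$vo2_exp)
  v_mpa_kmh <- 3.6 * sqrt(se_mpa * 9.81 * ad$height_mean)
  cfg$mg_coef <- cfg$adult_hip_mpa_mg / v_mpa_kmh^cfg$mg_exp

  structure(cfg, class = "generator_config")
}

#' Remove all stochastic dispersion from a generator config
#'
#' Sets every noise and between-subject SD to zero so that simulated
#' calibration points lie exactly on the generating curves (the noise-free
#' limit used by parameter-recovery oracles).
#' @param cfg a [generator_config()].
#' @export
noise_free <- function(cfg) {
  for (g in names(cfg$groups)) {
    cfg$groups[[g]]$height_sd <- 0
    cfg$groups[[g]]$weight_sd <- 0
  }
  cfg$subject_econ_sdlog <- 0
  cfg$subject_mg_sdlog <- 0
  cfg$subject_ree_sdlog <- 0
  cfg$mg_stage_cv <- 0
  cfg$vo2net_meas_cv <- 0
  cfg$vo2_trace_cv <- 0
  cfg
}

# ---- generating curves (closed form) --------------------------------------

# mass-specific net VO2 at equivalent speed se
gt_vo2net_se <- function(se, cfg) cfg$vo2_coef * se^cfg$vo2_exp

# hip/thigh mg at absolute speed (km/h) for a canonical group member
gt_mg <- function(v_kmh, placement, group, cfg) {
  base <- cfg$mg_coef * v_kmh^cfg$mg_exp
  if (placement == "thigh") base <- base * cfg$thigh_mult[[group]]
  base
}

#' Analytic (ground-truth) cut-points for a generator config
#'
#' Closed-form inversion of the generating curves at canonical group
#' parameters: the VO2net cut-points are the images of the MET cut-points
#' under the adult linear MET-VO2net relation (slope = adult resting VO2 per
#' kg, intercept = minus adult standing VO2 per kg); the traditional method
#' uses each group's own resting physiology. Both are mapped to mg through
#' the equivalent-speed and mg-speed curves at the group mean height.
#'
#' @param cfg a [generator_config()].
#' @param met_cutpoints named MET cut-points.
#' @return list with `table` (data frame: placement, age_group, method,
#'   level, mg - exact, not rounded) and `vo2net_cutpoints`.
#' @export
analytic_cutpoints <- function(cfg, met_cutpoints = default_met_cutpoints()) {
  if (cfg$vo2_exp <= 0 || cfg$mg_exp <= 0)
    stop("generating curves must be monotone (positive exponents)")
  ad <- cfg$groups$adults
  vo2net_cp <- ad$ree_kg * (met_cutpoints - cfg$stand_ratio)
  names(vo2net_cp) <- names(met_cutpoints)
  rows <- list()
  for (g in names(cfg$groups)) {
    gp <- cfg$groups[[g]]
    for (p in c("hip", "thigh")) for (m in c("vo2net", "met")) {
      fcut <- if (m == "vo2net") vo2net_cp else
        gp$ree_kg * (met_cutpoints - cfg$stand_ratio)
      se <- (fcut / cfg$vo2_coef)^(1 / cfg$vo2_exp)
      v_kmh <- 3.6 * sqrt(se * 9.81 * gp$height_mean)
      rows[[length(rows) + 1]] <- data.frame(
        placement = p, age_group = g, method = m, level = names(met_cutpoints),
        mg = gt_mg(v_kmh, p, g, cfg))
    }
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  list(table = tab, vo2net_cutpoints = vo2net_cp)
}

# ---- cohorts ---------------------------------------------------------------

#' Simulate the calibration cohort
#'
#' Reproducible cohort of (by default) 10 children, 10 adolescents and 10
#' adults with group-appropriate anthropometry and latent between-subject
#' factors (economy, accelerometer level, resting metabolism). Sets the RNG
#' from `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @return data frame of subject profiles.
#' @export
simulate_cohort <- function(cfg) {
  set.seed(cfg$seed)
  rows <- list()
  for (g in names(cfg$groups)) {
    gp <- cfg$groups[[g]]; n <- cfg$lab_n[[g]]
    if (n == 0) next
    prefix <- c(children = "CH", adolescents = "AL", adults = "AD")[[g]]
    rows[[g]] <- data.frame(
      subject_id = sprintf("%s%02d", prefix, seq_len(n)),
      age_group = g,
      age = round(runif(n, gp$age_range[1], gp$age_range[2])),
      sex = rep_len(c("F", "M"), n),
      height_m = rnorm(n, gp$height_mean, gp$height_sd),
      weight_kg = pmax(rnorm(n, gp$weight_mean, gp$weight_sd), 15),
      ree_kg = gp$ree_kg * lognorm_factor(n, cfg$subject_ree_sdlog),
      econ_factor = lognorm_factor(n, cfg$subject_econ_sdlog),
      mg_factor = lognorm_factor(n, cfg$subject_mg_sdlog))
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

# mean-one log-normal multiplicative factor
lognorm_factor <- function(n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

# ---- direct calibration points (curves + noise, no raw signal) ------------

#' Simulate calibration points directly from the generating curves
#'
#' The fast route: one record per subject x stage x placement with mg and
#' criterion values drawn from the generating curves plus the configured
#' dispersion, bypassing raw-signal synthesis. In the noise-free limit the
#' points lie exactly on the curves, which makes this the route for exact
#' parameter-recovery oracles.
#'
#' @param cohort from [simulate_cohort()].
#' @param cfg the same [generator_config()].
#' @return calibration-point data frame (columns as in [calibrate_cutpoints()]).
#' @export
simulate_calibration_points <- function(cohort, cfg) {
  speeds <- stage_speeds_kmh()
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    s <- cohort[i, ]
    stand_kg <- cfg$stand_ratio * s$ree_kg
    for (p in c("hip", "thigh")) {
      se <- compute_speed_eq(kmh_to_ms(speeds), s$height_m)
      f <- gt_vo2net_se(se, cfg) * s$econ_factor
      vo2_net <- f + rnorm(length(f), 0, cfg$vo2net_meas_cv * f)
      vo2_net[1] <- 0                         # stand: zero by construction
      met <- (stand_kg + vo2_net) / s$ree_kg
      mg <- gt_mg(speeds, p, s$age_group, cfg) * s$mg_factor *
        exp(rnorm(length(speeds), 0, cfg$mg_stage_cv))
      mg[1] <- cfg$stand_mg
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = s$subject_id, age_group = s$age_group, placement = p,
        stage = names(speeds), speed_kmh = unname(speeds),
        speed_eq = unname(se), mg = unname(mg), vo2_net = unname(vo2_net),
        met = unname(met))
    }
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

# ---- raw lab sessions ------------------------------------------------------

#' Simulate one treadmill lab session with raw signals
#'
#' Produces 100 Hz hip and thigh recordings covering 4 min standing plus six
#' 4-min treadmill stages, and a 5-s binned VO2 trace covering a 20-min
#' seated rest followed by the stages. The accelerometer carrier is white
#' noise band-limited to 1-6 Hz (inside the analysis pass band) and scaled
#' per stage so that the expected post-filter epoch mg equals the generating
#' curve value for that subject and stage; VO2 rises to each stage plateau
#' with a 30-s mono-exponential. Draws from the current RNG state.
#'
#' @param subject one row of [simulate_cohort()].
#' @param cfg the [generator_config()].
#' @return list with `hip`, `thigh` ([triaxial_recording()]s, t = 0 at stand
#'   start), `vo2` (data frame `time_s`, `vo2_ml_min`, `stage`; rest occupies
#'   negative times), `stage_starts`, and `truth` (per-stage target mg and
#'   VO2 plateaus).
#' @export
simulate_lab_session <- function(subject, cfg) {
  speeds <- stage_speeds_kmh()
  stages <- names(speeds)
  stage_starts <- setNames((seq_along(stages) - 1) * 240, stages)
  fs <- cfg$sample_rate
  total_s <- 240 * length(stages)

  se <- compute_speed_eq(kmh_to_ms(speeds), subject$height_m)
  f <- gt_vo2net_se(se, cfg) * subject$econ_factor
  f[1] <- 0
  stand_abs <- cfg$stand_ratio * subject$ree_kg * subject$weight_kg
  rest_abs <- subject$ree_kg * subject$weight_kg
  plateaus <- stand_abs + f * subject$weight_kg    # absolute mL/min per stage

  # --- VO2 trace: 20-min rest on negative time, then the stages
  t_rest <- seq(-1200, -5, by = 5)
  t_act <- seq(0, total_s - 5, by = 5)
  prev <- c(rest_abs, plateaus[-length(plateaus)])
  k <- findInterval(t_act, stage_starts)
  t_rel <- t_act - stage_starts[k]
  v_act <- plateaus[k] + (prev[k] - plateaus[k]) * exp(-t_rel / cfg$vo2_tau)
  clean <- c(rep(rest_abs, length(t_rest)), v_act)
  vo2 <- data.frame(
    time_s = c(t_rest, t_act),
    vo2_ml_min = pmax(clean + rnorm(length(clean), 0, cfg$vo2_trace_cv * clean), 1),
    stage = c(rep("rest", length(t_rest)), stages[k]))

  # --- raw accelerometry: per-stage scaled band-limited carrier
  mg_target <- vapply(seq_along(stages), function(j) {
    if (stages[j] == "stand") cfg$stand_mg else
      gt_mg(speeds[[j]], "hip", subject$age_group, cfg) * subject$mg_factor *
        exp(rnorm(1, 0, cfg$mg_stage_cv))
  }, numeric(1))
  carrier_band <- butter_design(4, c(1, 6), fs = fs, type = "band")
  make_rec <- function(placement) {
    mult <- if (placement == "thigh") cfg$thigh_mult[[subject$age_group]] else 1
    n <- total_s * fs
    axes <- lapply(1:3, function(a) {
      raw <- filtfilt(carrier_band, rnorm(n))
      for (j in seq_along(stages)) {
        idx <- (stage_starts[j] * fs + 1):((stage_starts[j] + 240) * fs)
        sigma <- mg_target[j] * mult / 1000 / sqrt(2) / (gamma(2) / gamma(1.5))
        raw[idx] <- raw[idx] / sd(raw[idx]) * sigma
      }
      raw
    })
    triaxial_recording(axes[[1]] + 1, axes[[2]], axes[[3]], sample_rate = fs,
                       subject_id = subject$subject_id, placement = placement)
  }
  list(subject_id = subject$subject_id,
       hip = make_rec("hip"), thigh = make_rec("thigh"),
       vo2 = vo2, stage_starts = stage_starts,
       truth = data.frame(stage = stages, speed_kmh = unname(speeds),
                          mg_target_hip = mg_target,
                          vo2_plateau = unname(plateaus)))
}

#' Simulate the whole lab study
#'
#' Cohort plus one raw lab session per subject, fully determined by
#' `cfg$seed`.
#' @param cfg a [generator_config()].
#' @return list with `cohort` and `sessions` (named by subject).
#' @export
simulate_lab_study <- function(cfg) {
  cohort <- simulate_cohort(cfg)       # sets the seed
  sessions <- lapply(seq_len(nrow(cohort)), function(i)
    simulate_lab_session(cohort[i, ], cfg))
  names(sessions) <- cohort$subject_id
  list(cohort = cohort, sessions = sessions)
}

# ---- free-living -----------------------------------------------------------

#' Simulate the free-living cohort
#'
#' Age categories: children, adolescents, younger adults, older adults, with
#' configurable sizes and age ranges. Sets the RNG from `cfg$seed`.
#' @param cfg a [generator_config()].
#' @return data frame with `subject_id`, `age`, `category`, `cutpoint_group`.
#' @export
simulate_freeliving_cohort <- function(cfg) {
  set.seed(cfg$seed)
  fl <- cfg$free_living
  rows <- lapply(names(fl$n), function(catg) {
    n <- fl$n[[catg]]
    if (n == 0) return(NULL)
    ages <- round(runif(n, fl$age_ranges[[catg]][1], fl$age_ranges[[catg]][2]))
    data.frame(subject_id = sprintf("FL_%s_%02d", catg, seq_len(n)),
               age = ages, category = catg, cutpoint_group = cutpoint_group(ages))
  })
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

# default bout-to-bout transition matrix from target occupancy and dwells:
# identical rows proportional to occupancy / mean dwell
fl_transition <- function(cfg, category) {
  fl <- cfg$free_living
  if (!is.null(fl$transition)) return(fl$transition)
  occ <- fl$occupancy[category, ]
  p <- occ / fl$dwell_min
  p <- p / sum(p)
  matrix(rep(p, 5), nrow = 5, byrow = TRUE,
         dimnames = list(intensity_levels(), intensity_levels()))
}

#' Simulate one free-living week of 3-s epochs
#'
#' A semi-Markov process over the five intensity states: bout states follow
#' the transition matrix (each day starts sedentary), bout durations are
#' exponential with state-specific means, and each epoch's mg is drawn
#' uniformly within the state's band of the subject's ground-truth hip
#' cut-points. Night (23:00-06:00) is planted as device-off sleep and daytime
#' non-wear bouts as zero signal; both carry wear = FALSE in the truth.
#' Draws from the current RNG state.
#'
#' @param subject one row of [simulate_freeliving_cohort()].
#' @param cfg a [generator_config()].
#' @param truth_cutpoints optional precomputed [analytic_cutpoints()] result.
#' @return list with `series` (an [epoch_series()], wear flags all `TRUE` -
#'   non-wear is for the pipeline to find) and `truth` (`state` per epoch,
#'   `wear` per epoch).
#' @export
simulate_free_living_week <- function(subject, cfg, truth_cutpoints = NULL) {
  fl <- cfg$free_living
  if (is.null(truth_cutpoints)) truth_cutpoints <- analytic_cutpoints(cfg)
  tt <- truth_cutpoints$table
  cp <- tt$mg[tt$placement == "hip" & tt$method == "vo2net" &
                tt$age_group == subject$cutpoint_group]
  names(cp) <- tt$level[tt$placement == "hip" & tt$method == "vo2net" &
                          tt$age_group == subject$cutpoint_group]
  cp <- cp[c("LPA", "MPA", "VPA", "VVPA")]
  lo <- c(fl$sed_floor_mg, cp)
  hi <- c(cp, cp[["VVPA"]] * fl$vvpa_top_mult)

  trans <- fl_transition(cfg, subject$category)
  ep_day <- 86400 / fl$epoch_s
  lev <- intensity_levels()
  state_all <- integer(0); mg_all <- numeric(0); wear_all <- logical(0)
  for (day in seq_len(fl$days)) {
    st <- integer(0); s <- 1L  # start the day sedentary
    while (length(st) < ep_day) {
      dwell_ep <- max(1L, round(rexp(1, 1 / fl$dwell_min[[s]]) * 60 / fl$epoch_s))
      st <- c(st, rep(s, dwell_ep))
      s <- sample.int(5L, 1L, prob = trans[s, ])
    }
    st <- st[seq_len(ep_day)]
    mg <- runif(ep_day, lo[st], hi[st])
    wear <- rep(TRUE, ep_day)

    hrs <- (seq_len(ep_day) - 1) * fl$epoch_s / 3600
    night <- hrs >= 23 | hrs < 6
    mg[night] <- runif(sum(night), 0, 1)
    wear[night] <- FALSE                    # device off during sleep
    if (runif(1) < fl$nonwear_prob) {
      start_h <- runif(1, fl$nonwear_window_h[1], fl$nonwear_window_h[2])
      dur_h <- runif(1, fl$nonwear_dur_min[1], fl$nonwear_dur_min[2]) / 60
      nw <- hrs >= start_h & hrs < start_h + dur_h
      mg[nw] <- 0; wear[nw] <- FALSE
    }
    st[!wear] <- NA_integer_
    state_all <- c(state_all, st); mg_all <- c(mg_all, mg)
    wear_all <- c(wear_all, wear)
  }
  series <- epoch_series(mg_all, fl$epoch_s, start_time = fl$start,
                         subject_id = subject$subject_id)
  list(series = series,
       truth = list(state = factor(lev[state_all], levels = lev, ordered = TRUE),
                    wear = wear_all))
}

#' Simulate the whole free-living study
#'
#' Cohort plus one week per subject, fully determined by `cfg$seed`.
#' @param cfg a [generator_config()].
#' @return list with `subjects`, `weeks` (named by subject) and
#'   `truth_cutpoints`.
#' @export
simulate_free_living_study <- function(cfg) {
  subjects <- simulate_freeliving_cohort(cfg)  # sets the seed
  tc <- analytic_cutpoints(cfg)
  weeks <- lapply(seq_len(nrow(subjects)), function(i)
    simulate_free_living_week(subjects[i, ], cfg, tc))
  names(weeks) <- subjects$subject_id
  list(subjects = subjects, weeks = weeks, truth_cutpoints = tc)
}
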