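# synthetic_data: determinism, encoded structure, ground-truth oracles

test_that("cohorts are deterministic under a fixed seed", {
  cfg <- generator_config(123)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  expect_false(identical(simulate_cohort(generator_config(124)),
                         simulate_cohort(cfg)))
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co), 30)
  expect_equal(as.integer(table(co$age_group)[c("children", "adolescents",
                                                "adults")]),
               c(10L, 10L, 10L))
  hm <- tapply(co$height_m, co$age_group, mean)
  expect_true(hm[["children"]] < hm[["adolescents"]])
  expect_true(hm[["adolescents"]] < hm[["adults"]])
  expect_error(generator_config(), "seed")
})

test_that("generator anchors reproduce published physiology", {
  cfg <- generator_config(1)
  # adults walking at 5.6 km/h sit at 5.0 MET by construction
  se <- compute_speed_eq(kmh_to_ms(5.6), cfg$groups$adults$height_mean)
  f <- cfg$vo2_coef * se^cfg$vo2_exp
  met <- (cfg$stand_ratio * cfg$groups$adults$ree_kg + f) / cfg$groups$adults$ree_kg
  expect_equal(met, 5.0, tolerance = 1e-9)
  # children at the same walk are near the published ~4.3 MET
  sec <- compute_speed_eq(kmh_to_ms(5.6), cfg$groups$children$height_mean)
  fc <- cfg$vo2_coef * sec^cfg$vo2_exp
  metc <- (cfg$stand_ratio * cfg$groups$children$ree_kg + fc) /
    cfg$groups$children$ree_kg
  expect_lt(abs(metc - 4.3), 0.5)
  expect_lt(metc, met)
  # the adult hip moderate cut-point is tuned to 167 mg exactly
  an <- analytic_cutpoints(cfg)$table
  expect_equal(an$mg[an$age_group == "adults" & an$placement == "hip" &
                       an$method == "vo2net" & an$level == "MPA"], 167)
})

test_that("noise-free lab points lie exactly on the generating curves", {
  cfg <- noise_free(generator_config(6))
  co <- simulate_cohort(cfg)
  pts <- simulate_calibration_points(co, cfg)
  # children have strictly higher VO2net than adults at every common speed
  for (st in c("walk3", "walk6", "run10")) {
    ch <- unique(pts$vo2_net[pts$stage == st & pts$age_group == "children"])
    ad <- unique(pts$vo2_net[pts$stage == st & pts$age_group == "adults"])
    expect_length(ch, 1)   # all subjects identical when noise-free
    expect_gt(ch, ad)
  }
  # hip mg is shared across groups at equal speed (total mechanical work)
  for (st in c("walk4", "run8"))
    expect_length(unique(pts$mg[pts$stage == st & pts$placement == "hip"]), 1)
  # thigh is inflated most for children
  for (st in c("walk4", "run8")) {
    r <- function(g) unique(pts$mg[pts$stage == st & pts$placement == "thigh" &
                                     pts$age_group == g]) /
      unique(pts$mg[pts$stage == st & pts$placement == "hip" &
                      pts$age_group == g])
    expect_gt(r("children"), r("adolescents"))
    expect_gt(r("adolescents"), r("adults"))
  }
})

test_that("raw lab sessions realize the target stage mg through the chain", {
  cfg <- generator_config(2)
  co <- simulate_cohort(cfg)
  s <- co[co$age_group == "adults", ][1, ]
  set.seed(2)
  ses <- simulate_lab_session(s, cfg)
  ep <- process_recording(ses$hip)
  tt <- (seq_along(ep$intensity) - 1) * ep$epoch_length
  got <- vapply(names(ses$stage_starts), function(st)
    calibration_window(tt, ep$intensity, ses$stage_starts[[st]]), numeric(1))
  target <- ses$truth$mg_target_hip
  moving <- target > 10   # skip the near-still stand stage
  expect_rel_equal(got[moving], target[moving], 0.05)
})

test_that("analytic cut-points invert the generating curves in closed form", {
  cfg <- generator_config(3)
  an <- analytic_cutpoints(cfg)
  # strictly increasing in the criterion value within every cell
  for (cell in split(an$table, an$table[c("placement", "age_group", "method")],
                     drop = TRUE)) {
    mg <- cell$mg[match(c("LPA", "MPA", "VPA", "VVPA"), cell$level)]
    expect_true(all(diff(mg) > 0))
  }
  # adult cells identical across methods by construction
  ad <- an$table[an$table$age_group == "adults", ]
  wide <- split(ad$mg, ad$method)
  expect_equal(wide$vo2net, wide$met)

  # linear generating curve (vo2net = c * mg): cut-point mg = cutpoint / c
  lin <- generator_config(3, overrides = list(vo2_exp = 1, mg_exp = 2))
  anl <- analytic_cutpoints(lin)
  hip_ad <- anl$table[anl$table$age_group == "adults" &
                        anl$table$placement == "hip" &
                        anl$table$method == "vo2net", ]
  # slope from the MPA anchor, then check every level
  cc <- anl$vo2net_cutpoints[["MPA"]] /
    hip_ad$mg[hip_ad$level == "MPA"]
  expect_equal(hip_ad$mg[match(c("LPA", "MPA", "VPA", "VVPA"), hip_ad$level)],
               unname(anl$vo2net_cutpoints / cc), tolerance = 1e-9)

  # non-monotone generating curve is refused
  bad <- generator_config(3)
  bad$vo2_exp <- -1
  expect_error(analytic_cutpoints(bad), "monotone")
})

test_that("free-living weeks honour the planted structure", {
  # identity transition starting sedentary -> all wear epochs sedentary
  cfg <- small_fl_config(7, n = c(children = 1, adolescents = 0,
                                  adults_young = 0, adults_old = 0), days = 2)
  cfg$free_living$transition <- diag(5)
  cfg$free_living$nonwear_prob <- 0
  fl <- simulate_free_living_study(cfg)
  w <- fl$weeks[[1]]
  expect_true(all(w$truth$state[w$truth$wear] == "SED"))

  # with no non-wear bouts, planted wear is 17 h/day -> every day valid
  ser <- exclude_night(detect_nonwear(w$series))
  lv <- classify_epochs(ser, cutpoints_for(analytic_table(cfg), "hip",
                                           "children", "vo2net"))
  d <- summarize_days(ser, lv)
  expect_true(all(d$valid))
  expect_equal(d$wear_min, rep(17 * 60, 2))

  # noise-free epochs classified with generator-matched cut-points
  # recover the true state labels exactly
  cfg2 <- small_fl_config(8, n = c(children = 1, adolescents = 0,
                                   adults_young = 1, adults_old = 0), days = 2)
  fl2 <- simulate_free_living_study(cfg2)
  for (sid in names(fl2$weeks)) {
    w2 <- fl2$weeks[[sid]]
    grp <- fl2$subjects$cutpoint_group[fl2$subjects$subject_id == sid]
    lv2 <- classify_epochs(w2$series, cutpoints_for(analytic_table(cfg2),
                                                    "hip", grp, "vo2net"))
    wear <- w2$truth$wear
    expect_equal(as.character(lv2[wear]), as.character(w2$truth$state[wear]))
  }
})
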