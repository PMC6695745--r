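# free_living: non-wear, night window, classification, day/group summaries

test_that("non-wear detection flags long still runs and respects overrides", {
  # 8 h of zero variance inside a day -> non-wear
  day <- c(runif(4 * 60, 20, 300), rep(0, 8 * 60), runif(5 * 60, 20, 300))
  ser <- epoch_series(day, 60, start_time = t0())
  det <- detect_nonwear(ser)
  expect_true(all(!det$wear[241:720]))
  expect_true(all(det$wear[c(1:240, 721:1020)]))

  # 30 min of stillness stays wear (below the 60-min run threshold)
  day2 <- c(runif(120, 20, 300), rep(0, 30), runif(120, 20, 300))
  det2 <- detect_nonwear(epoch_series(day2, 60, start_time = t0()))
  expect_true(all(det2$wear))

  # an explicit idle column takes precedence
  ser$declared_nonwear <- rep(c(FALSE, TRUE), c(1000, 20))
  det3 <- detect_nonwear(ser)
  expect_identical(det3$wear, !ser$declared_nonwear)

  # raw-signal route: within-epoch axis SD below 3 mg counts as still
  set.seed(9)
  rec <- make_rec(0, rate = 30, dur = 3 * 3600)
  active <- rep(c(TRUE, FALSE), c(3600 * 30, 2 * 3600 * 30))
  for (ax in c("x", "y", "z"))
    rec[[ax]] <- ifelse(active, rnorm(length(active), 0, 0.05), 0)
  ser4 <- epoch_mg(rec, 60)
  det4 <- detect_nonwear(ser4, raw = rec)
  expect_true(all(det4$wear[1:60]))
  expect_true(all(!det4$wear[61:180]))
})

test_that("planted non-wear in a synthetic week is recovered >= 99 %", {
  cfg <- small_fl_config(4, n = c(children = 1, adolescents = 0,
                                  adults_young = 1, adults_old = 0), days = 7)
  fl <- simulate_free_living_study(cfg)
  for (w in fl$weeks) {
    det <- detect_nonwear(w$series)
    expect_gt(mean(det$wear == w$truth$wear), 0.99)
  }
})

test_that("night exclusion is half-open [23:00, 06:00)", {
  times <- t0() + c(22 * 3600 + 59 * 60, 23 * 3600, 23 * 3600 + 1,
                    5 * 3600 + 59 * 60 + 57, 6 * 3600, 12 * 3600)
  ser <- epoch_series(rep(10, 6), 3, time = times)
  out <- exclude_night(ser)
  expect_equal(format(out$time, "%H:%M:%S"),
               c("22:59:00", "06:00:00", "12:00:00"))
  # 24 h continuous day -> 17 h of epochs remain
  full <- epoch_series(rep(1, 28800), 3, start_time = t0())
  expect_length(exclude_night(full)$intensity, 17 * 1200)
})

test_that("classification is closed on the left with SED below LPA", {
  cp <- c(LPA = 39, MPA = 167, VPA = 582, VVPA = 994)  # adult hip values
  ser <- epoch_series(c(0, 38, 39, 166, 167, 581, 582, 994, 2000), 3,
                      start_time = t0())
  lv <- classify_epochs(ser, cp)
  expect_equal(as.character(lv),
               c("SED", "SED", "LPA", "LPA", "MPA", "MPA", "VPA", "VVPA", "VVPA"))
  expect_true(is.ordered(lv))
  expect_error(classify_epochs(ser, c(LPA = 100, MPA = 50, VPA = 500,
                                      VVPA = 900)), "increasing")
})

test_that("lowering a cut-point never decreases time at or above that level", {
  set.seed(13)
  ser <- epoch_series(runif(5000, 0, 1200), 3, start_time = t0())
  cp <- c(LPA = 39, MPA = 167, VPA = 582, VVPA = 994)
  base <- classify_epochs(ser, cp)
  for (lev in names(cp)) {
    lowered <- cp
    lowered[lev] <- cp[lev] * 0.7
    if (any(diff(lowered) <= 0)) next
    alt <- classify_epochs(ser, lowered)
    expect_gte(sum(alt >= lev), sum(base >= lev))
  }
})

test_that("day summaries conserve minutes and apply the 720-min rule", {
  # 720 one-minute wear epochs, all sedentary -> valid day at 100 % SED
  ser <- epoch_series(rep(0, 720), 60, start_time = t0() + 6 * 3600)
  lv <- classify_epochs(ser, c(LPA = 39, MPA = 167, VPA = 582, VVPA = 994))
  d <- summarize_days(ser, lv)
  expect_equal(d$sed_min, 720)
  expect_equal(d$wear_min, 720)
  expect_true(d$valid)
  # 719 min -> invalid
  d719 <- summarize_days(subset_719 <- epoch_series(rep(0, 719), 60,
                                                    start_time = t0() + 6 * 3600),
                         factor(rep("SED", 719),
                                levels = c("SED", "LPA", "MPA", "VPA", "VVPA"),
                                ordered = TRUE))
  expect_false(d719$valid)

  # mixed synthetic day: minutes match a brute-force tally, and conserve
  set.seed(17)
  ser2 <- epoch_series(runif(20000, 0, 1500), 3, start_time = t0(),
                       wear = runif(20000) > 0.1)
  cp <- c(LPA = 39, MPA = 167, VPA = 582, VVPA = 994)
  lv2 <- classify_epochs(ser2, cp)
  d2 <- summarize_days(ser2, lv2)
  for (i in seq_len(nrow(d2))) {
    idx <- format(ser2$time, "%Y-%m-%d") == d2$date[i] & ser2$wear
    tally <- table(lv2[idx]) * 3 / 60
    expect_equal(d2$sed_min[i], unname(tally[["SED"]]))
    expect_equal(d2$vvpa_min[i], unname(tally[["VVPA"]]))
    expect_equal(d2$sed_min[i] + d2$lpa_min[i] + d2$mpa_min[i] +
                   d2$vpa_min[i] + d2$vvpa_min[i], d2$wear_min[i],
                 tolerance = 1e-6)
    expect_equal(d2$mvpa_min[i], d2$mpa_min[i] + d2$vpa_min[i] + d2$vvpa_min[i])
  }
})

test_that("group summary averages valid days per subject then by category", {
  days <- data.frame(subject_id = "S1", date = "2020-03-02", wear_min = 800,
                     sed_min = 500, lpa_min = 150, mpa_min = 100,
                     vpa_min = 40, vvpa_min = 10, mvpa_min = 150, valid = TRUE)
  subjects <- data.frame(subject_id = "S1", age = 10)
  g <- summarize_group(days, subjects)
  expect_equal(g$mean_min[g$level == "MVPA"], 150)
  expect_equal(g$sd_min[g$level == "MVPA"], 0)
  expect_equal(g$mean_pct[g$level == "MPA"], 100 * 100 / 800)
  expect_equal(unique(g$age_category), "children")
  # per-day percentages over the levels sum to 100
  expect_equal(sum(g$mean_pct[g$level != "MVPA"]), 100)

  # a subject with no valid day is excluded with a warning
  days2 <- rbind(days, within(days, {
    subject_id <- "S2"; valid <- FALSE
  }))
  subjects2 <- rbind(subjects, data.frame(subject_id = "S2", age = 40))
  expect_warning(g2 <- summarize_group(days2, subjects2), "S2")
  expect_false("adults_young" %in% g2$age_category)
})

test_that("age maps to cut-point groups and reporting categories", {
  expect_equal(cutpoint_group(c(4, 12, 13, 16, 17, 49, 50, 67)),
               c("children", "children", "adolescents", "adolescents",
                 "adults", "adults", "adults", "adults"))
  expect_equal(as.character(age_category(c(12, 13, 16, 17, 49, 50))),
               c("children", "adolescents", "adolescents",
                 "adults_young", "adults_young", "adults_old"))
})
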