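# shared fixture builders - everything is generated in code, no data files

t0 <- function() as.POSIXct("2020-03-02 00:00:00", tz = "UTC")

# recording with all axes equal to a given function of time
make_rec <- function(f, rate = 100, dur = 60, placement = "hip") {
  tt <- seq(0, dur - 1 / rate, by = 1 / rate)
  v <- if (is.function(f)) f(tt) else rep(f, length(tt))
  triaxial_recording(v, v, v, sample_rate = rate, start_time = t0(),
                     placement = placement)
}

sine_rec <- function(freq, amp = 1, rate = 100, dur = 60) {
  make_rec(function(tt) amp * sin(2 * pi * freq * tt), rate = rate, dur = dur)
}

# ground-truth cut-point table as a classification-ready cutpoint_table
# (mg kept at full precision so generator-matched classification is exact)
analytic_table <- function(cfg) {
  an <- analytic_cutpoints(cfg)
  tab <- an$table
  tab$r_squared <- 1
  structure(tab, class = c("cutpoint_table", "data.frame"),
            vo2net_cutpoints = an$vo2net_cutpoints,
            met_cutpoints = default_met_cutpoints(),
            complete = TRUE, errors = character(0))
}

# tiny free-living generator config (scaled for test runtime)
small_fl_config <- function(seed, n = c(children = 2, adolescents = 2,
                                        adults_young = 2, adults_old = 2),
                            days = 2) {
  generator_config(seed, overrides = list(free_living = list(n = n, days = days)))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
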