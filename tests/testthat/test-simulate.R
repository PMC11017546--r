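test_that("the generator is byte-identical under a fixed seed", {
  cfg <- sim_config(n_locations = 4, n_days = 120, n_children = 3000,
                    seed = 99)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$exposure$pm25, b$exposure$pm25)
  expect_identical(a$exposure$tmax, b$exposure$tmax)
  expect_identical(a$records, b$records)
  # a different seed moves the draws
  c2 <- simulate_study(sim_config(n_locations = 4, n_days = 120,
                                  n_children = 3000, seed = 100))
  expect_false(identical(a$records, c2$records))
})

test_that("zero amplitudes and zero noise give constant series", {
  cfg <- sim_config(n_locations = 3, n_days = 90, n_children = 300,
                    seed = 1,
                    pm_params = list(winter_amp = 0, ar_sd = 0,
                                     spatial_sd = 0, local_sd = 0,
                                     spike_rate = 0),
                    temp_params = list(amplitude = 0, noise_sd = 0,
                                       spatial_sd = 0))
  st <- simulate_exposure(cfg)
  expect_equal(max(st$pm25) - min(st$pm25), 0)
  expect_equal(unique(as.vector(st$pm25)),
               exp(cfg$pm_params$baseline_log_mean))
  expect_equal(max(st$tmax) - min(st$tmax), 0)
})

test_that("default exposure series land in the emulated regime", {
  st <- simulate_exposure(sim_config(seed = 2024))
  pm <- st$pm25
  expect_gt(min(pm), 0.1)
  expect_lt(max(pm), 80)
  expect_gt(max(pm), 15)          # smoke episodes reach unhealthy levels
  seas <- season_of(st$dates)
  # wood-smoke winters sit above shoulder seasons at the median
  expect_gt(median(pm[seas == "winter", ]), median(pm[seas == "fall", ]))
  tm <- st$tmax
  expect_gt(mean(tm[seas == "summer", ]), mean(tm[seas == "winter", ]) + 10)
  expect_identical(dim(pm), c(821L, 25L))
})

test_that("the null hazard reproduces the baseline event rate", {
  tr <- sim_truth(lag_coeffs = rep(0, 15), temp_interaction = 0)
  cfg <- sim_config(n_locations = 5, n_days = 400, n_children = 20000,
                    seed = 8, truth = tr)
  st <- simulate_exposure(cfg)
  rec <- simulate_events(cfg, st)
  expect_equal(attr(rec, "alpha"), stats::qlogis(tr$baseline_daily_rate),
               tolerance = 1e-6)
  expected <- tr$baseline_daily_rate * 20000 * (400 - 14)
  expect_lt(abs(nrow(rec) - expected) / sqrt(expected), 4)
})

test_that("a stronger lag effect produces more events (uncalibrated)", {
  mk <- function(b) sim_config(
    n_locations = 5, n_days = 400, n_children = 8000, seed = 55,
    truth = sim_truth(lag_coeffs = c(rep(b, 14), 0), temp_interaction = 0))
  cfg1 <- mk(0.004); cfg2 <- mk(0.012)
  st <- simulate_exposure(cfg1)
  n1 <- nrow(simulate_events(cfg1, st, calibrate = FALSE))
  n2 <- nrow(simulate_events(cfg2, st, calibrate = FALSE))
  expect_gt(n2, n1)
})

test_that("classified category shares track the configured mix", {
  st <- small_study(seed = 123, n_days = 400, n_children = 20000)
  ev <- build_case_events(st$records)
  share <- table(ev$category) / nrow(st$records)
  # URTI dominates, asthma and LRTI are small; dual-listed infection codes
  # push LRTI slightly above its nominal draw probability
  expect_gt(share[["URTI"]], 0.75)
  expect_lt(share[["URTI"]], 0.92)
  expect_true(share[["asthma"]] > 0.05 && share[["asthma"]] < 0.15)
  expect_true(share[["LRTI"]] > 0.04 && share[["LRTI"]] < 0.18)
  # some records match no category at all
  expect_lt(nrow(ev[!duplicated(ev$record_id), ]), nrow(st$records))
})

test_that("synthetic studies round-trip through the CSV readers", {
  st <- small_study(seed = 31, n_days = 90, n_children = 2000,
                    n_locations = 3)
  dir <- withr::local_tempdir()
  write_sim_study(st, dir)
  rec2 <- read_health_records(file.path(dir, "records.csv"))
  expect_equal(nrow(rec2), nrow(st$records))
  expect_equal(rec2$visit_date, st$records$visit_date)
  st2 <- read_exposure(file.path(dir, "exposure.csv"))
  expect_equal(st2$pm25, st$exposure$pm25, tolerance = 1e-12)
  expect_equal(st2$dates, st$exposure$dates)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$lag_coeffs, st$truth$lag_coeffs)
})

test_that("config validation rejects malformed parameters", {
  expect_error(sim_config(n_days = 30), "n_days")
  expect_error(sim_config(pm_params = list(bogus = 1)), "unknown simulation")
  expect_error(sim_config(pm_params = list(ar_phi = 1.2)), "ar_phi")
  expect_error(sim_truth(lag_coeffs = rep(0, 10)), "15")
})
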