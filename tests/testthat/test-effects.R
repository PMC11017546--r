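# hand-made converged fit object for pure lincom arithmetic
fake_fit <- function(beta, vc) {
  structure(list(coefficients = beta, vcov = vc, loglik = 0,
                 loglik_null = 0, n_strata = 10L, n_obs = 45L,
                 iterations = 1L, converged = TRUE,
                 diagnostics = list(separation = FALSE)),
            class = "cclogit")
}

test_that("percentile cutoffs follow order-statistic interpolation", {
  expect_equal(unname(temperature_percentiles(0:100)), c(15, 50, 85))
  expect_warning(q <- temperature_percentiles(rep(3, 10)),
                 "not strictly increasing")
  expect_equal(unname(q), c(3, 3, 3))
  expect_error(temperature_percentiles(c(1, 2)), "at least 3")
  # independent oracle: linear interpolation between closest order stats
  set.seed(77)
  for (rep in 1:5) {
    x <- rnorm(50 + rep, 5, 8)
    got <- temperature_percentiles(x)
    srt <- sort(x)
    n <- length(srt)
    oracle <- vapply(c(0.15, 0.5, 0.85), function(p) {
      h <- (n - 1) * p + 1
      lo <- floor(h)
      srt[lo] + (h - lo) * (srt[min(lo + 1, n)] - srt[lo])
    }, numeric(1))
    expect_equal(unname(got), oracle, tolerance = 1e-12)
  }
})

test_that("model specs validate windows against lag structure", {
  expect_identical(length(default_windows("cumulative")), 15L)
  expect_identical(length(default_windows("weekly_avg")), 9L)
  expect_identical(default_windows("weekly_avg")[[9]], c(8L, 14L))
  expect_error(model_spec("x", "weekly_avg", lag_windows = list(c(0, 5))),
               "inconsistent")
  expect_error(model_spec("x", "cumulative", lag_windows = list(c(1, 5))),
               "inconsistent")
  expect_error(model_spec("x", "single", temperature_lag = 7), "0..6")
})

test_that("design matrices carry the model spec's covariates and drop strata whole", {
  st <- small_study(seed = 5)
  ev <- build_case_events(st$records)
  ms <- build_matched_sets(ev[ev$category == "URTI", ][1:40, ])
  des0 <- build_design(ms, st$exposure,
                       model_spec("URTI", "single",
                                  lag_windows = list(c(0, 0))),
                       window = c(0, 0))
  expect_identical(colnames(des0$X), "pm")
  expect_equal(des0$X[, "pm"],
               lag_single(st$exposure, des0$data$location_id,
                          des0$data$date, 0))
  dtemp <- build_design(ms, st$exposure,
                        model_spec("URTI", "cumulative",
                                   modifier = "temperature"),
                        window = c(0, 13))
  expect_identical(colnames(dtemp$X), c("pm", "tmax", "pm_tmax"))
  expect_equal(dtemp$X[, "pm_tmax"],
               unname(dtemp$X[, "pm"] * dtemp$X[, "tmax"]))
  dseas <- build_design(ms, st$exposure,
                        model_spec("URTI", "weekly_avg",
                                   modifier = "season"),
                        window = c(7, 13))
  expect_identical(colnames(dseas$X),
                   c("pm", "pm_spring", "pm_summer", "pm_fall"))
  # no season main effects anywhere
  expect_false(any(colnames(dseas$X) %in%
                     c("winter", "spring", "summer", "fall")))
  # season-stratified PM columns are zero off-season
  seas <- season_of(dseas$data$date)
  expect_true(all(dseas$X[seas != "spring", "pm_spring"] == 0))
  # events in the first month lack 14-day history: dropped whole, counted
  early <- build_matched_sets(ev[ev$category == "URTI", ])
  dd <- build_design(early, st$exposure,
                     model_spec("URTI", "cumulative"), window = c(0, 14))
  expect_identical(dd$n_strata + dd$n_dropped,
                   length(unique(early$stratum_id)))
  expect_true(dd$n_dropped > 0)
  kept_per_stratum <- table(dd$stratum)
  expect_true(all(kept_per_stratum %in% 4:5))
})

test_that("lincom arithmetic is exact in closed form", {
  vc <- matrix(c(0.04, 0.01, 0.01, 0.09), 2,
               dimnames = list(c("pm", "pm_tmax"), c("pm", "pm_tmax")))
  f <- fake_fit(c(pm = 0.2, pm_tmax = -0.05), vc)
  # unit vector reproduces the coefficient's own Wald summary
  one <- lincom(f, c(pm = 1))
  expect_equal(one$or, exp(0.2))
  expect_equal(one$se, 0.2)
  expect_equal(one$ci_lo, exp(0.2 - stats::qnorm(0.975) * 0.2))
  # general combination
  w <- c(pm = 2, pm_tmax = 3)
  lc <- lincom(f, w)
  expect_equal(lc$log_or, 2 * 0.2 + 3 * -0.05)
  expect_equal(lc$se, sqrt(drop(t(c(2, 3)) %*% vc %*% c(2, 3))))
  # zero combination: null effect with degenerate interval
  z <- lincom(f, c(pm = 0))
  expect_equal(c(z$or, z$ci_lo, z$ci_hi, z$p_value), c(1, 1, 1, 1))
  expect_error(lincom(f, c(bogus = 1)), "unknown coefficient")
})

test_that("zero interaction collapses all temperature groups to the main OR", {
  vc <- diag(c(0.002, 0.001, 1e-9))
  dimnames(vc) <- list(c("pm", "tmax", "pm_tmax"),
                       c("pm", "tmax", "pm_tmax"))
  f <- fake_fit(c(pm = 0.01, tmax = 0.05, pm_tmax = 0), vc)
  dlm <- structure(list(
    spec = model_spec("URTI", "cumulative", lag_windows = list(c(0, 13)),
                      modifier = "temperature"),
    models = list(list(window = c(0, 13), fit = f, n_strata = 10L,
                       n_dropped = 0L, season_n = NULL)),
    cutoffs = c(colder = -0.7, median = 6.2, hotter = 20.7)),
    class = "dlm_fit")
  me <- marginal_effects(dlm)
  expect_identical(me$group, c("colder", "median", "hotter"))
  expect_equal(me$or, rep(exp(14 * 0.01), 3), tolerance = 1e-9)
})

test_that("delta-method intervals agree with a parametric bootstrap", {
  ins <- random_instance(91, n_strata = 120, n_cov = 2)
  fit <- cclogit_fit(ins$X, ins$stratum, ins$case)
  w <- c(1, 0.5)
  lc <- lincom(fit, w)
  set.seed(2024)
  L <- t(chol(vcov(fit)))
  draws <- coef(fit) + L %*% matrix(rnorm(2 * 2000), 2)
  boot <- exp(drop(t(w) %*% draws))
  bq <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  expect_lt(abs(lc$ci_lo - bq[1]) / bq[1], 0.02)
  expect_lt(abs(lc$ci_hi - bq[2]) / bq[2], 0.02)
})

test_that("season marginal ORs are invariant to the reference season", {
  st <- small_study(seed = 9, n_days = 400, n_children = 9000)
  ev <- build_case_events(st$records)
  ms <- build_matched_sets(ev[ev$category == "URTI", ])
  me_w <- marginal_effects(fit_dlm(ms, st$exposure,
    model_spec("URTI", "cumulative", lag_windows = list(c(0, 6)),
               modifier = "season", reference_season = "winter")))
  me_s <- marginal_effects(fit_dlm(ms, st$exposure,
    model_spec("URTI", "cumulative", lag_windows = list(c(0, 6)),
               modifier = "season", reference_season = "summer")))
  expect_equal(me_w$or, me_s$or, tolerance = 1e-10)
  expect_equal(me_w$ci_lo, me_s$ci_lo, tolerance = 1e-8)
  expect_identical(me_w$group, me_s$group)
})

test_that("per-window and joint estimates agree on interaction-free data", {
  tr <- sim_truth(lag_coeffs = c(rep(0.006, 7), rep(0, 8)),
                  temp_interaction = 0,
                  category_mix = c(asthma = 0, LRTI = 0, URTI = 1,
                                   other = 0))
  cfg <- sim_config(n_locations = 25, n_days = 821, n_children = 4300,
                    seed = 314, truth = tr)
  st <- simulate_study(cfg)
  ev <- build_case_events(st$records)
  ms <- build_matched_sets(ev[ev$category == "URTI", ])
  pw <- fit_dlm(ms, st$exposure,
                model_spec("URTI", "cumulative",
                           lag_windows = list(c(0, 6))))
  me_pw <- marginal_effects(pw)
  jt <- fit_dlm(ms, st$exposure,
                model_spec("URTI", "cumulative",
                           lag_windows = list(c(0, 6)),
                           dlm_mode = "joint"))
  me_jt <- marginal_effects(jt)
  # the joint-mode window log-OR is the sum of its per-lag coefficients
  cf <- coef(jt$models[[1]]$fit)
  expect_equal(log(me_jt$or), sum(cf[paste0("pm_lag", 0:6)]),
               tolerance = 1e-10)
  # both target the same truth (7 x 0.006); agreement within Monte-Carlo
  # error of the joint estimate
  se_jt <- sqrt(drop(t(rep(1, 7)) %*%
                       vcov(jt$models[[1]]$fit)[1:7, 1:7] %*% rep(1, 7)))
  expect_lt(abs(log(me_jt$or) - log(me_pw$or)), 2 * se_jt)
  expect_equal(log(me_pw$or), 7 * 0.006, tolerance = 3 * se_jt)
})
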