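# shared fixtures, all built in code

# single-location store whose pm25 is 1, 2, ..., n on consecutive days
linear_store <- function(n = 20, start = "2018-08-01", location = "a",
                         tmax = 10) {
  exposure_store(data.frame(location_id = location,
                            date = as.Date(start) + seq_len(n) - 1,
                            pm25 = seq_len(n), tmax = tmax))
}

# store with arbitrary matrices on a date grid
matrix_store <- function(pm, tmax = pm * 0 + 10, start = "2018-01-01",
                         locations = sprintf("L%02d", seq_len(ncol(pm)))) {
  nd <- nrow(pm)
  exposure_store(data.frame(
    location_id = rep(locations, each = nd),
    date = rep(as.Date(start) + 0:(nd - 1), ncol(pm)),
    pm25 = as.vector(pm), tmax = as.vector(tmax)))
}

# n_strata 1:1 matched pairs with given case-minus-control differences on
# one covariate; control covariate 0
paired_design <- function(diffs) {
  n <- length(diffs)
  data.frame(stratum = rep(seq_len(n), each = 2),
             is_case = rep(c(1L, 0L), n),
             x = as.vector(rbind(diffs, 0)))
}

# random small conditional-logit instance (for oracle comparisons)
random_instance <- function(seed, n_strata = 10, n_cov = 1,
                            stratum_size = 4) {
  set.seed(seed)
  n <- n_strata * stratum_size
  X <- matrix(stats::rnorm(n * n_cov), n, n_cov,
              dimnames = list(NULL, paste0("x", seq_len(n_cov))))
  list(X = X,
       stratum = rep(seq_len(n_strata), each = stratum_size),
       case = rep(c(1L, rep(0L, stratum_size - 1)), n_strata))
}

# independent brute-force conditional log-likelihood over a grid of beta
# values (one column per candidate); no code shared with the Newton path
grid_loglik <- function(X, stratum, case, B) {
  eta <- X %*% B                                   # n x n_grid
  num <- eta[case == 1L, , drop = FALSE]
  ll <- colSums(num)
  for (s in unique(stratum)) {
    es <- eta[stratum == s, , drop = FALSE]
    m <- apply(es, 2, max)
    ll <- ll - (m + log(colSums(exp(sweep(es, 2, m)))))
  }
  ll
}

# two-stage dense grid-search maximizer of the conditional likelihood
grid_search_beta <- function(X, stratum, case, lim = 5) {
  p <- ncol(X)
  centre <- rep(0, p)
  width <- lim
  step <- if (p == 1) 0.01 else 0.1
  repeat {
    axes <- lapply(seq_len(p), function(j)
      seq(centre[j] - width, centre[j] + width, by = step))
    B <- t(as.matrix(expand.grid(axes)))
    ll <- grid_loglik(X, stratum, case, B)
    centre <- B[, which.max(ll)]
    if (step <= 2e-5) break
    width <- 2 * step
    step <- step / 20
  }
  centre
}

# small simulated study used by several pipeline tests
small_study <- function(seed = 42, n_days = 200, n_children = 6000,
                        n_locations = 5, truth = sim_truth(), ...) {
  simulate_study(sim_config(n_locations = n_locations, n_days = n_days,
                            n_children = n_children, seed = seed,
                            truth = truth, ...))
}

# recovery-study configuration: one outcome category, about 2000 strata
recovery_config <- function(seed) {
  sim_config(n_locations = 25, n_days = 821, n_children = 4300, seed = seed,
             truth = sim_truth(category_mix = c(asthma = 0, LRTI = 0,
                                                URTI = 1, other = 0)))
}

# fit the cumulative 0-13 x temperature model on one simulated study and
# return estimates, SEs and stratum count
recovery_fit <- function(seed) {
  st <- simulate_study(recovery_config(seed))
  ev <- build_case_events(st$records)
  ms <- build_matched_sets(ev[ev$category == "URTI", ])
  spec <- model_spec("URTI", "cumulative", lag_windows = list(c(0, 13)),
                     modifier = "temperature")
  m <- fit_dlm(ms, st$exposure, spec)$models[[1]]
  cf <- coef(m$fit)
  se <- sqrt(diag(vcov(m$fit)))
  c(b = cf[["pm"]], g = cf[["pm_tmax"]], se_b = se[["pm"]],
    se_g = se[["pm_tmax"]], n = m$n_strata,
    converged = as.numeric(m$fit$converged))
}

# one null replicate: zero truth, Wald p-value of the cumulative effect
null_replicate <- function(seed) {
  tr <- sim_truth(lag_coeffs = rep(0, 15), temp_interaction = 0,
                  category_mix = c(asthma = 0, LRTI = 0, URTI = 1,
                                   other = 0))
  cfg <- sim_config(n_locations = 10, n_days = 260, n_children = 8000,
                    seed = seed, truth = tr)
  st <- simulate_study(cfg)
  ev <- build_case_events(st$records)
  ms <- build_matched_sets(ev[ev$category == "URTI", ])
  spec <- model_spec("URTI", "cumulative", lag_windows = list(c(0, 13)))
  me <- marginal_effects(fit_dlm(ms, st$exposure, spec))
  c(p = me$p_value, log_or = log(me$or))
}
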