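test_that("conditional log-likelihood matches hand-computable cases", {
  # uniform probabilities at beta = 0: one stratum of 5 rows
  X <- matrix(rnorm(5), 5, 1)
  out <- conditional_loglik(0, X, rep(1, 5), c(1, 0, 0, 0, 0))
  expect_equal(out$loglik, log(1 / 5))
  # no within-stratum contrast: loglik flat, gradient zero everywhere
  Xc <- matrix(rep(c(1, 3), each = 3), 6, 1)
  s <- rep(1:2, each = 3)
  cs <- rep(c(1, 0, 0), 2)
  for (b in c(-2, 0, 1.7)) {
    o <- conditional_loglik(b, Xc, s, cs)
    expect_equal(o$loglik, 2 * log(1 / 3))
    expect_equal(o$gradient, 0)
  }
  expect_error(conditional_loglik(Inf, X, rep(1, 5), c(1, 0, 0, 0, 0)),
               "non-finite")
})

test_that("analytic gradient and hessian agree with finite differences", {
  ins <- random_instance(7, n_strata = 6, n_cov = 2)
  beta <- c(0.4, -0.8)
  out <- conditional_loglik(beta, ins$X, ins$stratum, ins$case)
  h <- 1e-6
  for (j in 1:2) {
    e <- numeric(2); e[j] <- h
    up <- conditional_loglik(beta + e, ins$X, ins$stratum, ins$case)
    dn <- conditional_loglik(beta - e, ins$X, ins$stratum, ins$case)
    expect_equal(unname(out$gradient[j]),
                 (up$loglik - dn$loglik) / (2 * h), tolerance = 1e-5)
    expect_equal(out$hessian[, j], (up$gradient - dn$gradient) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("1:1 strata reduce to the paired logit on covariate differences", {
  set.seed(11)
  n <- 15
  d <- data.frame(stratum = rep(1:n, each = 2),
                  is_case = rep(c(1L, 0L), n),
                  x = rnorm(2 * n), z = rnorm(2 * n))
  X <- as.matrix(d[, c("x", "z")])
  dx <- X[d$is_case == 1, ] - X[d$is_case == 0, ]
  for (b in list(c(0, 0), c(0.5, -1), c(-2, 0.3))) {
    ll <- conditional_loglik(b, X, d$stratum, d$is_case)$loglik
    expect_equal(ll, sum(stats::plogis(drop(dx %*% b), log.p = TRUE)))
  }
})

test_that("the paired-difference toy has the closed-form estimate log 2", {
  d <- paired_design(c(1, 1, -1))
  f <- cclogit(is_case ~ x + strata(stratum), d)
  expect_true(f$converged)
  expect_equal(unname(coef(f)), log(2), tolerance = 1e-9)
  expect_equal(unname(exp(coef(f))), 2, tolerance = 1e-9)
})

test_that("Newton estimates agree with a dense grid-search oracle", {
  for (seed in 1:6) {
    n_cov <- 1 + seed %% 2
    ins <- random_instance(seed, n_strata = 10, n_cov = n_cov)
    fit <- cclogit_fit(ins$X, ins$stratum, ins$case)
    expect_true(fit$converged)
    oracle <- grid_search_beta(ins$X, ins$stratum, ins$case)
    expect_lt(max(abs(unname(coef(fit)) - unname(oracle))), 1e-4)
  }
})

test_that("estimates match an established survival implementation", {
  skip_if_not_installed("survival")
  set.seed(23)
  n <- 60
  d <- data.frame(s = rep(1:n, each = 4),
                  y = rep(c(1, 0, 0, 0), n),
                  a = rnorm(4 * n), b = rnorm(4 * n))
  f1 <- cclogit(y ~ a + b + strata(s), d)
  f2 <- survival::coxph(survival::Surv(rep(1, 4 * n), d$y) ~ a + b +
                          survival::strata(s), data = d)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(unname(vcov(f1)), unname(vcov(f2)), tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik[2], tolerance = 1e-8)
})

test_that("stratum-shift invariance and scale equivariance hold", {
  ins <- random_instance(31, n_strata = 12, n_cov = 1)
  f0 <- cclogit_fit(ins$X, ins$stratum, ins$case)
  # add a different constant to every stratum's rows
  shift <- as.numeric(ins$stratum) * 3.3
  f1 <- cclogit_fit(ins$X + shift, ins$stratum, ins$case)
  expect_equal(coef(f0), coef(f1), tolerance = 1e-8)
  expect_equal(vcov(f0), vcov(f1), tolerance = 1e-6)
  expect_equal(f0$loglik, f1$loglik, tolerance = 1e-10)
  # rescale the covariate by s: beta and SE scale by 1/s
  sc <- 4
  f2 <- cclogit_fit(ins$X * sc, ins$stratum, ins$case)
  expect_equal(unname(coef(f2)), unname(coef(f0)) / sc, tolerance = 1e-8)
  expect_equal(sqrt(diag(vcov(f2))), sqrt(diag(vcov(f0))) / sc,
               tolerance = 1e-6)
})

test_that("degenerate designs fail loudly", {
  # no within-stratum variation in one covariate
  d <- data.frame(stratum = rep(1:3, each = 2), is_case = rep(c(1, 0), 3),
                  x = rep(c(0, 1, 2), each = 2))
  expect_error(cclogit(is_case ~ x + strata(stratum), d),
               "no within-stratum variation")
  # monotone likelihood: case always the larger exposure
  sep <- paired_design(rep(1, 8))
  expect_warning(f <- cclogit(is_case ~ x + strata(stratum), sep),
                 "separation")
  expect_false(f$converged)
  expect_true(f$diagnostics$separation)
  expect_error(lincom(f, c(x = 1)), "converged")
  # malformed strata
  expect_error(cclogit_fit(matrix(1:4), c(1, 1, 2, 2), c(1, 1, 1, 0)),
               "exactly one case")
})

test_that("summary, confint and predict expose Wald inference", {
  ins <- random_instance(5, n_strata = 25, n_cov = 2)
  fit <- cclogit_fit(ins$X, ins$stratum, ins$case)
  sm <- summary(fit)
  expect_identical(dim(sm$coefficients), c(2L, 5L))
  se <- sqrt(diag(vcov(fit)))
  ci <- confint(fit)
  expect_equal(unname(ci[, 1]), unname(coef(fit) - 1.959964 * se),
               tolerance = 1e-6)
  d <- data.frame(stratum = ins$stratum, is_case = ins$case,
                  x1 = ins$X[, 1], x2 = ins$X[, 2])
  f2 <- cclogit(is_case ~ x1 + x2 + strata(stratum), d)
  pr <- predict(f2, d, type = "prob")
  expect_equal(unname(drop(rowsum(pr, ins$stratum))), rep(1, 25))
  expect_equal(predict(f2, d, type = "lp"),
               drop(ins$X %*% coef(f2)), tolerance = 1e-10)
})
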