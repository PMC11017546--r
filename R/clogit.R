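#' Exact conditional log-likelihood for 1:m matched sets
#'
#' For stratum \eqn{s} with case row \eqn{i} and rows \eqn{j \in s}, the
#' contribution is \eqn{\log[\exp(x_i \beta) / \sum_j \exp(x_j \beta)]}.
#' With exactly one case per stratum this exact conditional likelihood
#' coincides with the Breslow, Efron and exact partial likelihoods, so no
#' tie handling is involved. Evaluation subtracts the within-stratum maximum
#' of the linear predictor before exponentiating.
#'
#' @param beta numeric coefficient vector (finite).
#' @param X numeric model matrix, one row per stratum-day, no intercept.
#' @param stratum stratum identifier per row (any type; coerced to factor).
#' @param case 0/1 (or logical) case indicator, exactly one 1 per stratum.
#' @return list with \code{loglik} (scalar), \code{gradient} (length p) and
#'   \code{hessian} (p x p, the second-derivative matrix, negative definite
#'   away from degeneracy).
#' @export
conditional_loglik <- function(beta, X, stratum, case) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (length(beta) != p) stop("length(beta) != ncol(X)", call. = FALSE)
  if (any(!is.finite(beta))) stop("non-finite beta", call. = FALSE)
  s <- as.integer(factor(stratum))
  case <- as.integer(case)
  if (!all(rowsum(case, s) == 1L))
    stop("each stratum must contain exactly one case row", call. = FALSE)
  eta <- drop(X %*% beta)
  mx <- as.vector(tapply(eta, s, max))
  w <- exp(eta - mx[s])
  denom <- drop(rowsum(w, s))
  prob <- as.vector(w / denom[s])
  ll <- sum((eta - mx[s])[case == 1L]) - sum(log(denom))
  grad <- drop(crossprod(X, case - prob))
  xbar <- rowsum(prob * X, s)                # per-stratum E[x]
  hess <- -(crossprod(X, prob * X) - crossprod(xbar))
  list(loglik = ll, gradient = grad, hessian = hess)
}

# error unless every covariate varies within at least one stratum
.check_identifiable <- function(X, s) {
  cn <- colnames(X)
  ns <- drop(rowsum(rep(1, length(s)), s))
  for (j in seq_len(ncol(X))) {
    m <- drop(rowsum(X[, j], s)) / ns
    if (all(abs(X[, j] - m[s]) < 1e-12))
      stop("covariate '", cn[j],
           "' has no within-stratum variation (not identifiable in a ",
           "conditional logistic model)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit conditional logistic regression by Newton-Raphson
#'
#' Maximizes the exact conditional likelihood of [conditional_loglik()] with
#' analytic gradient and Hessian, step-halving when a step fails to improve
#' the log-likelihood, and observed-information covariance (inverse negative
#' Hessian at the optimum). Deterministic: starts at \code{beta = 0}.
#'
#' This is the computational engine behind [cclogit()]; call it directly
#' when the design matrix is already assembled (as [fit_dlm()] does).
#'
#' @inheritParams conditional_loglik
#' @param grad_tol convergence when \code{max(abs(gradient)) < grad_tol}.
#' @param step_tol convergence when \code{max(abs(step)) < step_tol}.
#' @param max_iter maximum Newton iterations.
#' @param beta_bound monotone-likelihood (separation) guard: if any
#'   \code{abs(beta)} exceeds this bound the fit is flagged non-converged.
#' @return object of class \code{"cclogit"}; see [cclogit()].
#' @export
cclogit_fit <- function(X, stratum, case, grad_tol = 1e-8, step_tol = 1e-10,
                        max_iter = 50L, beta_bound = 15) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  s <- as.integer(factor(stratum))
  case <- as.integer(case)
  if (!all(rowsum(case, s) == 1L))
    stop("each stratum must contain exactly one case row", call. = FALSE)
  ns <- tabulate(s)
  if (any(ns < 2L))
    stop("stratum with fewer than 2 rows", call. = FALSE)
  .check_identifiable(X, s)

  p <- ncol(X)
  beta <- rep(0, p)
  cur <- conditional_loglik(beta, X, s, case)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$hessian, -cur$gradient),
                     error = function(e) NULL)
    if (is.null(step)) {  # singular Hessian: damped gradient ascent fallback
      step <- cur$gradient / max(1, max(abs(cur$gradient)))
    }
    # step-halving on the log-likelihood
    lam <- 1
    repeat {
      cand <- beta + lam * step
      new <- conditional_loglik(cand, X, s, case)
      if (new$loglik >= cur$loglik - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    delta <- cand - beta
    beta <- cand
    cur <- new
    if (max(abs(beta)) > beta_bound) { separation <- TRUE; break }
    if (max(abs(cur$gradient)) < grad_tol || max(abs(delta)) < step_tol) {
      # one polishing step so equivariant re-parameterizations agree to
      # near machine precision
      pol <- tryCatch(solve(cur$hessian, -cur$gradient),
                      error = function(e) NULL)
      if (!is.null(pol)) {
        cand <- beta + pol
        new <- conditional_loglik(cand, X, s, case)
        if (is.finite(new$loglik) && new$loglik >= cur$loglik - 1e-12) {
          beta <- cand; cur <- new
        }
      }
      converged <- TRUE
      break
    }
  }
  if (separation)
    warning("monotone likelihood / separation suspected: |beta| exceeded ",
            beta_bound, "; estimates are not interpretable", call. = FALSE)
  if (!converged && !separation)
    warning("Newton-Raphson did not converge in ", max_iter, " iterations",
            call. = FALSE)
  vcov <- if (converged) {
    tryCatch(solve(-cur$hessian), error = function(e)
      matrix(NA_real_, p, p))
  } else matrix(NA_real_, p, p)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  ll0 <- conditional_loglik(rep(0, p), X, s, case)$loglik
  structure(list(
    coefficients = beta, vcov = vcov, loglik = cur$loglik, loglik_null = ll0,
    n_strata = length(unique(s)), n_obs = nrow(X), iterations = iter,
    converged = converged,
    diagnostics = list(separation = separation,
                       max_abs_gradient = max(abs(cur$gradient)))),
    class = "cclogit")
}

#' Stratum marker for model formulas
#'
#' Used inside a [cclogit()] formula to mark the matched-set identifier,
#' e.g. \code{case ~ pm + strata(stratum_id)}.
#'
#' @param x stratum identifier variable.
#' @return \code{x} unchanged.
#' @export
strata <- function(x) x

#' Conditional logistic regression for case-crossover data
#'
#' Formula front end to [cclogit_fit()]. The formula must contain exactly one
#' \code{strata()} term naming the matched-set identifier; no intercept is
#' fitted (it is not identifiable conditionally).
#'
#' @param formula model formula, e.g.
#'   \code{is_case ~ pm + tmax + pm:tmax + strata(stratum_id)}.
#' @param data data.frame containing the variables.
#' @param ... passed to [cclogit_fit()] (tolerances, iteration and
#'   separation bounds).
#' @return object of class \code{"cclogit"} with components
#'   \code{coefficients}, \code{vcov}, \code{loglik}, \code{loglik_null},
#'   \code{n_strata}, \code{n_obs}, \code{iterations}, \code{converged} and
#'   \code{diagnostics}. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{vcov}, \code{logLik}, \code{confint}, \code{nobs},
#'   \code{predict}.
#' @examples
#' d <- data.frame(stratum = rep(1:3, each = 2),
#'                 is_case = rep(c(1, 0), 3),
#'                 x = c(1, 0, 1, 0, 0, 1))
#' f <- cclogit(is_case ~ x + strata(stratum), d)
#' coef(f)  # log 2
#' @export
cclogit <- function(formula, data, ...) {
  tm <- stats::terms(formula, specials = "strata", data = data)
  strat_ix <- attr(tm, "specials")$strata
  if (length(strat_ix) != 1L)
    stop("formula must contain exactly one strata() term", call. = FALSE)
  mf <- stats::model.frame(tm, data = data, na.action = stats::na.fail)
  stratum <- mf[[strat_ix]]  # specials index counts the response, as mf does
  # drop the strata term (located among the term labels) before building X
  drop_pos <- grep("^strata\\(", attr(tm, "term.labels"))
  tm2 <- stats::drop.terms(tm, drop_pos, keep.response = TRUE)
  X <- stats::model.matrix(tm2, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  y <- stats::model.response(mf)
  fit <- cclogit_fit(X, stratum, y, ...)
  fit$call <- match.call()
  fit$formula <- formula
  fit
}

#' @export
coef.cclogit <- function(object, ...) object$coefficients

#' @export
vcov.cclogit <- function(object, ...) object$vcov

#' @export
logLik.cclogit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_strata, class = "logLik")
}

#' @export
nobs.cclogit <- function(object, ...) object$n_obs

#' @export
print.cclogit <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Conditional logistic regression (exact conditional likelihood)\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("%d strata, %d rows; logLik = %.4f (null %.4f); %s in %d iter\n",
              x$n_strata, x$n_obs, x$loglik, x$loglik_null,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.cclogit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- cbind(coef = object$coefficients, `exp(coef)` = exp(object$coefficients),
               se = se, z = z, `Pr(>|z|)` = p)
  structure(list(coefficients = tab, loglik = object$loglik,
                 loglik_null = object$loglik_null, n_strata = object$n_strata,
                 converged = object$converged, call = object$call),
            class = "summary.cclogit")
}

#' @export
print.summary.cclogit <- function(x, ...) {
  cat("Conditional logistic regression\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("n_strata = %d; logLik = %.4f; LR chi2 vs null = %.3f\n",
              x$n_strata, x$loglik, 2 * (x$loglik - x$loglik_null)))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
confint.cclogit <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  se <- sqrt(diag(object$vcov))
  q <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(cf - q * se, cf + q * se)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out[parm, , drop = FALSE]
}

#' Predict from a conditional logistic fit
#'
#' @param object a \code{"cclogit"} fit.
#' @param newdata data.frame with the model covariates (plus the stratum
#'   variable when \code{type = "prob"}).
#' @param type \code{"lp"} for the linear predictor, \code{"prob"} for the
#'   within-stratum conditional case probabilities (softmax of the linear
#'   predictor over each stratum's rows).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.cclogit <- function(object, newdata, type = c("lp", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(object$formula))
    stop("predict needs a fit created through the formula interface",
         call. = FALSE)
  tm <- stats::terms(object$formula, specials = "strata", data = newdata)
  drop_pos <- grep("^strata\\(", attr(tm, "term.labels"))
  tm2 <- stats::delete.response(stats::drop.terms(tm, drop_pos,
                                                  keep.response = TRUE))
  mf <- stats::model.frame(stats::delete.response(tm), data = newdata,
                           na.action = stats::na.fail)
  X <- stats::model.matrix(tm2, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  eta <- unname(drop(X %*% object$coefficients[colnames(X)]))
  if (type == "lp") return(eta)
  s <- as.integer(factor(mf[[grep("^strata\\(", names(mf))[1]]]))
  mx <- as.vector(tapply(eta, s, max))
  w <- exp(eta - mx[s])
  as.vector(w / drop(rowsum(w, s))[s])
}
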