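#' Maximum likelihood estimation for the IEP distribution
#'
#' Fits IEP(`alpha`, `lambda`) to a sample of strictly positive observations
#' by Newton-Raphson on the analytic score, iterating in
#' `(log alpha, log lambda)` so positivity never has to be imposed as a
#' constraint.  Steps are safeguarded by halving until the log-likelihood
#' increases, and directions that are not ascent directions (indefinite
#' Hessian far from the optimum) are replaced by the scaled gradient.  If
#' Newton-Raphson fails to drive the score below `tol`, a derivative-free
#' Nelder-Mead pass over the log-likelihood is run and Newton-Raphson is
#' restarted from its solution; the `method` field records which path
#' produced the estimate.
#'
#' The default starting point is `alpha = 1` and
#' `lambda = median(x) * log(1 - log(0.5))`, which inverts the closed-form
#' median at `alpha = 1` and is therefore scale-aware.
#'
#' @param x positive observations (at least 3, not all identical).
#' @param start optional length-2 vector `c(alpha, lambda)` of starting
#'   values.
#' @param tol convergence tolerance on the infinity norm of the score.
#' @param max_iter maximum Newton iterations per pass.
#'
#' @return An object of class `"iep_fit"`: a list with `coefficients`
#'   (named `alpha`, `lambda`), `loglik`, `converged`, `iterations`,
#'   `score`, `info` (observed Fisher information, the negated Hessian at
#'   the estimate), `vcov` (its inverse), `n`, `x` (the data, kept for
#'   bootstrap resampling), and `method`.  `coef`, `logLik`, `vcov`,
#'   `confint` (Wald) and `print` methods are provided.  Non-convergence is
#'   reported explicitly through `converged = FALSE` (with `info`/`vcov`
#'   set to `NA`), never as a silently bad estimate.
#'
#' @examples
#' fit <- iep_mle(iep_region("AFR")$cfr)
#' coef(fit)        # matches the published (0.9993, 0.6609)
#' confint(fit)
#' @seealso [iep_boot_ci()] for percentile bootstrap intervals,
#'   [iep_ks_test()] for goodness of fit.
#' @export
iep_mle <- function(x, start = NULL, tol = 1e-8, max_iter = 100L) {
  .check_positive(x)
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 observations to fit two parameters", call. = FALSE)
  out <- list(n = n, x = x)
  class(out) <- "iep_fit"
  if (length(unique(x)) == 1L) {
    out$converged <- FALSE
    out$method <- "degenerate"
    out$coefficients <- c(alpha = NA_real_, lambda = NA_real_)
    out$loglik <- NA_real_
    out$iterations <- 0L
    warning("degenerate sample: all observations identical; fit flagged as failed")
    return(out)
  }
  if (is.null(start)) start <- c(1, median(x) * log1p(-log(0.5)))

  nr <- .newton_log(start,
                    fn   = function(a, l) .loglik_safe(x, a, l),
                    grad = function(a, l) .score_safe(x, a, l),
                    hess = function(a, l) .hess_safe(x, a, l),
                    tol = tol, max_iter = max_iter)
  method <- "newton"
  if (!nr$converged) {
    ## Nelder-Mead rescue; if the user's start is infeasible (likelihood
    ## -Inf, e.g. the overflow region), restart from the default instead
    nm_start <- if (is.finite(.loglik_safe(x, start[1], start[2]))) start
                else c(1, median(x) * log1p(-log(0.5)))
    nm <- optim(log(nm_start),
                function(th) -.loglik_safe(x, exp(th[1]), exp(th[2])),
                method = "Nelder-Mead",
                control = list(maxit = 2000L, reltol = 1e-14))
    nr2 <- .newton_log(exp(nm$par),
                       fn   = function(a, l) .loglik_safe(x, a, l),
                       grad = function(a, l) .score_safe(x, a, l),
                       hess = function(a, l) .hess_safe(x, a, l),
                       tol = tol, max_iter = max_iter)
    if (nr2$converged || nr2$value >= nr$value) {
      nr <- nr2
      method <- "nelder-mead+newton"
    }
  }

  est <- nr$par
  out$coefficients <- c(alpha = est[1], lambda = est[2])
  out$loglik <- nr$value
  out$converged <- nr$converged
  out$iterations <- nr$iterations
  out$score <- nr$grad
  out$method <- method
  if (nr$converged) {
    oi <- tryCatch(iep_observed_info(x, est[1], est[2]),
                   error = function(e) NULL)
    if (is.null(oi)) {
      out$converged <- FALSE
    } else {
      out$info <- oi$info
      out$vcov <- oi$vcov
    }
  }
  if (!out$converged)
    warning("iep_mle did not converge (score norm ",
            format(max(abs(nr$grad))), "); estimate flagged as failed")
  out
}

## guarded derivative evaluations for the optimiser (no validation, no
## third partials; overflow surfaces as NA which .newton_log treats as
## a failed step)
.score_safe <- function(x, a, l) {
  if (!is.finite(a) || !is.finite(l) || a <= 0 || l <= 0)
    return(c(NA_real_, NA_real_))
  s <- log(l) - log(x)
  t <- exp(a * s)
  if (anyNA(t) || any(t > 709)) return(c(NA_real_, NA_real_))
  et <- exp(t)
  n <- length(x)
  g <- t * (1 - et)
  c(n / a + sum(s) + sum(s * g), n * a / l + (a / l) * sum(g))
}
.hess_safe <- function(x, a, l) {
  if (!is.finite(a) || !is.finite(l) || a <= 0 || l <= 0)
    return(matrix(NA_real_, 2, 2))
  s <- log(l) - log(x)
  t <- exp(a * s)
  if (anyNA(t) || any(t > 709)) return(matrix(NA_real_, 2, 2))
  et <- exp(t)
  n <- length(x)
  g <- t * (1 - et)
  B <- t * (1 - et - t * et)
  L11 <- -n / a^2 + sum(s^2 * B)
  L12 <- n / l + (sum(g) + a * sum(s * B)) / l
  L22 <- -(a / l^2) * (n + sum(g)) + (a^2 / l^2) * sum(B)
  matrix(c(L11, L12, L12, L22), 2L, 2L)
}

## Safeguarded Newton ascent over th = log(par) for positive 2-parameter
## objectives.  fn/grad/hess take the ORIGINAL-scale parameters; the chain
## rule for the log reparameterisation is applied here.  Convergence is on
## the infinity norm of the original-scale gradient.
.newton_log <- function(start, fn, grad, hess, tol = 1e-8, max_iter = 100L) {
  th <- log(unname(start))
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    a <- exp(th[1]); l <- exp(th[2])
    g0 <- grad(a, l)
    if (all(is.finite(g0)) && max(abs(g0)) < tol) {
      return(list(par = c(a, l), value = fn(a, l), grad = g0,
                  converged = TRUE, iterations = it))
    }
    H0 <- hess(a, l)
    if (!all(is.finite(g0)) || !all(is.finite(H0))) break
    ## transformed gradient and Hessian
    g <- c(a * g0[1], l * g0[2])
    H <- matrix(c(a^2 * H0[1, 1] + a * g0[1], a * l * H0[1, 2],
                  a * l * H0[1, 2], l^2 * H0[2, 2] + l * g0[2]), 2L, 2L)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step)) || sum(g * step) >= 0)
      step <- -g / max(1, sqrt(sum(g^2)))   # fall back to gradient ascent
    f0 <- fn(a, l)
    h <- 1; moved <- FALSE
    for (k in 1:40) {
      thn <- th - h * step
      fnv <- fn(exp(thn[1]), exp(thn[2]))
      if (is.finite(fnv) && fnv > f0) { moved <- TRUE; break }
      h <- h / 2
    }
    if (!moved) {
      ## flat to machine precision along the search direction: accept the
      ## full step if the objective does not deteriorate, else give up
      thn <- th - step
      fnv <- fn(exp(thn[1]), exp(thn[2]))
      if (!is.finite(fnv) || fnv < f0 - 1e-8) break
    }
    th <- thn
  }
  a <- exp(th[1]); l <- exp(th[2])
  g0 <- grad(a, l)
  conv <- all(is.finite(g0)) && max(abs(g0)) < tol
  list(par = c(a, l), value = fn(a, l), grad = g0,
       converged = conv, iterations = iterations)
}

## Lean fitter for simulation loops: no input validation, no S3 baggage.
## Returns c(alpha, lambda) or NULL on failure.
.fit_fast <- function(x, tol = 1e-8, max_iter = 60L) {
  start <- c(1, median(x) * log1p(-log(0.5)))
  nr <- .newton_log(start,
                    fn   = function(a, l) .loglik_safe(x, a, l),
                    grad = function(a, l) .score_safe(x, a, l),
                    hess = function(a, l) .hess_safe(x, a, l),
                    tol = tol, max_iter = max_iter)
  if (!nr$converged) {
    nm <- tryCatch(
      optim(log(start), function(th) -.loglik_safe(x, exp(th[1]), exp(th[2])),
            method = "Nelder-Mead", control = list(maxit = 1000L)),
      error = function(e) NULL)
    if (is.null(nm)) return(NULL)
    nr <- .newton_log(exp(nm$par),
                      fn   = function(a, l) .loglik_safe(x, a, l),
                      grad = function(a, l) .score_safe(x, a, l),
                      hess = function(a, l) .hess_safe(x, a, l),
                      tol = tol, max_iter = max_iter)
    if (!nr$converged) return(NULL)
  }
  nr$par
}

#' Observed Fisher information and variance-covariance matrix
#'
#' Negated analytic Hessian of the IEP log-likelihood at `(alpha, lambda)`
#' (normally the MLE) and its inverse, the asymptotic variance-covariance
#' matrix of the estimator.
#'
#' @inheritParams iep_loglik
#' @return list with `info` (2x2 observed information) and `vcov` (its
#'   inverse).  An error is raised if the information matrix is not
#'   positive definite, i.e. the supplied point is not a local maximum.
#' @export
iep_observed_info <- function(x, alpha, lambda) {
  info <- -iep_derivs(x, alpha, lambda)$hessian
  if (info[1, 1] <= 0 || det(info) <= 0)
    stop("observed information is not positive definite at (",
         format(alpha), ", ", format(lambda),
         "): not a local maximum", call. = FALSE)
  list(info = info, vcov = solve(info))
}

#' @export
coef.iep_fit <- function(object, ...) object$coefficients

#' @export
logLik.iep_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' @export
vcov.iep_fit <- function(object, ...) object$vcov

#' Wald (asymptotic normal) confidence intervals
#'
#' Intervals `estimate -/+ z * sqrt(var)` from the inverse observed
#' information.  Bounds are reported untruncated: a lower bound can be
#' negative even though the parameters are positive, which is exactly the
#' small-sample undercoverage the bootstrap interval addresses.
#'
#' @param object a converged [iep_mle()] fit.
#' @param parm ignored; both parameters are always reported.
#' @param level confidence level in (0, 1).
#' @param ... unused.
#' @return data frame with columns `parameter`, `lower`, `upper`, `level`,
#'   `method`.
#' @export
confint.iep_fit <- function(object, parm, level = 0.95, ...) {
  if (!isTRUE(object$converged))
    stop("confidence intervals require a converged fit", call. = FALSE)
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)", call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  est <- object$coefficients
  se <- sqrt(diag(object$vcov))
  data.frame(parameter = c("alpha", "lambda"),
             lower = est - z * se, upper = est + z * se,
             level = level, method = "wald", row.names = NULL)
}

#' @export
print.iep_fit <- function(x, digits = 4L, ...) {
  cat("Inverse Exponential Power fit (n =", x$n, ")\n")
  if (!isTRUE(x$converged)) {
    cat("  FAILED to converge (method:", x$method, ")\n")
    return(invisible(x))
  }
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  cat(sprintf("  alpha  = %.*f  (se %.*f)\n", digits, est[1], digits, se[1]))
  cat(sprintf("  lambda = %.*f  (se %.*f)\n", digits, est[2], digits, se[2]))
  cat(sprintf("  log-likelihood = %.*f  [%s, %d iterations]\n",
              digits, x$loglik, x$method, x$iterations))
  invisible(x)
}
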