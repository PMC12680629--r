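#' Bayes estimates by the Tierney-Kadane approximation
#'
#' Laplace approximation applied separately to the numerator and
#' denominator of the posterior-mean ratio.  With
#' \eqn{\eta(\theta) = [\ell(\theta) + \rho(\theta)]/n} (scaled log
#' posterior kernel) and
#' \eqn{\eta^*(\theta) = \log(u(\theta))/n + \eta(\theta)}, the estimate of
#' `u` under squared-error loss is
#' \deqn{\hat u = \sqrt{\det\Sigma^* / \det\Sigma}\;
#'   \exp\{n[\eta^*(\hat\theta^*) - \eta(\hat\theta)]\},}
#' where the hatted points maximise the respective surfaces and
#' \eqn{\Sigma}, \eqn{\Sigma^*} are the inverses of the negated Hessians
#' there.  Taking `u = alpha` and `u = lambda` gives the two parameter
#' estimates; the approximation error is `O(1/n^2)`.
#'
#' Both optimisations run the same safeguarded Newton ascent as
#' [iep_mle()] (log-parameter coordinates, analytic gradients and
#' Hessians), started at the MLE, whose maximiser the posterior mode
#' perturbs only slightly.
#'
#' @param x positive observations (at least 3).
#' @param prior an [iep_prior()].
#' @param fit optional converged [iep_mle()] fit of `x`, used as the
#'   starting point.
#' @return named vector `c(alpha, lambda)`.
#' @examples
#' iep_tk(iep_region("AFR")$cfr)   # (0.9645, 0.6695) under default priors
#' @export
iep_tk <- function(x, prior = iep_prior(), fit = NULL) {
  if (is.null(fit)) fit <- iep_mle(x)
  if (!isTRUE(fit$converged))
    stop("Tierney-Kadane requires a converged MLE as starting point",
         call. = FALSE)
  base <- .tk_base(x, prior, fit$coefficients)
  c(alpha  = .tk_expect(x, prior, base, .tk_param_target(1L)),
    lambda = .tk_expect(x, prior, base, .tk_param_target(2L)))
}

## maximise eta and cache mode, value, det(-H) for the denominator
.tk_base <- function(x, prior, start) {
  n <- length(x)
  opt <- .newton_log(start,
    fn   = function(a, l) .logpost_safe(x, a, l, prior) / n,
    grad = function(a, l) .logpost_grad_safe(x, a, l, prior) / n,
    hess = function(a, l) .logpost_hess_safe(x, a, l, prior) / n,
    tol = 1e-10, max_iter = 100L)
  if (!opt$converged) stop("maximisation of eta failed", call. = FALSE)
  H <- .logpost_hess_safe(x, opt$par[1], opt$par[2], prior) / n
  d <- det(-H)
  if (!is.finite(d) || d <= 0)
    stop("negated Hessian of eta not positive definite", call. = FALSE)
  list(n = n, mode = opt$par, value = opt$value, neg_det = d)
}

## target descriptor for u(theta) = theta_m
.tk_param_target <- function(m) {
  list(
    logu = function(a, l) if (m == 1L) log(a) else log(l),
    grad = function(a, l) { g <- c(0, 0); g[m] <- 1 / c(a, l)[m]; g },
    hess = function(a, l) { H <- matrix(0, 2, 2); H[m, m] <- -1 / c(a, l)[m]^2; H }
  )
}

## Laplace ratio for a general positive u described by `target`
## (logu + its gradient/Hessian); seam used by the tests with constant u.
.tk_expect <- function(x, prior, base, target) {
  n <- base$n
  opt <- .newton_log(base$mode,
    fn   = function(a, l) target$logu(a, l) / n + .logpost_safe(x, a, l, prior) / n,
    grad = function(a, l) target$grad(a, l) / n + .logpost_grad_safe(x, a, l, prior) / n,
    hess = function(a, l) target$hess(a, l) / n + .logpost_hess_safe(x, a, l, prior) / n,
    tol = 1e-10, max_iter = 100L)
  if (!opt$converged) stop("maximisation of eta* failed", call. = FALSE)
  Hs <- target$hess(opt$par[1], opt$par[2]) / n +
    .logpost_hess_safe(x, opt$par[1], opt$par[2], prior) / n
  ds <- det(-Hs)
  if (!is.finite(ds) || ds <= 0)
    stop("negated Hessian of eta* not positive definite", call. = FALSE)
  ## det Sigma* / det Sigma = det(-H) / det(-H*)
  sqrt(base$neg_det / ds) * exp(n * (opt$value - base$value))
}
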