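#' Independent gamma priors for the IEP parameters
#'
#' The Bayes machinery assumes independent shape-rate gamma priors,
#' `alpha ~ Gamma(shape_alpha, rate_alpha)` and
#' `lambda ~ Gamma(shape_lambda, rate_lambda)`, each with density
#' proportional to \eqn{\theta^{\gamma-1} e^{-\delta\theta}}.  The defaults
#' `(1, 2)` for `alpha` and `(2, 1)` for `lambda` are the informative priors
#' used throughout the package's simulation benchmarks (prior means 0.5 and
#' 2 respectively).
#'
#' @param shape_alpha,rate_alpha,shape_lambda,rate_lambda positive gamma
#'   hyperparameters.
#' @return object of class `"iep_prior"`.
#' @examples
#' pr <- iep_prior()
#' iep_log_prior(0.5, 2, pr)
#' @export
iep_prior <- function(shape_alpha = 1, rate_alpha = 2,
                      shape_lambda = 2, rate_lambda = 1) {
  h <- c(shape_alpha = shape_alpha, rate_alpha = rate_alpha,
         shape_lambda = shape_lambda, rate_lambda = rate_lambda)
  if (anyNA(h) || any(!is.finite(h)) || any(h <= 0))
    stop("all gamma hyperparameters must be positive and finite",
         call. = FALSE)
  structure(as.list(h), class = "iep_prior")
}

#' @export
print.iep_prior <- function(x, ...) {
  cat(sprintf("IEP gamma priors: alpha ~ Gamma(%g, %g), lambda ~ Gamma(%g, %g)  [shape, rate]\n",
              x$shape_alpha, x$rate_alpha, x$shape_lambda, x$rate_lambda))
  invisible(x)
}

#' Log prior density and log posterior kernel
#'
#' `iep_log_prior` evaluates the joint log prior density (normalising
#' constants included).  `iep_log_posterior` evaluates the log posterior
#' kernel, i.e. log-likelihood plus log prior, up to the additive constant
#' given by the marginal likelihood, which is never computed here.
#'
#' @param alpha,lambda positive IEP parameters.
#' @param prior an [iep_prior()].
#' @param x positive observations.
#' @return a scalar.
#' @export
iep_log_prior <- function(alpha, lambda, prior = iep_prior()) {
  .check_params(alpha, lambda)
  stopifnot(inherits(prior, "iep_prior"))
  with(prior,
       (shape_alpha - 1) * log(alpha) + (shape_lambda - 1) * log(lambda) -
         rate_alpha * alpha - rate_lambda * lambda +
         shape_alpha * log(rate_alpha) + shape_lambda * log(rate_lambda) -
         lgamma(shape_alpha) - lgamma(shape_lambda))
}

#' @rdname iep_log_prior
#' @export
iep_log_posterior <- function(x, alpha, lambda, prior = iep_prior()) {
  iep_loglik(x, alpha, lambda) + iep_log_prior(alpha, lambda, prior)
}

## gradient of the log prior: (rho_1, rho_2)
.prior_grad <- function(alpha, lambda, prior) {
  c((prior$shape_alpha - 1) / alpha - prior$rate_alpha,
    (prior$shape_lambda - 1) / lambda - prior$rate_lambda)
}

## diagonal Hessian of the log prior
.prior_hess <- function(alpha, lambda, prior) {
  diag(c(-(prior$shape_alpha - 1) / alpha^2,
         -(prior$shape_lambda - 1) / lambda^2), 2L)
}

## guarded log posterior kernel for optimisers/samplers
.logpost_safe <- function(x, alpha, lambda, prior) {
  if (!is.finite(alpha) || !is.finite(lambda) || alpha <= 0 || lambda <= 0)
    return(-Inf)
  ll <- .loglik_safe(x, alpha, lambda)
  if (!is.finite(ll)) return(-Inf)
  ll + iep_log_prior(alpha, lambda, prior)
}

## gradient / Hessian of the log posterior kernel (original scale), guarded
.logpost_grad_safe <- function(x, alpha, lambda, prior) {
  g <- .score_safe(x, alpha, lambda)
  g + .prior_grad(alpha, lambda, prior)
}
.logpost_hess_safe <- function(x, alpha, lambda, prior) {
  .hess_safe(x, alpha, lambda) + .prior_hess(alpha, lambda, prior)
}
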