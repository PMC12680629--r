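#' Bayes estimates by Lindley's approximation
#'
#' Second-order expansion of the posterior mean around the MLE.  For a
#' scalar function `u` of the parameters the approximation is
#' \deqn{E[u\,|\,x] \approx u(\hat\theta)
#'  + \tfrac12 \sum_{ij} (u_{ij} + 2 u_i \rho_j)\,\sigma_{ij}
#'  + \tfrac12 \sum_{ijkl} L_{ijk}\,\sigma_{ij}\sigma_{kl}\,u_l,}
#' evaluated at the MLE, where \eqn{\rho} is the log-prior gradient,
#' \eqn{[\sigma_{ij}] = [-L_{ij}]^{-1}} is the inverse negated Hessian of
#' the log-likelihood, and \eqn{L_{ijk}} are its third partials.  Applying
#' it with `u = alpha` and `u = lambda` (so all `u_ij = 0` and `u_i` is a
#' unit vector) gives the squared-error-loss Bayes estimates of the two
#' parameters.  The approximation error is `O(1/n)`; the Tierney-Kadane
#' estimator ([iep_tk()]) is `O(1/n^2)` and the quadrature posterior mean
#' ([iep_posterior_mean_quad()]) is the numerical gold standard.
#'
#' @param x positive observations.
#' @param prior an [iep_prior()].
#' @param fit optional converged [iep_mle()] fit of `x` (refitted if
#'   missing).
#' @return named vector `c(alpha, lambda)` of approximate posterior means.
#' @examples
#' iep_lindley(iep_region("AFR")$cfr)
#' @export
iep_lindley <- function(x, prior = iep_prior(), fit = NULL) {
  if (is.null(fit)) fit <- iep_mle(x)
  if (!isTRUE(fit$converged))
    stop("Lindley's approximation requires a converged MLE", call. = FALSE)
  est <- unname(fit$coefficients)
  db <- iep_derivs(x, est[1], est[2])
  info <- -db$hessian
  if (info[1, 1] <= 0 || det(info) <= 0)
    stop("negated Hessian not positive definite at the MLE", call. = FALSE)
  sigma <- solve(info)
  rho <- .prior_grad(est[1], est[2], prior)
  L3 <- .third_array(db$third)
  c(alpha  = est[1] + .lindley_correction(1L, sigma, rho, L3),
    lambda = est[2] + .lindley_correction(2L, sigma, rho, L3))
}

## correction term for u(theta) = theta_m: u_l = 1[l == m], all u_ij = 0
.lindley_correction <- function(m, sigma, rho, L3) {
  u <- c(0, 0); u[m] <- 1
  corr <- 0
  for (i in 1:2) for (j in 1:2)
    corr <- corr + u[i] * rho[j] * sigma[i, j]
  for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2)
    corr <- corr + 0.5 * L3[i, j, k] * sigma[i, j] * sigma[k, l] * u[l]
  corr
}
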