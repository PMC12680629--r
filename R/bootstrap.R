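#' Percentile bootstrap confidence intervals
#'
#' Parametric percentile bootstrap: `n_boot` samples of size `n` are drawn
#' from the fitted IEP(`alpha_hat`, `lambda_hat`), each is refitted by
#' maximum likelihood, and the interval for each parameter is the pair of
#' empirical `gamma/2` and `1 - gamma/2` quantiles of the bootstrap
#' estimates (linear interpolation between order statistics,
#' `quantile(type = 7)`).  A nonparametric variant that resamples the
#' observations with replacement is available via `type`, but the
#' parametric scheme is the default.
#'
#' Replicates whose refit does not converge are dropped and counted in the
#' `n_failed` attribute; if more than 20% fail the interval is not
#' trustworthy and an error is raised.
#'
#' @param fit a converged [iep_mle()] fit.
#' @param n_boot number of bootstrap replicates (at least 50).
#' @param level confidence level in (0, 1).
#' @param seed optional integer seed making the interval reproducible.
#' @param type `"parametric"` (default) or `"nonparametric"`.
#' @return data frame with columns `parameter`, `lower`, `upper`, `level`,
#'   `method`; attributes `n_failed` (dropped replicates) and `estimates`
#'   (matrix of bootstrap estimates actually used).
#' @examples
#' fit <- iep_mle(iep_region("SEAR")$cfr)
#' iep_boot_ci(fit, n_boot = 200, seed = 7)
#' @export
iep_boot_ci <- function(fit, n_boot = 1000L, level = 0.95, seed = NULL,
                        type = c("parametric", "nonparametric")) {
  type <- match.arg(type)
  if (!inherits(fit, "iep_fit") || !isTRUE(fit$converged))
    stop("'fit' must be a converged iep_mle() fit", call. = FALSE)
  if (n_boot < 50L) stop("'n_boot' must be at least 50", call. = FALSE)
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  est <- fit$coefficients
  n <- fit$n
  boot <- matrix(NA_real_, n_boot, 2L)
  for (b in seq_len(n_boot)) {
    xb <- if (type == "parametric") riep(n, est[1], est[2])
          else sample(fit$x, n, replace = TRUE)
    fb <- .fit_fast(xb)
    if (!is.null(fb)) boot[b, ] <- fb
  }
  ok <- stats::complete.cases(boot)
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_boot)
    stop(n_failed, " of ", n_boot, " bootstrap refits failed (> 20%)",
         call. = FALSE)
  ci <- .percentile_interval(boot[ok, , drop = FALSE], level)
  ci$method <- paste0("percentile_", type, "_bootstrap")
  attr(ci, "n_failed") <- n_failed
  attr(ci, "estimates") <- boot[ok, , drop = FALSE]
  ci
}

## empirical percentile interval from a matrix of (alpha, lambda) estimates
.percentile_interval <- function(estimates, level) {
  gamma <- 1 - level
  qs <- apply(estimates, 2L, quantile,
              probs = c(gamma / 2, 1 - gamma / 2), type = 7, names = FALSE)
  data.frame(parameter = c("alpha", "lambda"),
             lower = qs[1, ], upper = qs[2, ],
             level = level, row.names = NULL)
}
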