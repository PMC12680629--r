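#' Monte Carlo bias / MSE comparison of the estimators
#'
#' For every sample size in `n_grid` and every replicate, a sample is drawn
#' from IEP(`truth`) by inverse-transform sampling, each requested
#' estimator is applied, and the estimates are summarised per
#' (method, n, parameter) as the mean estimate, the mean absolute error
#' (`bias`, following the convention of the benchmark tables this harness
#' reproduces), the signed mean bias (`signed_bias`) and the mean squared
#' error against the fixed truth.  Replicates where an estimator fails are
#' dropped from that estimator's summary and counted.
#'
#' Reproducibility: replicate `r` at sample size `n` uses the seed
#' `(seed + 7919 * n + r) mod (2^31 - 1)`, so runs are reproducible and
#' individual cells can be recomputed in isolation.
#'
#' @param truth length-2 vector `c(alpha, lambda)` of true parameters, held
#'   fixed across replicates.
#' @param prior an [iep_prior()] used by the Bayes estimators.
#' @param n_grid vector of sample sizes (each at least 5).
#' @param n_reps replicates per sample size.
#' @param methods subset of `c("mle", "lindley", "tk", "mcmc")`, or a named
#'   list of functions `function(x) c(alpha, lambda)` for injecting custom
#'   estimators (used by the tests).
#' @param seed master integer seed.
#' @param mcmc_iter,mcmc_burn_in chain length controls for the `"mcmc"`
#'   method.
#' @return data frame with one row per method x n x parameter:
#'   columns `method`, `n`, `parameter`, `truth`, `average`, `bias` (mean
#'   absolute error), `signed_bias`, `mse`, `n_failed`, `n_used`.
#' @examples
#' iep_bias_mse_study(c(2, 2), n_grid = c(20, 50), n_reps = 25,
#'                    methods = "mle", seed = 1)
#' @export
iep_bias_mse_study <- function(truth, prior = iep_prior(),
                               n_grid = c(10, 20, 30, 50, 100, 500),
                               n_reps = 10000L,
                               methods = c("mle", "lindley", "tk"),
                               seed = 1L,
                               mcmc_iter = 3000L, mcmc_burn_in = 1000L) {
  stopifnot(length(truth) == 2L, all(truth > 0), n_reps >= 1L,
            all(n_grid >= 5L))
  estimators <- .resolve_estimators(methods, prior, mcmc_iter, mcmc_burn_in)
  rows <- list()
  for (n in n_grid) {
    est_store <- lapply(estimators, function(e) matrix(NA_real_, n_reps, 2L))
    for (r in seq_len(n_reps)) {
      set.seed(.derive_seed(seed, n, r))
      xs <- riep(n, truth[1], truth[2])
      for (mname in names(estimators)) {
        v <- tryCatch(estimators[[mname]](xs), error = function(e) NULL)
        if (!is.null(v) && length(v) == 2L && all(is.finite(v)))
          est_store[[mname]][r, ] <- v
      }
    }
    for (mname in names(estimators)) {
      E <- est_store[[mname]]
      ok <- stats::complete.cases(E)
      n_failed <- sum(!ok)
      if (n_failed > 0.05 * n_reps)
        warning(sprintf("%s at n = %d: %d of %d replicates failed (> 5%%)",
                        mname, n, n_failed, n_reps))
      E <- E[ok, , drop = FALSE]
      for (p in 1:2) {
        err <- E[, p] - truth[p]
        rows[[length(rows) + 1L]] <- data.frame(
          method = mname, n = n,
          parameter = c("alpha", "lambda")[p], truth = truth[p],
          average = mean(E[, p]), bias = mean(abs(err)),
          signed_bias = mean(err), mse = mean(err^2),
          n_failed = n_failed, n_used = nrow(E))
      }
    }
  }
  do.call(rbind, rows)
}

.derive_seed <- function(seed, n, r) {
  as.integer((as.double(seed) + 7919 * n + r) %% 2147483647)
}

.resolve_estimators <- function(methods, prior, mcmc_iter, mcmc_burn_in) {
  if (is.list(methods)) {
    stopifnot(!is.null(names(methods)), all(vapply(methods, is.function, TRUE)))
    return(methods)
  }
  methods <- match.arg(methods, c("mle", "lindley", "tk", "mcmc"),
                       several.ok = TRUE)
  registry <- list(
    mle = function(x) .fit_fast(x),
    lindley = function(x) {
      par <- .fit_fast(x)
      if (is.null(par)) return(NULL)
      fit <- structure(list(coefficients = par, converged = TRUE),
                       class = "iep_fit")
      unname(iep_lindley(x, prior, fit = fit))
    },
    tk = function(x) {
      par <- .fit_fast(x)
      if (is.null(par)) return(NULL)
      fit <- structure(list(coefficients = par, converged = TRUE),
                       class = "iep_fit")
      unname(iep_tk(x, prior, fit = fit))
    },
    mcmc = function(x) {
      ch <- iep_mh(x, prior, n_iter = mcmc_iter, burn_in = mcmc_burn_in)
      unname(iep_sel_estimate(ch))
    })
  registry[methods]
}

#' Interval coverage study (Wald and percentile bootstrap)
#'
#' Generates `n_datasets` samples per size from IEP(`truth`), fits each by
#' maximum likelihood, forms the Wald and the parametric percentile
#' bootstrap interval, and records whether each interval contains the truth
#' together with its length.  Datasets whose fit (or too many of whose
#' bootstrap refits) fail are dropped and counted.
#'
#' @inheritParams iep_bias_mse_study
#' @param n_datasets independent datasets per sample size.
#' @param n_boot bootstrap replicates per dataset.
#' @param level nominal confidence level.
#' @return data frame with one row per interval-method x n x parameter:
#'   `method`, `n`, `parameter`, `coverage`, `avg_length`, `n_failed`,
#'   `n_used`.
#' @examples
#' iep_coverage_study(c(1.6, 0.3), n_grid = 20, n_datasets = 20,
#'                    n_boot = 60, seed = 1)
#' @export
iep_coverage_study <- function(truth, n_grid = c(20, 30, 50, 100, 150),
                               n_datasets = 500L, n_boot = 250L,
                               level = 0.95, seed = 1L) {
  stopifnot(length(truth) == 2L, all(truth > 0))
  methods <- c("wald", "percentile")
  rows <- list()
  for (n in n_grid) {
    hit <- len <- array(NA_real_, c(n_datasets, 2L, 2L),
                        dimnames = list(NULL, methods, c("alpha", "lambda")))
    failed <- 0L
    for (d in seq_len(n_datasets)) {
      set.seed(.derive_seed(seed, n, d))
      xs <- riep(n, truth[1], truth[2])
      par <- .fit_fast(xs)
      if (is.null(par)) { failed <- failed + 1L; next }
      oi <- tryCatch(iep_observed_info(xs, par[1], par[2]),
                     error = function(e) NULL)
      if (is.null(oi)) { failed <- failed + 1L; next }
      z <- qnorm(1 - (1 - level) / 2)
      se <- sqrt(diag(oi$vcov))
      ## Wald
      for (p in 1:2) {
        lo <- par[p] - z * se[p]; up <- par[p] + z * se[p]
        hit[d, "wald", p] <- truth[p] >= lo && truth[p] <= up
        len[d, "wald", p] <- up - lo
      }
      ## percentile bootstrap (parametric, seeded off the dataset seed)
      boot <- matrix(NA_real_, n_boot, 2L)
      for (b in seq_len(n_boot)) {
        fb <- .fit_fast(riep(n, par[1], par[2]))
        if (!is.null(fb)) boot[b, ] <- fb
      }
      okb <- stats::complete.cases(boot)
      if (sum(okb) < 0.8 * n_boot) { hit[d, "percentile", ] <- NA; next }
      ci <- .percentile_interval(boot[okb, , drop = FALSE], level)
      for (p in 1:2) {
        hit[d, "percentile", p] <- truth[p] >= ci$lower[p] &&
          truth[p] <= ci$upper[p]
        len[d, "percentile", p] <- ci$upper[p] - ci$lower[p]
      }
    }
    for (m in methods) for (p in 1:2) {
      ok <- !is.na(hit[, m, p])
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, n = n, parameter = c("alpha", "lambda")[p],
        coverage = mean(hit[ok, m, p]), avg_length = mean(len[ok, m, p]),
        n_failed = sum(!ok), n_used = sum(ok))
    }
  }
  do.call(rbind, rows)
}
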