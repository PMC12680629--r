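test_that("gamma prior density is normalised and has the stated gradient", {
  pr <- iep_prior(1.5, 2, 2.5, 0.8)
  z <- integrate(function(a) {
    vapply(a, function(ai) {
      integrate(function(l) vapply(l, function(li)
        exp(iep_log_prior(ai, li, pr)), 0), 0, Inf, rel.tol = 1e-10)$value
    }, 0)
  }, 0, Inf, rel.tol = 1e-10)
  expect_equal(z$value, 1, tolerance = 1e-6)
  # analytic log-prior gradient (gamma - 1)/theta - delta vs finite differences
  th <- c(0.7, 1.9)
  expect_equal(iepfit:::.prior_grad(th[1], th[2], pr),
               fd_grad(function(t) iep_log_prior(t[1], t[2], pr), th),
               tolerance = 1e-7)
  # shape-1 collapse to exponential priors: linear in the parameters
  pr1 <- iep_prior(1, 2, 1, 3)
  d <- iep_log_prior(2, 2, pr1) - iep_log_prior(1, 1, pr1)
  expect_equal(d, -2 * 1 - 3 * 1)
})

test_that("posterior kernel is likelihood plus prior and peaks near the MLE", {
  x <- iep_region("AFR")$cfr
  pr <- iep_prior()
  expect_equal(iep_log_posterior(x, 1.1, 0.7, pr),
               iep_loglik(x, 1.1, 0.7) + iep_log_prior(1.1, 0.7, pr))
  expect_true(is.finite(iep_log_posterior(x, 0.9993, 0.6609, pr)))
  # with a near-flat prior the kernel maximiser is the MLE
  flat <- iep_prior(1, 1e-8, 1, 1e-8)
  fit <- iep_mle(x)
  opt <- optim(log(coef(fit) * 1.3),
               function(th) -iep_log_posterior(x, exp(th[1]), exp(th[2]), flat),
               method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(unname(exp(opt$par)), unname(coef(fit)), tolerance = 1e-4)
})

test_that("Lindley reduces to the MLE when prior gradient and third partials vanish", {
  sigma <- matrix(c(0.05, 0.01, 0.01, 0.03), 2)
  zero3 <- array(0, c(2, 2, 2))
  expect_identical(iepfit:::.lindley_correction(1L, sigma, c(0, 0), zero3), 0)
  expect_identical(iepfit:::.lindley_correction(2L, sigma, c(0, 0), zero3), 0)
})

test_that("Tierney-Kadane of a constant function returns the constant", {
  x <- iep_region("SEAR")$cfr
  pr <- iep_prior()
  fit <- iep_mle(x)
  base <- iepfit:::.tk_base(x, pr, coef(fit))
  const_target <- list(logu = function(a, l) log(7.5),
                       grad = function(a, l) c(0, 0),
                       hess = function(a, l) matrix(0, 2, 2))
  expect_equal(iepfit:::.tk_expect(x, pr, base, const_target), 7.5,
               tolerance = 1e-8)
})

test_that("a zero proposal scale degenerates to a constant chain", {
  ch <- iep_mh(iep_region("SEAR")$cfr, n_iter = 200, burn_in = 0,
               scale = 0, seed = 2)
  expect_equal(nrow(unique(ch$draws)), 1L)
  expect_equal(unname(ch$draws[1, ]), unname(ch$mode), tolerance = 1e-12)
})

test_that("the random-walk kernel recovers an injected standard normal", {
  lt <- function(z) -sum(z^2) / 2
  res <- iepfit:::.rw_mh(lt, start = c(0, 0),
                         cov_chol = chol(diag(2) * (2.4 / sqrt(2))^2),
                         n_iter = 50000, seed = 13)
  kept <- res$chain[5001:50000, ]
  expect_equal(colMeans(kept), c(0, 0), tolerance = 0.05)
  expect_equal(cov(kept), diag(2), tolerance = 0.1, ignore_attr = TRUE)
  expect_gt(res$acceptance_rate, 0.1)
})

test_that("chains are bit-reproducible under a fixed seed", {
  x <- iep_region("SEAR")$cfr
  c1 <- iep_mh(x, n_iter = 500, burn_in = 100, seed = 77)
  c2 <- iep_mh(x, n_iter = 500, burn_in = 100, seed = 77)
  expect_identical(c1$draws, c2$draws)
  expect_identical(c1$acceptance_rate, c2$acceptance_rate)
})

test_that("posterior-mean estimate from a chain is the draw average", {
  ch <- structure(list(draws = cbind(alpha = c(1, 3), lambda = c(1, 3)),
                       n_iter = 2L, burn_in = 0L),
                  class = "iep_chain")
  expect_equal(unname(iep_sel_estimate(ch)), c(2, 2))
  ch$draws <- cbind(alpha = rep(2, 5), lambda = rep(3, 5)); ch$n_iter <- 5L
  expect_equal(unname(iep_sel_estimate(ch)), c(2, 3))
})

test_that("Lindley, Tierney-Kadane and MCMC all agree with the quadrature mean", {
  set.seed(71)
  x <- riep(100, 2, 2)
  pr <- iep_prior()
  oracle <- iep_posterior_mean_quad(x, pr)
  expect_equal(unname(iep_lindley(x, pr)), unname(oracle), tolerance = 0.02)
  expect_equal(unname(iep_tk(x, pr)), unname(oracle), tolerance = 0.01)
  ch <- iep_mh(x, pr, n_iter = 10000, burn_in = 2000, seed = 19)
  est <- iep_sel_estimate(ch)
  kept <- ch$draws[2001:10000, ]
  # batch-means Monte Carlo standard errors (40 batches of 200)
  bm <- apply(kept, 2, function(v) {
    m <- colMeans(matrix(v, nrow = 200))
    sd(m) / sqrt(length(m))
  })
  expect_true(all(abs(est - oracle) <= 3 * bm))
})

test_that("the quadrature mean approaches the MLE for flat priors at large n", {
  set.seed(81)
  x <- riep(2000, 1.5, 1)
  flat <- iep_prior(1, 1e-8, 1, 1e-8)
  pm <- iep_posterior_mean_quad(x, flat, nodes = 100)
  fit <- iep_mle(x)
  expect_equal(unname(pm), unname(coef(fit)), tolerance = 0.01)
})

test_that("Tierney-Kadane tracks the oracle more closely than Lindley on average", {
  set.seed(91)
  pr <- iep_prior()
  err <- matrix(NA_real_, 30, 2)
  for (r in 1:30) {
    x <- riep(30, 2, 2)
    fit <- tryCatch(iep_mle(x), warning = function(w) NULL)
    if (is.null(fit) || !fit$converged) next
    oracle <- iep_posterior_mean_quad(x, pr, nodes = 80)
    err[r, 1] <- sum(abs(iep_lindley(x, pr, fit) - oracle))
    err[r, 2] <- sum(abs(iep_tk(x, pr, fit) - oracle))
  }
  ok <- complete.cases(err)
  expect_gt(sum(ok), 20)
  expect_lt(mean(err[ok, 2]), mean(err[ok, 1]))
})
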