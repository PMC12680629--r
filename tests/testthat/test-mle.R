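test_that("all bundled regional samples fit with a vanishing score", {
  fits <- region_mles()
  for (r in names(fits)) {
    expect_true(fits[[r]]$converged, info = r)
    expect_lt(max(abs(fits[[r]]$score)), 1e-8)
    expect_true(all(diag(fits[[r]]$vcov) > 0), info = r)
  }
})

test_that("the fit is order-invariant and robust to the starting point", {
  x <- iep_region("EUR")$cfr
  f1 <- iep_mle(x)
  f2 <- iep_mle(rev(x))
  f3 <- iep_mle(sample(x))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  expect_equal(coef(f1), coef(f3), tolerance = 1e-10)
  for (st in list(c(0.3, 0.1), c(0.5, 2), c(2, 0.2), c(3, 3), c(1, 5))) {
    fs <- iep_mle(x, start = st)
    expect_true(fs$converged)
    expect_equal(coef(fs), coef(f1), tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("the estimator is consistent and beats a coarse grid search", {
  set.seed(61)
  x <- riep(5000, 2, 2)
  fit <- iep_mle(x)
  expect_equal(unname(coef(fit)), c(2, 2), tolerance = 0.05 / 2)
  # independent coarse maximisation of the likelihood surface
  grid <- expand.grid(a = seq(1.5, 2.5, by = 0.05),
                      l = seq(1.5, 2.5, by = 0.05))
  ll <- mapply(function(a, l) iep_loglik(x, a, l), grid$a, grid$l)
  best <- grid[which.max(ll), ]
  expect_equal(unname(coef(fit)), c(best$a, best$l), tolerance = 0.06)
  expect_gte(fit$loglik, max(ll))
})

test_that("degenerate and undersized samples are flagged, not mis-fit", {
  expect_warning(f <- iep_mle(rep(1.5, 10)), "degenerate")
  expect_false(f$converged)
  expect_error(iep_mle(c(1, 2)), "at least 3")
})

test_that("observed information inverts to the covariance", {
  x <- iep_region("WPR")$cfr
  fit <- iep_mle(x)
  oi <- iep_observed_info(x, coef(fit)[1], coef(fit)[2])
  expect_equal(oi$info %*% oi$vcov, diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unname(oi$info), unname(-iep_derivs(x, coef(fit)[1],
                                                   coef(fit)[2])$hessian))
  # far from any maximum the matrix is indefinite and must be refused
  expect_error(iep_observed_info(x, 5, 0.05), "positive definite")
})

test_that("Wald intervals are symmetric around the estimate", {
  fake <- structure(list(converged = TRUE,
                         coefficients = c(alpha = 2, lambda = 2),
                         vcov = diag(c(0.04, 0.04)), n = 30L),
                    class = "iep_fit")
  ci <- confint(fake, level = 0.95)
  expect_equal(ci$lower, c(1.608007, 1.608007), tolerance = 1e-6)
  expect_equal(ci$upper, c(2.391993, 2.391993), tolerance = 1e-6)
  expect_equal((ci$lower + ci$upper) / 2, c(2, 2))
  expect_error(confint(fake, level = 1.2), "level")
})

test_that("percentile interval uses linear-interpolation quantiles", {
  est <- cbind(1:100, 1:100)
  ci <- iepfit:::.percentile_interval(est, 0.95)
  expect_equal(ci$lower, c(3.475, 3.475))
  expect_equal(ci$upper, c(97.525, 97.525))
})

test_that("bootstrap intervals are reproducible and bracket the MLE", {
  fit <- iep_mle(iep_region("SEAR")$cfr)
  ci1 <- iep_boot_ci(fit, n_boot = 200, seed = 5)
  ci2 <- iep_boot_ci(fit, n_boot = 200, seed = 5)
  expect_identical(ci1$lower, ci2$lower)
  expect_true(all(ci1$lower <= coef(fit) & coef(fit) <= ci1$upper))
  expect_true(attr(ci1, "n_failed") <= 40)
  # nonparametric switch exists and runs
  cin <- iep_boot_ci(fit, n_boot = 100, seed = 5, type = "nonparametric")
  expect_match(cin$method[1], "nonpar")
  expect_error(iep_boot_ci(fit, n_boot = 10), "at least 50")
})
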