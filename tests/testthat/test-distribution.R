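test_that("density matches its closed form and is log-stable", {
  # at x = lambda the inner exponent is 1, so f = (alpha/lambda) e^(2-e)
  expect_equal(diep(1, 1, 1), exp(2 - exp(1)))
  for (i in 1:5) {
    a <- runif(1, 0.3, 4); l <- runif(1, 0.3, 4)
    expect_equal(diep(l, a, l), (a / l) * exp(2 - exp(1)))
  }
  expect_equal(diep(1, 1, 1, log = TRUE), 2 - exp(1))
  # deep left tail: density underflows to 0, not Inf/NaN
  expect_identical(diep(1e-6, 2, 1), 0)
  expect_identical(diep(1e-6, 2, 1, log = TRUE), -Inf)
  # exp(log f) = f wherever f is representable
  x <- exp(seq(log(0.05), log(50), length.out = 40))
  expect_equal(exp(diep(x, 1.3, 0.8, log = TRUE)), diep(x, 1.3, 0.8))
})

test_that("density integrates to one across the parameter grid", {
  for (a in c(0.5, 1, 2, 4)) for (l in c(0.5, 1, 2, 4)) {
    z <- integrate(diep, 0, Inf, alpha = a, lambda = l,
                   rel.tol = 1e-10, subdivisions = 500L)
    expect_equal(z$value, 1, tolerance = 1e-8)
  }
})

test_that("cdf agrees with the integrated density and is a proper cdf", {
  expect_equal(piep(1, 1, 1), exp(1 - exp(1)))
  for (a in c(0.7, 3)) expect_equal(piep(2, a, 2), exp(1 - exp(1)))  # alpha-free at x = lambda
  xg <- exp(seq(log(0.1), log(20), length.out = 20))
  for (th in list(c(1, 1), c(2, 0.5))) {
    Fx <- piep(xg, th[1], th[2])
    expect_true(all(diff(Fx) >= 0))
    expect_true(all(Fx >= 0 & Fx <= 1))
    for (k in seq_along(xg)) {
      z <- integrate(diep, 0, xg[k], alpha = th[1], lambda = th[2],
                     rel.tol = 1e-11)$value
      expect_equal(Fx[k], z, tolerance = 1e-8)
    }
  }
  expect_lt(piep(1e-4, 1, 1), 1e-12)
  expect_equal(piep(1e7, 1, 1), 1, tolerance = 1e-6)
})

test_that("survival and hazard satisfy their identities", {
  expect_equal(piep(1, 2, 1, lower.tail = FALSE), 1 - exp(1 - exp(1)))
  set.seed(4)
  x <- riep(20, 1.5, 0.9)
  expect_equal(hiep(x, 1.5, 0.9) * piep(x, 1.5, 0.9, lower.tail = FALSE),
               diep(x, 1.5, 0.9))
  # far right tail: survival underflows to 0 and the sentinel fires
  expect_warning(h <- hiep(1e170, 2, 1), "hazard")
  expect_identical(h, Inf)
  # inverse-family hazard at alpha = 2: rises to a mode then decays
  xg <- exp(seq(log(0.05), log(60), length.out = 200))
  hz <- hiep(xg, 2, 1)
  pk <- which.max(hz)
  expect_gt(pk, 1); expect_lt(pk, 200)
  expect_true(all(diff(hz[pk:200]) < 0))
})

test_that("quantile function inverts the cdf", {
  expect_equal(qiep(exp(1 - exp(1)), 1.7, 2.3), 2.3)
  # frozen from the independent root of F(x) = 1/2 at (1, 1)
  expect_equal(qiep(0.5, 1, 1), 1.8990141, tolerance = 1e-7)
  ug <- seq(0.001, 0.999, length.out = 25)
  for (th in list(c(0.5, 1), c(1, 2), c(2, 0.5), c(3, 3))) {
    expect_equal(piep(qiep(ug, th[1], th[2]), th[1], th[2]), ug,
                 tolerance = 1e-12)
    xg <- qiep(ug, th[1], th[2])
    expect_equal(qiep(piep(xg, th[1], th[2]), th[1], th[2]), xg,
                 tolerance = 1e-10)
  }
  expect_error(qiep(0, 1, 1), "inside")
  expect_error(qiep(1, 1, 1), "inside")
})

test_that("sampling is reproducible, positive, and matches the cdf", {
  set.seed(99); s1 <- riep(50, 2, 2)
  set.seed(99); s2 <- riep(50, 2, 2)
  expect_identical(s1, s2)
  expect_true(all(riep(1, 0.4, 0.2) > 0))
  set.seed(7)
  x <- riep(1e5, 2, 2)
  xs <- sort(x); n <- length(x)
  Fx <- piep(xs, 2, 2)
  D <- max(pmax(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n))
  expect_lt(D, 0.01)
})

test_that("invalid inputs are rejected with domain errors", {
  expect_error(diep(-1, 1, 1), "positive")
  expect_error(diep(1, 0, 1), "alpha")
  expect_error(piep(1, 1, -2), "lambda")
  expect_error(riep(0, 1, 1), "count")
})
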