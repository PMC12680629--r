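# Shared numerical oracles: central finite differences with steps scaled to
# the parameter magnitude (eps^(1/3) for first/second differences, eps^(1/4)
# for the third-order checks), plus a generator for random test instances.

`%||%` <- function(a, b) if (is.null(a)) b else a

fd_step <- function(theta, order = 2) {
  max(abs(theta), 1) * .Machine$double.eps^(1 / (order + 1))
}

# gradient of scalar f(c(alpha, lambda)) by central differences
fd_grad <- function(f, theta) {
  vapply(1:2, function(i) {
    h <- fd_step(theta[i], 2)
    e <- c(0, 0); e[i] <- h
    (f(theta + e) - f(theta - e)) / (2 * h)
  }, 0)
}

# Hessian of scalar f by differencing an analytic gradient g(theta) -> 2-vec
fd_jacobian <- function(g, theta, order = 2) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    h <- fd_step(theta[j], order)
    e <- c(0, 0); e[j] <- h
    J[, j] <- (g(theta + e) - g(theta - e)) / (2 * h)
  }
  J
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1)

# random (alpha, lambda) in [0.3, 4]^2 and a sample drawn from it
random_instance <- function(n = NULL) {
  theta <- runif(2, 0.3, 4)
  if (is.null(n)) n <- sample(5:50, 1)
  list(theta = theta, x = riep(n, theta[1], theta[2]))
}

region_mles <- function() {
  lapply(setNames(nm = iep_regions()),
         function(r) iep_mle(iep_region(r)$cfr))
}
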