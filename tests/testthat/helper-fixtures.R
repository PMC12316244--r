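# Shared fixture builders.  Everything is generated in code at test time.

toy_X <- function(n) cbind(Intercept = 1, x = seq(-1, 1, length.out = n))

# small mixed-status dataset used across modules
toy_data <- function() {
  X <- toy_X(6)
  censored_data(
    y = c(-0.5, 0.2, 1.0, 1.5, 2.0, 2.5),
    status = c("observed", "observed", "left", "observed", "right", "right"),
    X = X, names = colnames(X))
}

# write a small CSV in the generic censored layout and return its path
toy_csv <- function(path = tempfile(fileext = ".csv")) {
  df <- data.frame(y = c(1.2, 3.4, 5.0, 2.2),
                   status = c("observed", "right", "observed", "left"),
                   x1 = c(0.1, -0.3, 0.7, 0.0),
                   x2 = c(1, 0, 1, 1))
  write.csv(df, path, row.names = FALSE)
  path
}

# conjugate normal-mean fixture: y_i ~ N(mu, 1), mu ~ N(0, tau2).
# returns closed-form posterior draws and the pointwise loglik matrix.
conjugate_fixture <- function(n = 8, S = 4000, tau2 = 100, seed = 42) {
  set.seed(seed)
  y <- rnorm(n, 1, 1)
  prec <- n + 1 / tau2
  post_mean <- sum(y) / prec
  post_sd <- sqrt(1 / prec)
  mu <- rnorm(S, post_mean, post_sd)
  ll <- sapply(y, function(yi) dnorm(yi, mu, 1, log = TRUE))
  list(y = y, mu = mu, loglik = ll, tau2 = tau2)
}

# quadrature-normalized Student-t kernel oracle: normalize
# exp(-(nu+1)/2 * log(1 + z^2/nu)) numerically, independent of dt()
t_kernel_oracle <- function(nu) {
  kern <- function(z) exp(-(nu + 1) / 2 * log(1 + z^2 / nu))
  nc <- integrate(kern, -Inf, Inf, rel.tol = 1e-10)$value
  list(pdf = function(z) kern(z) / nc,
       cdf = function(z) integrate(function(u) kern(u) / nc, -Inf, z,
                                   rel.tol = 1e-10)$value)
}

run_quick_fit <- function(data, fam, seed = 1, iterations = 600,
                          warmup = 300, chains = 2, ...) {
  run_mcmc(data, fam,
           cfg = sampler_config(chains = chains, iterations = iterations,
                                warmup = warmup, seed = seed), ...)
}
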