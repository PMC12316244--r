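test_that("log prior matches closed forms and enforces the nu support", {
  pr <- prior_config()
  # beta at its mode: p * standard normal max on the tau scale
  expect_equal(log_prior(c(0, 0, 0), 1, nu = NULL, pr) -
                 log_prior(numeric(0), 1, nu = NULL, pr),
               3 * (-0.5 * log(2 * pi * 1e4)))
  # half-Cauchy density at sigma = A is 1/(pi*A)
  prA <- prior_config(beta_scale = 1, sigma_scale = 5)
  expect_equal(log_prior(numeric(0), 5, nu = NULL, prA), log(1 / (pi * 5)))
  # free nu below the support boundary
  expect_identical(log_prior(0, 1, nu = 1.5, pr), -Inf)
  # truncated gamma term is properly normalized at the boundary
  expect_gt(log_prior(0, 1, nu = 2.5, pr), log_prior(0, 1, nu = NULL, pr) - Inf)
  expect_error(log_prior(0, -1, NULL, pr), "sigma")
})

test_that("lambda update draws from the conjugate gamma conditional", {
  set.seed(5)
  n <- 20000
  X <- matrix(1, n, 1)
  d <- censored_data(rep(0, n), rep("observed", n), X)
  # eps = 0 for every row, nu = 3: conditional is Gamma(2, rate 3/2)
  st <- list(beta = 0, sigma = 1, nu = 3, ystar = rep(0, n))
  lam <- update_lambda(st, d, error_family("student_t"))
  expect_gt(suppressWarnings(
    ks.test(lam, pgamma, shape = 2, rate = 1.5))$p.value, 0.001)
  expect_equal(mean(lam), 4 / 3, tolerance = 0.03)
  # large nu: mixing scales degenerate at 1 (normal limit)
  st$nu <- 1e6
  expect_equal(mean(update_lambda(st, d, error_family("student_t"))), 1,
               tolerance = 0.01)
  # normal family freezes lambda at 1
  expect_identical(update_lambda(st, d, error_family("normal")), rep(1, n))
  # the two-stage hierarchy marginalizes to t residuals
  set.seed(6)
  lam <- rgamma(n, 1.5, rate = 1.5)
  eps <- rnorm(n, 0, 1 / sqrt(lam))
  expect_gt(suppressWarnings(ks.test(eps, pt, df = 3))$p.value, 0.001)
})

test_that("censored imputation samples the correct truncated normals", {
  set.seed(7)
  n <- 10000
  X <- matrix(1, n, 1)
  mu <- 2
  # right-censored exactly at mu: half-normal, mean mu + sqrt(2/pi)
  d <- censored_data(rep(mu, n), rep("right", n), X)
  st <- list(beta = mu, sigma = 1, lambda = rep(1, n), ystar = rep(mu, n))
  ys <- impute_censored(st, d)
  expect_true(all(ys >= mu))
  expect_equal(mean(ys), mu + sqrt(2 / pi), tolerance = 0.03)
  # bound far below the mean: truncation inactive
  d_far <- censored_data(rep(mu - 20, n), rep("right", n), X)
  st$ystar <- rep(mu - 20, n)
  ys <- impute_censored(st, d_far)
  expect_lt(suppressWarnings(ks.test(ys, pnorm, mean = mu))$statistic, 0.02)
  # left censoring mirrors right censoring
  d_left <- censored_data(rep(mu, n), rep("left", n), X)
  ys <- impute_censored(st, d_left)
  expect_true(all(ys <= mu))
  expect_equal(mean(ys), mu - sqrt(2 / pi), tolerance = 0.03)
  # observed rows pass through untouched; deep tails never yield NaN
  d_mix <- censored_data(c(0.5, 1e3), c("observed", "right"),
                         matrix(1, 2, 1))
  st2 <- list(beta = 0, sigma = 1, lambda = c(1, 1), ystar = c(0.5, 1e3))
  ys <- impute_censored(st2, d_mix)
  expect_identical(ys[1], 0.5)
  expect_true(is.finite(ys[2]) && ys[2] >= 1e3)
})

test_that("coefficient update matches a dense-grid conditional oracle", {
  set.seed(8)
  n <- 5
  X <- cbind(1, c(-1, -0.5, 0, 0.5, 1))
  ystar <- c(0.8, 1.1, 1.9, 2.4, 3.1)
  lambda <- c(0.5, 2, 1, 0.8, 1.5)
  sigma <- 0.7
  pr <- prior_config(beta_scale = 2)
  d <- censored_data(ystar, rep("observed", n), X)
  # oracle: evaluate the unnormalized conditional on a dense 2-d grid
  g <- seq(-1, 5, length.out = 241)
  grid <- expand.grid(b0 = g, b1 = g)
  lw <- apply(grid, 1, function(b) {
    mu <- drop(X %*% b)
    sum(dnorm(ystar, mu, sigma / sqrt(lambda), log = TRUE)) +
      sum(dnorm(b, 0, pr$beta_scale, log = TRUE))
  })
  w <- exp(lw - max(lw)); w <- w / sum(w)
  m_oracle <- c(sum(w * grid$b0), sum(w * grid$b1))
  v_oracle <- c(sum(w * grid$b0^2), sum(w * grid$b1^2)) - m_oracle^2
  st <- list(sigma = sigma, lambda = lambda, ystar = ystar)
  draws <- t(replicate(20000, update_beta(st, d, pr)))
  expect_equal(colMeans(draws), m_oracle, tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(apply(draws, 2, var), v_oracle, tolerance = 0.05,
               ignore_attr = TRUE)
  # no data: the conditional is the prior
  d0 <- structure(list(y = numeric(0), status = character(0),
                       lower = numeric(0), upper = numeric(0),
                       X = matrix(0, 0, 2), names = c("a", "b"),
                       n = 0L, p = 2L), class = "censored_data")
  prior_draws <- t(replicate(5000, update_beta(st, d0, pr)))
  expect_equal(apply(prior_draws, 2, sd), c(2, 2), tolerance = 0.1,
               ignore_attr = TRUE)
})

test_that("sigma's auxiliary scheme marginalizes to the right conditional", {
  # given (ystar, lambda, beta), alternating the two inverse-gamma draws
  # targets p(sigma | rest) = half-Cauchy(A) x normal likelihood
  set.seed(9)
  n <- 6
  X <- matrix(1, n, 1)
  eps <- c(-0.8, 0.3, 1.2, -0.4, 0.05, 0.6)
  lambda <- c(1, 0.5, 2, 1, 1.2, 0.7)
  A <- 1.5
  pr <- prior_config(sigma_scale = A)
  d <- censored_data(eps, rep("observed", n), X)
  st <- list(beta = 0, lambda = lambda, ystar = eps, a_aux = 1)
  draws <- numeric(20000)
  for (i in seq_along(draws)) {
    sg <- update_sigma(st, d, pr)
    st$a_aux <- sg$a_aux
    draws[i] <- sg$sigma
  }
  # oracle: 1-d quadrature of the exact conditional density
  dens <- function(s) {
    sapply(s, function(si)
      exp(log(2) + dcauchy(si, 0, A, log = TRUE) +
            sum(dnorm(eps, 0, si / sqrt(lambda), log = TRUE))))
  }
  nc <- integrate(dens, 0, Inf)$value
  cdf <- function(s) integrate(dens, 0, s)$value / nc
  qs <- quantile(draws, c(0.1, 0.25, 0.5, 0.75, 0.9))
  for (q in qs) {
    p_emp <- mean(draws <= q)
    expect_equal(cdf(q), p_emp, tolerance = 0.02)
  }
})

test_that("nu update is a valid Metropolis kernel that recovers truth", {
  # zero-width proposal is always accepted (MH identity)
  st <- list(nu = 4, lambda = rep(1, 10))
  up <- update_nu(st, prior_config(), mh_step = 0)
  expect_true(up$accepted)
  expect_equal(up$nu, 4)
  # recovery: lambda drawn at nu0 concentrates the conditional near nu0
  set.seed(10)
  nu0 <- 6
  lam <- rgamma(2000, nu0 / 2, rate = nu0 / 2)
  st <- list(nu = 4, lambda = lam)
  pr <- prior_config()
  chain <- numeric(3000)
  for (i in seq_along(chain)) {
    st <- c(update_nu(st, pr, 0.3)["nu"], list(lambda = lam))
    chain[i] <- st$nu
  }
  post_mean <- mean(chain[-(1:500)])
  # oracle: 1-d grid posterior over nu given the same lambda
  nus <- seq(2.05, 20, by = 0.005)
  lp <- sapply(nus, function(v)
    dgamma(v, pr$nu_shape, pr$nu_rate, log = TRUE) +
      sum(dgamma(lam, v / 2, rate = v / 2, log = TRUE)))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  grid_mean <- sum(w * nus)
  expect_equal(post_mean, grid_mean, tolerance = 0.15 * grid_mean)
  expect_lt(abs(grid_mean - nu0), 0.15 * nu0)
})

test_that("the full sampler is deterministic and family-consistent", {
  d <- generate_dataset(sim_config(n = 80, censor_rate = 0.2, seed = 2),
                        seed = 2)
  cau <- run_quick_fit(d, error_family("cauchy"), seed = 3)
  cau2 <- run_quick_fit(d, error_family("cauchy"), seed = 3)
  expect_identical(cau$chains, cau2$chains)
  expect_identical(cau$loglik, cau2$loglik)
  # cauchy == student_t with nu fixed at 1, draw for draw
  t1 <- run_quick_fit(d, error_family("student_t", nu = 1), seed = 3)
  expect_equal(unname(cau$chains[[1]]), unname(t1$chains[[1]]))
  expect_equal(cau$loglik, t1$loglik)
})

test_that("row permutation permutes loglik columns", {
  d <- generate_dataset(sim_config(n = 40, censor_rate = 0.2, seed = 4),
                        seed = 4)
  perm <- sample(d$n)
  dp <- censored_data(d$y[perm], d$status[perm], d$X[perm, ],
                      names = d$names)
  beta <- c(1, 2, -1)
  expect_equal(pointwise_loglik(dp, beta, 1.2,
                                error_family("student_t", nu = 3)),
               pointwise_loglik(d, beta, 1.2,
                                error_family("student_t", nu = 3))[perm])
})

test_that("without censoring the sampler matches least squares", {
  set.seed(11)
  n <- 200
  X <- cbind(1, runif(n, -1, 1), rbinom(n, 1, 0.5))
  y <- drop(X %*% c(1, 2, -1)) + rnorm(n)
  d <- censored_data(y, rep("observed", n), X,
                     names = c("Intercept", "x1", "x2"))
  # imputation is the identity with no censored rows
  st <- list(beta = c(1, 2, -1), sigma = 1, lambda = rep(1, n), ystar = y)
  expect_identical(impute_censored(st, d), y)
  fit <- run_quick_fit(d, error_family("normal"), seed = 5,
                       iterations = 1000, warmup = 500)
  s <- summary(fit)
  ols <- coef(lm(y ~ X - 1))
  for (i in 1:3)
    expect_lt(abs(s$Estimate[i] - ols[i]), 3 * s$Est_Error[i])
})

test_that("degenerate all-censored data warns but still runs", {
  X <- toy_X(10)
  d <- censored_data(rep(2, 10), rep("right", 10), X)
  expect_warning(
    fit <- run_quick_fit(d, error_family("normal"), iterations = 200,
                         warmup = 100),
    "censored")
  expect_true(all(is.finite(posterior_draws(fit))))
})
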