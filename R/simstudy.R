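#' Simulation-study configuration
#'
#' Describes one cell of the simulation design: data are generated from
#' \eqn{y^* = \beta_0 + \beta_1 x_1 + \beta_2 x_2 + \epsilon} with
#' \eqn{x_1 \sim} Uniform(-1, 1), \eqn{x_2 \sim} Bernoulli(0.5) and
#' \eqn{\epsilon} from the chosen symmetric family scaled by
#' \code{sigma_true}, then right-censored at the empirical
#' \eqn{(1 - censor\_rate)} quantile of the replicate's latent responses.
#' Defaults follow the study design: \eqn{\beta = (1, 2, -1)},
#' \eqn{\sigma = 1}, \eqn{n = 300}, Student-t errors with \eqn{\nu = 3}.
#'
#' @param beta_true true coefficient vector (intercept first).
#' @param sigma_true true error scale.
#' @param family_true generating [error_family()] (needs a concrete
#'   \code{nu} for \code{"student_t"}).
#' @param n sample size per replicate.
#' @param censor_rate target right-censoring fraction in \eqn{[0, 0.95]}.
#' @param replications number of replicate datasets.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(beta_true = c(1, 2, -1), sigma_true = 1,
                       family_true = error_family("student_t", nu = 3),
                       n = 300, censor_rate = 0.1, replications = 1000,
                       seed = 1) {
  stopifnot(sigma_true > 0, inherits(family_true, "error_family"),
            n >= length(beta_true) + 2, replications >= 1)
  if (censor_rate < 0 || censor_rate > 0.95)
    stop("censor_rate must be in [0, 0.95]", call. = FALSE)
  if (family_true$family == "student_t" && is.na(family_true$nu))
    stop("family_true needs a concrete nu", call. = FALSE)
  structure(list(beta_true = beta_true, sigma_true = sigma_true,
                 family_true = family_true, n = as.integer(n),
                 censor_rate = censor_rate,
                 replications = as.integer(replications),
                 seed = as.integer(seed)),
            class = "sim_config")
}

r_errors <- function(n, fam, sigma) {
  switch(fam$family,
    normal = stats::rnorm(n, 0, sigma),
    sigma * stats::rt(n, df = fam$nu))
}

#' Generate one censored replicate dataset
#'
#' Draws covariates and errors under the configuration, forms the latent
#' responses, and right-censors the \eqn{\lceil n \cdot censor\_rate
#' \rceil} largest at the empirical threshold (the smallest censored
#' latent value), so the realized censoring fraction is exact.  The latent
#' truth is attached for scoring.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed for this replicate.
#' @return a [censored_data()] with attributes \code{truth} (list with
#'   \code{beta}, \code{sigma}, \code{ystar}, \code{threshold}).
#' @export
generate_dataset <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed))
  n <- cfg$n
  x1 <- stats::runif(n, -1, 1)
  x2 <- stats::rbinom(n, 1, 0.5)
  X <- cbind(Intercept = 1, x1 = x1, x2 = x2)
  ystar <- drop(X %*% cfg$beta_true) +
    r_errors(n, cfg$family_true, cfg$sigma_true)
  k <- ceiling(n * cfg$censor_rate)
  if (k > 0) {
    thr <- sort(ystar, decreasing = TRUE)[k]
    cens <- ystar >= thr
    y <- ifelse(cens, thr, ystar)
    status <- ifelse(cens, "right", "observed")
  } else {
    thr <- Inf
    y <- ystar
    status <- rep("observed", n)
  }
  # the threshold is a design constant, so it bounds every unit's
  # observation window, not just the rows that happened to be censored
  out <- censored_data(y, status, X, lower = rep(-Inf, n),
                       upper = rep(thr, n), names = colnames(X))
  attr(out, "truth") <- list(beta = cfg$beta_true, sigma = cfg$sigma_true,
                             ystar = ystar, threshold = thr)
  out
}

replicate_seeds <- function(master, R) {
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, R)
}

#' Run replicated fits and score frequentist operating characteristics
#'
#' For each replicate: generate a dataset under \code{cfg}, fit
#' \code{fit_family} with [run_mcmc()], summarize, and record the
#' posterior mean, 95\% interval and coverage of the truth for each
#' regression coefficient.  Replicates whose fit errors are excluded; more
#' than 1\% failures aborts (a systematic problem, not bad luck).
#'
#' @param cfg a [sim_config()].
#' @param fit_family [error_family()] to fit (defaults to the generating
#'   family).
#' @param prior a [prior_config()].
#' @param sampler_cfg a [sampler_config()]; per-replicate seeds override
#'   its \code{seed}.
#' @param level credible level for coverage (default 0.95).
#' @return list with \code{metrics} (the aggregated
#'   bias/RMSE/coverage/width table from [metrics_table()]),
#'   \code{records} (one row per replicate and parameter) and
#'   \code{n_failed}.
#' @export
run_replications <- function(cfg, fit_family = cfg$family_true,
                             prior = prior_config(),
                             sampler_cfg = sampler_config(chains = 2),
                             level = 0.95) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- replicate_seeds(cfg$seed, cfg$replications)
  recs <- vector("list", cfg$replications)
  n_failed <- 0L
  pnames <- paste0("b_", c("Intercept", "x1", "x2"))
  for (r in seq_len(cfg$replications)) {
    res <- tryCatch({
      d <- generate_dataset(cfg, seed = seeds[r])
      scfg <- sampler_cfg
      scfg$seed <- seeds[r]
      fit <- run_mcmc(d, fit_family, prior, scfg, compute_loglik = FALSE)
      s <- summary(fit, level = level)
      s <- s[match(pnames, s$Parameter), ]
      data.frame(replicate = r,
                 parameter = pnames,
                 truth = cfg$beta_true,
                 estimate = s$Estimate,
                 ci_lower = s$CI_Lower, ci_upper = s$CI_Upper,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("replicate ", r, " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L else recs[[r]] <- res
  }
  if (n_failed > max(1L, ceiling(0.01 * cfg$replications)))
    stop(n_failed, " of ", cfg$replications,
         " replicates failed (> 1%): systematic problem", call. = FALSE)
  records <- do.call(rbind, recs)
  list(metrics = metrics_table(records), records = records,
       n_failed = n_failed)
}

#' Aggregate per-replicate records into a metrics table
#'
#' Computes, per parameter: \code{Bias} (mean of posterior mean minus
#' truth), \code{RMSE} (root mean squared error of the posterior means),
#' \code{Coverage} (fraction of replicates whose interval contains the
#' truth) and \code{CI_Width} (mean interval width).
#'
#' @param records data.frame with columns \code{parameter}, \code{truth},
#'   \code{estimate}, \code{ci_lower}, \code{ci_upper} (as produced by
#'   [run_replications()]).
#' @return data.frame with one row per parameter and columns Parameter,
#'   Bias, RMSE, Coverage, CI_Width, R.
#' @export
metrics_table <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  out <- do.call(rbind, lapply(split(records, records$parameter), function(g) {
    err <- g$estimate - g$truth
    data.frame(Parameter = g$parameter[1L],
               Bias = mean(err),
               RMSE = sqrt(mean(err^2)),
               Coverage = mean(g$ci_lower <= g$truth & g$truth <= g$ci_upper),
               CI_Width = mean(g$ci_upper - g$ci_lower),
               R = nrow(g),
               stringsAsFactors = FALSE)
  }))
  out <- out[match(unique(records$parameter), out$Parameter), ]
  rownames(out) <- NULL
  out
}
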