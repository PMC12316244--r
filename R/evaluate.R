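# Predictive model assessment: lppd, WAIC, PSIS-LOO and posterior
# predictive checks, all driven by the draws-by-n pointwise observed-data
# log-likelihood matrix stored on a fit.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

check_loglik <- function(loglik) {
  if (is.null(loglik) || !is.matrix(loglik) || nrow(loglik) < 1L)
    stop("loglik must be a draws-by-n matrix with at least one draw",
         call. = FALSE)
  if (any(!is.finite(loglik)))
    stop("loglik contains non-finite entries", call. = FALSE)
  loglik
}

#' Log pointwise predictive density
#'
#' \eqn{lppd = \sum_i \log( \frac{1}{S}\sum_s \exp(\ell_{si}) )}, computed
#' with log-sum-exp for stability.
#'
#' @param loglik draws-by-observations matrix of pointwise log-likelihoods.
#' @return a single number.
#' @export
lppd <- function(loglik) {
  loglik <- check_loglik(loglik)
  S <- nrow(loglik)
  sum(apply(loglik, 2L, logsumexp) - log(S))
}

#' Widely applicable information criterion
#'
#' \eqn{WAIC = -2(lppd - pWAIC)} where \eqn{pWAIC} is the summed
#' posterior variance of the pointwise log-likelihoods (the effective
#' number of parameters).  \code{LPD} is the in-sample log predictive
#' density, equal to [lppd()].
#'
#' @inheritParams lppd
#' @return a list with elements \code{WAIC}, \code{pWAIC}, \code{LPD}.
#' @export
waic <- function(loglik) {
  loglik <- check_loglik(loglik)
  lp <- lppd(loglik)
  if (nrow(loglik) < 2L) {
    warning("single draw: pWAIC is 0 by construction", call. = FALSE)
    p <- 0
  } else {
    p <- sum(apply(loglik, 2L, stats::var))
  }
  list(WAIC = -2 * (lp - p), pWAIC = p, LPD = lp)
}

#' Fit a generalized Pareto tail
#'
#' Profile-posterior-mean estimate (Zhang--Stephens) of the generalized
#' Pareto shape \eqn{k} and scale \eqn{\sigma} from a sample of positive
#' exceedances, with the standard small-sample shape regularization
#' (shrinking \eqn{k} toward 0.5 with prior weight 10).  Sign convention:
#' \eqn{k > 0} is a heavy (polynomial) tail, \eqn{k = 0} exponential.
#'
#' @param x positive exceedances over the tail threshold (at least 5).
#' @param wip apply the weakly-informative shape prior (default
#'   \code{TRUE}).
#' @return list with \code{k} and \code{sigma} (\code{k = NaN} for a
#'   degenerate all-equal sample).
#' @export
gpd_fit <- function(x, wip = TRUE) {
  x <- sort(as.numeric(x))
  N <- length(x)
  if (N < 5L) stop("need at least 5 exceedances", call. = FALSE)
  if (x[1L] < 0) stop("exceedances must be positive", call. = FALSE)
  if (x[N] <= x[1L]) return(list(k = NaN, sigma = NaN))
  M <- 30L + floor(sqrt(N))
  jj <- seq_len(M)
  xstar <- x[max(1L, floor(N / 4 + 0.5))]
  theta <- 1 / x[N] + (1 - sqrt(M / (jj - 0.5))) / (3 * xstar)
  k_of <- function(b) -mean(log1p(-b * x))
  ks <- vapply(theta, k_of, 0)
  L <- N * (log(theta / ks) + ks - 1)
  w <- 1 / vapply(jj, function(j) sum(exp(L - L[j])), 0)
  b_hat <- sum(theta * w)
  k_zs <- k_of(b_hat)            # Zhang-Stephens sign: -xi
  sigma <- k_zs / b_hat
  k <- -k_zs                     # usual shape: positive = heavy tail
  if (wip) k <- (N * k + 10 * 0.5) / (N + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' For each observation the raw importance ratios
#' \eqn{r_s \propto \exp(-\ell_{si})} are stabilized by fitting a
#' generalized Pareto distribution to the \eqn{M = \min(0.2 S, 3\sqrt S)}
#' largest ratios and replacing them with expected order statistics of the
#' fitted tail; weights are truncated at the largest raw ratio.  The
#' leave-one-out predictive density is then the weighted posterior average
#' of the pointwise likelihood.
#'
#' @inheritParams lppd
#' @return list with \code{elpd_LOO}, \code{pLOO}, \code{LOOIC},
#'   per-observation \code{pareto_k}, per-observation \code{elpd_i} and a
#'   logical \code{flagged} vector marking \code{pareto_k > 0.7}.
#' @export
psis_loo <- function(loglik) {
  loglik <- check_loglik(loglik)
  S <- nrow(loglik)
  n <- ncol(loglik)
  if (S < 100L)
    warning("fewer than 100 draws: PSIS-LOO is unreliable", call. = FALSE)
  M <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  elpd_i <- numeric(n)
  pareto_k <- rep(NaN, n)
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    lw <- -ll
    lw <- lw - max(lw)
    if (M >= 5L && S > M) {
      ord <- order(lw)
      tail_idx <- ord[seq.int(S - M + 1L, S)]
      cut <- exp(lw[ord[S - M]])
      exceed <- exp(lw[tail_idx]) - cut
      if (max(exceed) > 0) {
        fit <- gpd_fit(exceed)
        if (is.finite(fit$k)) {
          pareto_k[i] <- fit$k
          sm <- log(cut + vapply((seq_len(M) - 0.5) / M, qgpd, 0,
                                 k = fit$k, sigma = fit$sigma))
          lw[tail_idx[order(lw[tail_idx])]] <- sm
        }
      }
      lw <- pmin(lw, 0)  # truncate at the largest raw weight
    }
    elpd_i[i] <- logsumexp(lw + ll) - logsumexp(lw)
  }
  elpd <- sum(elpd_i)
  list(elpd_LOO = elpd, pLOO = lppd(loglik) - elpd, LOOIC = -2 * elpd,
       pareto_k = pareto_k, elpd_i = elpd_i,
       flagged = !is.nan(pareto_k) & pareto_k > 0.7)
}

#' Posterior predictive check
#'
#' Simulates replicated response vectors from the fitted model: for each
#' replicate a posterior draw \eqn{(\beta, \sigma, \nu)} is selected, a
#' latent response is generated from the fitted error family, and the
#' dataset's censoring bounds are applied.  Observed-vs-replicated
#' discrepancies are reported for the mean, SD, maximum and censoring
#' fraction.
#'
#' @param fit a \code{symcens_fit}.
#' @param data the [censored_data()] the model was fit to.
#' @param n_rep number of replicated datasets (default 200).
#' @param seed integer seed.
#' @return list with \code{replicated} (n_rep-by-4 matrix of summaries),
#'   \code{observed} (the same summaries of the data) and \code{p_value}
#'   (two-sided tail probabilities of the observed summaries under the
#'   replicates).
#' @export
posterior_predictive <- function(fit, data, n_rep = 200, seed = 1) {
  stopifnot(inherits(fit, "symcens_fit"), inherits(data, "censored_data"))
  if (fit$n_obs != data$n || length(fit$data_names) != data$p)
    stop("fit and data are dimensionally inconsistent", call. = FALSE)
  set.seed(as.integer(seed))
  draws <- posterior_draws(fit)
  idx <- sample.int(nrow(draws), n_rep, replace = TRUE)
  fam <- fit$family
  stats_of <- function(y, cens_frac) c(mean = mean(y), sd = stats::sd(y),
                                       max = max(y), cens = cens_frac)
  bcols <- seq_len(data$p)
  rep_stats <- matrix(NA_real_, n_rep, 4,
                      dimnames = list(NULL, c("mean", "sd", "max", "cens")))
  for (r in seq_len(n_rep)) {
    th <- draws[idx[r], ]
    sigma <- th[["sigma"]]
    eps <- if (fam$family == "normal") stats::rnorm(data$n, 0, sigma)
      else sigma * stats::rt(data$n, df = if (fit$free_nu) th[["nu"]]
                                          else fixed_nu(fam, fit$prior))
    ystar <- drop(data$X %*% th[bcols]) + eps
    cens <- ystar >= data$upper | ystar <= data$lower
    yrep <- pmin(pmax(ystar, data$lower), data$upper)
    rep_stats[r, ] <- stats_of(yrep, mean(cens))
  }
  obs <- stats_of(data$y, mean(data$status != "observed"))
  pv <- vapply(colnames(rep_stats), function(s) {
    lo <- mean(rep_stats[, s] <= obs[[s]])
    2 * min(lo, 1 - lo)
  }, 0)
  list(replicated = rep_stats, observed = obs, p_value = pv)
}

#' Fit and compare several error families on one dataset
#'
#' Fits each family to the same data with [run_mcmc()] (identical
#' configuration and seed) and assembles LPD, WAIC, pWAIC, elpd_LOO, pLOO
#' and LOOIC per model.  A family whose fit fails is marked failed and the
#' others proceed.
#'
#' @param data a [censored_data()].
#' @param families list of [error_family()] objects (at least 2 for a
#'   meaningful comparison; 1 is allowed).
#' @param prior a [prior_config()].
#' @param cfg a [sampler_config()].
#' @return a \code{comparison_report}: data.frame with columns Model, LPD,
#'   WAIC, pWAIC, elpd_LOO, pLOO, LOOIC, failed, plus attributes
#'   \code{pareto_k} (per-model list) and \code{fits}.
#' @export
compare_models <- function(data, families, prior = prior_config(),
                           cfg = sampler_config()) {
  stopifnot(length(families) >= 1L)
  rows <- vector("list", length(families))
  kl <- vector("list", length(families))
  fits <- vector("list", length(families))
  for (j in seq_along(families)) {
    fam <- families[[j]]
    label <- fam$family
    res <- tryCatch({
      fit <- run_mcmc(data, fam, prior, cfg, compute_loglik = TRUE)
      w <- waic(fit$loglik)
      l <- psis_loo(fit$loglik)
      fits[[j]] <- fit
      kl[[j]] <- l$pareto_k
      data.frame(Model = label, LPD = w$LPD, WAIC = w$WAIC,
                 pWAIC = w$pWAIC, elpd_LOO = l$elpd_LOO, pLOO = l$pLOO,
                 LOOIC = l$LOOIC, failed = FALSE, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("fit failed for family ", label, ": ", conditionMessage(e),
              call. = FALSE)
      data.frame(Model = label, LPD = NA_real_, WAIC = NA_real_,
                 pWAIC = NA_real_, elpd_LOO = NA_real_, pLOO = NA_real_,
                 LOOIC = NA_real_, failed = TRUE, stringsAsFactors = FALSE)
    })
    rows[[j]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(kl) <- names(fits) <- out$Model
  attr(out, "pareto_k") <- kl
  attr(out, "fits") <- fits
  class(out) <- c("comparison_report", class(out))
  out
}

#' Write a model-comparison report to CSV or JSON
#'
#' @param report a \code{comparison_report} from [compare_models()].
#' @param path output path; \code{.json} writes JSON, otherwise CSV.
#' @return \code{path}, invisibly.
#' @export
write_comparison <- function(report, path) {
  df <- as.data.frame(report)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  else
    utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
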