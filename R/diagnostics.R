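# Convergence diagnostics: rank-normalized split-Rhat and bulk/tail
# effective sample size, following the modern (rank-based) definitions.
# Draws for one scalar parameter are an iterations-by-chains matrix.

as_draws_mat <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

split_chains <- function(x) {
  x <- as_draws_mat(x)
  N <- nrow(x)
  half <- N %/% 2L
  cbind(x[seq_len(half), , drop = FALSE],
        x[seq.int(N - half + 1L, N), , drop = FALSE])
}

# joint inverse-normal rank transform (average ranks for ties)
z_scale <- function(x) {
  x <- as_draws_mat(x)
  S <- length(x)
  z <- stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (S + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

rhat_mat <- function(x) {
  N <- nrow(x); M <- ncol(x)
  if (N < 2L || M < 2L) return(NaN)
  means <- colMeans(x)
  vars <- apply(x, 2L, stats::var)
  W <- mean(vars)
  B <- N * stats::var(means)
  if (!is.finite(W) || W == 0) {
    warning("constant draws: Rhat undefined", call. = FALSE)
    return(NaN)
  }
  sqrt(((N - 1) / N * W + B / N) / W)
}

ess_mat <- function(x) {
  N <- nrow(x); M <- ncol(x)
  if (N < 4L) return(NaN)
  acov <- apply(x, 2L, function(v) {
    Mft <- 2^ceiling(log2(2 * N))
    vc <- v - mean(v)
    f <- stats::fft(c(vc, rep(0, Mft - N)))
    Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(N)] / (Mft * N)
  })
  acov <- matrix(acov, N, M)
  chain_var <- acov[1L, ] * N / (N - 1)
  mean_var <- mean(chain_var)
  if (!is.finite(mean_var) || mean_var == 0) {
    warning("constant draws: ESS undefined", call. = FALSE)
    return(NaN)
  }
  var_plus <- mean_var * (N - 1) / N
  if (M > 1L) var_plus <- var_plus + stats::var(colMeans(x))
  rho <- rep(0, N)
  t <- 1L
  rho_even <- 1
  rho[1L] <- 1
  rho_odd <- 1 - (mean_var - mean(acov[2L, ])) / var_plus
  rho[2L] <- rho_odd
  while (t < N - 4L && !is.nan(rho_even + rho_odd) &&
         (rho_even + rho_odd) > 0) {
    t <- t + 2L
    rho_even <- 1 - (mean_var - mean(acov[t, ])) / var_plus
    rho_odd <- 1 - (mean_var - mean(acov[t + 1L, ])) / var_plus
    if ((rho_even + rho_odd) >= 0) {
      rho[t] <- rho_even
      rho[t + 1L] <- rho_odd
    }
  }
  max_t <- t
  if (rho_even > 0) rho[max_t + 1L] <- rho_even
  # enforce monotone decreasing pair sums
  t <- 1L
  while (t <= max_t - 4L) {
    t <- t + 2L
    if (rho[t] + rho[t + 1L] > rho[t - 2L] + rho[t - 1L]) {
      rho[t] <- (rho[t - 2L] + rho[t - 1L]) / 2
      rho[t + 1L] <- rho[t]
    }
  }
  S <- M * N
  tau <- -1 + 2 * sum(rho[seq_len(max_t)]) + rho[max_t + 1L]
  tau <- max(tau, 1 / log10(S))
  S / tau
}

#' Rank-normalized split-Rhat
#'
#' Potential scale reduction factor on half-chains after a joint
#' inverse-normal rank transform: each chain is split in half, all draws
#' are rank-normalized together, and
#' \eqn{\hat R = \sqrt{((N-1)/N \cdot W + B/N)/W}} is computed on the
#' transformed half-chains.  Values near 1 indicate convergence.
#'
#' @param x iterations-by-chains matrix (a vector is treated as one
#'   chain and split).
#' @return a single number; \code{NaN} with a warning when the draws are
#'   constant.
#' @export
split_rhat <- function(x) {
  rhat_mat(z_scale(split_chains(x)))
}

#' Bulk and tail effective sample size
#'
#' \code{ess_bulk()} is the effective sample size of the rank-normalized
#' split chains, using Geyer's initial-monotone-positive-sequence
#' truncation of the combined autocorrelation estimate.  \code{ess_tail()}
#' is the minimum of the effective sample sizes of the indicator
#' sequences \eqn{I(x \le q_{0.05})} and \eqn{I(x \ge q_{0.95})}, which
#' measures how well the chain resolves the distribution's tails.
#'
#' @inheritParams split_rhat
#' @return a single number (may exceed the number of draws for
#'   antithetic chains).
#' @export
ess_bulk <- function(x) {
  ess_mat(z_scale(split_chains(x)))
}

#' @rdname ess_bulk
#' @export
ess_tail <- function(x) {
  x <- as_draws_mat(x)
  q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  e1 <- ess_mat(split_chains(matrix(as.numeric(x <= q[1L]),
                                    nrow(x), ncol(x))))
  e2 <- ess_mat(split_chains(matrix(as.numeric(x >= q[2L]),
                                    nrow(x), ncol(x))))
  min(e1, e2)
}

#' Posterior summary table
#'
#' One row per model parameter with the posterior mean (\code{Estimate}),
#' posterior SD (\code{Est_Error}), equal-tailed credible bounds
#' (\code{CI_Lower}, \code{CI_Upper}), rank-normalized split-Rhat and
#' bulk/tail effective sample sizes.
#'
#' @param object a \code{symcens_fit} from [run_mcmc()].
#' @param level credible level (default 0.95, equal-tailed).
#' @param ... unused.
#' @return a data.frame with columns Parameter, Estimate, Est_Error,
#'   CI_Lower, CI_Upper, Rhat, Bulk_ESS, Tail_ESS.
#' @export
summary.symcens_fit <- function(object, level = 0.95, ...) {
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  rows <- lapply(object$par_names, function(par) {
    m <- posterior_draws(object, par)
    pooled <- as.numeric(m)
    ci <- stats::quantile(pooled, probs, names = FALSE)
    single <- length(pooled) < 2L
    data.frame(
      Parameter = par,
      Estimate = mean(pooled),
      Est_Error = if (single) 0 else stats::sd(pooled),
      CI_Lower = ci[1L], CI_Upper = ci[2L],
      Rhat = if (single) NaN else suppressWarnings(split_rhat(m)),
      Bulk_ESS = if (single) NaN else suppressWarnings(ess_bulk(m)),
      Tail_ESS = if (single) NaN else suppressWarnings(ess_tail(m)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a posterior summary table to CSV or JSON
#'
#' @param summary_df a data.frame as returned by
#'   \code{summary.symcens_fit}.
#' @param path output path; format chosen by extension (\code{.json}
#'   writes JSON, anything else CSV).
#' @return \code{path}, invisibly.
#' @export
write_summary <- function(summary_df, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(summary_df, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  else
    utils::write.csv(summary_df, path, row.names = FALSE)
  invisible(path)
}
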