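#' Censored regression dataset
#'
#' Container for a continuous response observed subject to left- or
#' right-censoring, together with its covariate matrix.  Each observation
#' carries a status code (\code{"observed"}, \code{"left"}, \code{"right"})
#' and an observable interval \code{(lower, upper)}; infinite bounds are
#' encoded as \code{-Inf}/\code{Inf} sentinels so the likelihood
#' case-dispatch stays branch-free.  For a left-censored row the recorded
#' response equals \code{lower}; for a right-censored row it equals
#' \code{upper}.
#'
#' @param y numeric response vector.
#' @param status character or factor with levels observed/left/right, or
#'   integer codes 0/1/2 in that order.
#' @param X covariate matrix (including an intercept column if wanted),
#'   \code{nrow(X) == length(y)}; all entries finite.
#' @param lower,upper optional bound vectors; defaults place the censoring
#'   bound at \code{y} for censored rows and \code{-Inf}/\code{Inf}
#'   elsewhere.
#' @param names optional covariate labels (defaults to \code{colnames(X)}).
#' @return an object of class \code{"censored_data"}: a list with elements
#'   \code{y}, \code{status}, \code{lower}, \code{upper}, \code{X},
#'   \code{names}, \code{n}, \code{p}.
#' @examples
#' X <- cbind(Intercept = 1, x = c(-1, 0, 1))
#' censored_data(c(0.2, 1.5, 2), c("observed", "observed", "right"), X)
#' @export
censored_data <- function(y, status, X, lower = NULL, upper = NULL,
                          names = colnames(X)) {
  status <- parse_status(status)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(y)
  if (length(status) != n || nrow(X) != n)
    stop("y, status and X must have matching lengths/rows", call. = FALSE)
  if (n < 1L) stop("need at least one observation", call. = FALSE)
  if (any(!is.finite(X)))
    stop("X contains non-finite entries (first at row ",
         which(rowSums(!is.finite(X)) > 0)[1L], ")", call. = FALSE)
  if (is.null(lower)) lower <- ifelse(status == "left", y, -Inf)
  if (is.null(upper)) upper <- ifelse(status == "right", y, Inf)
  if (is.null(names)) names <- paste0("x", seq_len(ncol(X)))
  out <- structure(
    list(y = as.numeric(y), status = status,
         lower = as.numeric(lower), upper = as.numeric(upper),
         X = X, names = names, n = n, p = ncol(X)),
    class = "censored_data")
  validate_censored_data(out)
  out
}

parse_status <- function(status) {
  codes <- c("observed", "left", "right")
  if (is.numeric(status)) {
    bad <- !status %in% 0:2
    if (any(bad))
      stop("unparseable status code at row ", which(bad)[1L], call. = FALSE)
    return(codes[status + 1L])
  }
  status <- as.character(status)
  bad <- !status %in% codes
  if (any(bad))
    stop("unparseable status '", status[which(bad)[1L]], "' at row ",
         which(bad)[1L], call. = FALSE)
  status
}

validate_censored_data <- function(d) {
  fail <- function(i, what)
    stop("invalid censored_data at row ", i, ": ", what, call. = FALSE)
  bothfin <- is.finite(d$lower) & is.finite(d$upper)
  bad <- bothfin & d$lower >= d$upper
  if (any(bad)) fail(which(bad)[1L], "lower >= upper")
  obs <- d$status == "observed"
  bad <- obs & ((is.finite(d$lower) & d$y <= d$lower) |
                  (is.finite(d$upper) & d$y >= d$upper))
  if (any(bad)) fail(which(bad)[1L], "observed y outside (lower, upper)")
  bad <- d$status == "left" & d$y != d$lower
  if (any(bad)) fail(which(bad)[1L], "left-censored y must equal lower")
  bad <- d$status == "right" & d$y != d$upper
  if (any(bad)) fail(which(bad)[1L], "right-censored y must equal upper")
  invisible(d)
}

#' @export
print.censored_data <- function(x, ...) {
  tab <- table(factor(x$status, c("observed", "left", "right")))
  cat(sprintf(
    "<censored_data: n = %d, p = %d (%d observed, %d left, %d right)>\n",
    x$n, x$p, tab[1L], tab[2L], tab[3L]))
  invisible(x)
}

#' Read a censored dataset from a delimited file
#'
#' Reads a header-ed CSV, maps the status column to observed/left/right
#' (text labels or integer codes 0/1/2), stores censoring bounds, and
#' assembles the covariate matrix.
#'
#' @param path CSV file path.
#' @param response name of the response column.
#' @param status_col name of the censoring-status column.
#' @param covariates character vector of covariate column names.
#' @param add_intercept prepend a column of ones (default \code{TRUE}).
#' @return a [censored_data()] object.
#' @export
read_censored_csv <- function(path, response, status_col, covariates,
                              add_intercept = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(response, status_col, covariates)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(df[covariates])
  nm <- covariates
  if (add_intercept) {
    X <- cbind(Intercept = 1, X)
    nm <- c("Intercept", nm)
  }
  colnames(X) <- nm
  censored_data(df[[response]], df[[status_col]], X, names = nm)
}

#' Write a censored dataset to CSV
#'
#' Inverse of [read_censored_csv()]: one row per observation with the
#' response, status label and covariate columns (the intercept column, if
#' present, is dropped and restored on re-read).
#'
#' @param data a [censored_data()] object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_censored_csv <- function(data, path) {
  keep <- data$names != "Intercept"
  df <- data.frame(y = data$y, status = data$status,
                   data$X[, keep, drop = FALSE], check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Adapter for survival-time CSVs in the lung-cancer layout
#'
#' Maps a CSV with columns \code{time}, \code{status} (1 = censored,
#' 2 = dead), \code{age}, \code{sex}, \code{ph.ecog} to a right-censored
#' regression dataset.  Status 2 becomes an observed response; status 1 a
#' right-censored one with the bound at the recorded time.  Survival times
#' are log-transformed by default (regression on the log-day scale keeps
#' the symmetric-error assumption tenable for positive, skewed times); rows
#' with missing \code{ph.ecog} are dropped and the count is reported via
#' \code{message()} and the \code{"n_dropped"} attribute.
#'
#' @param path CSV file path.
#' @param log_transform log-transform the survival time (default
#'   \code{TRUE}).
#' @return a [censored_data()] with covariates Intercept, age, sex,
#'   ph.ecog and attribute \code{n_dropped}.
#' @export
lung_adapter <- function(path, log_transform = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "status", "age", "sex", "ph.ecog")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- !df$status %in% c(1, 2)
  if (any(bad))
    stop("unknown status code ", df$status[which(bad)[1L]], " at row ",
         which(bad)[1L], call. = FALSE)
  keep <- !is.na(df$ph.ecog)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("lung_adapter: dropped ", n_dropped, " row(s) with missing ph.ecog")
  df <- df[keep, , drop = FALSE]
  y <- if (log_transform) log(df$time) else df$time
  status <- ifelse(df$status == 2, "observed", "right")
  X <- cbind(Intercept = 1, age = df$age, sex = df$sex, ph.ecog = df$ph.ecog)
  out <- censored_data(y, status, X, names = colnames(X))
  attr(out, "n_dropped") <- n_dropped
  out
}
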