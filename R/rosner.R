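#' Generalized ESD (Rosner) outlier test with high-side capping
#'
#' Identifies up to `max_k` outliers with the generalized extreme studentized
#' deviate test, then replaces flagged values that lie above the sample mean
#' (high-side outliers) with the 95th percentile of the full, pre-capping
#' sample. Low-side outliers are reported but left unchanged: the capping is
#' meant to tame extreme large values before log-scale curve fitting, and
#' small values carry real signal.
#'
#' The test iteratively removes the observation with the largest absolute
#' studentized deviation and compares each deviation statistic
#' \eqn{R_i} against its critical value
#' \eqn{\lambda_i = (n-i) t_{p,n-i-1} / \sqrt{(n-i-1+t^2)(n-i+1)}} with
#' \eqn{p = 1 - \alpha / (2(n-i+1))}; the number of outliers is the largest
#' \eqn{i} with \eqn{R_i > \lambda_i}.
#'
#' @param values Numeric vector, all finite.
#' @param alpha Significance level of the test (default 0.05).
#' @param max_k Maximum number of outlier candidates; default
#'   `max(1, ceiling(0.05 * length(values)))`.
#' @param cap_quantile Quantile of the full sample used as the cap
#'   (default 0.95, linear-interpolation definition).
#' @param min_n Below this sample size the test is skipped with a warning and
#'   the input is returned unchanged (default 10).
#' @return List of class `"rosner_cap"`: `values` (capped vector),
#'   `outliers` (indices flagged by the test), `capped` (indices actually
#'   replaced), `cap_value` (the percentile used, `NA` if nothing capped),
#'   `skipped` (logical, `TRUE` when `n < min_n`).
#' @examples
#' x <- c(rnorm(29), 50)
#' rosner_cap(x)$capped
#' @export
rosner_cap <- function(values, alpha = 0.05,
                       max_k = max(1L, ceiling(0.05 * length(values))),
                       cap_quantile = 0.95, min_n = 10L) {
  if (any(!is.finite(values))) stop("values must all be finite")
  stopifnot(alpha > 0, alpha < 1, max_k >= 1)
  n <- length(values)
  out <- list(values = values, outliers = integer(0), capped = integer(0),
              cap_value = NA_real_, skipped = FALSE)
  class(out) <- "rosner_cap"
  if (n < min_n) {
    warning("n < ", min_n, ": generalized ESD test skipped, values unchanged")
    out$skipped <- TRUE
    return(out)
  }
  max_k <- min(max_k, n - 2L)  # need >= 2 points left to studentize

  remaining <- seq_len(n)
  cand <- integer(0)  # candidate indices in removal order
  R <- numeric(0)
  for (i in seq_len(max_k)) {
    x <- values[remaining]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) break
    dev <- abs(x - mean(x))
    j <- which.max(dev)
    R[i] <- dev[j] / s
    cand[i] <- remaining[j]
    remaining <- remaining[-j]
  }
  k_tested <- length(R)
  if (k_tested > 0) {
    lambda <- vapply(seq_len(k_tested), function(i) {
      ni <- n - i
      p <- 1 - alpha / (2 * (ni + 1))
      tq <- stats::qt(p, df = ni - 1)
      ni * tq / sqrt((ni - 1 + tq^2) * (ni + 1))
    }, numeric(1))
    exceed <- which(R > lambda)
    n_out <- if (length(exceed) > 0) max(exceed) else 0L
    if (n_out > 0) {
      out$outliers <- sort(cand[seq_len(n_out)])
      high <- out$outliers[values[out$outliers] > mean(values)]
      if (length(high) > 0) {
        cap <- stats::quantile(values, probs = cap_quantile, names = FALSE,
                               type = 7)
        out$values[high] <- cap
        out$capped <- high
        out$cap_value <- cap
      }
    }
  }
  out
}

#' @export
print.rosner_cap <- function(x, ...) {
  cat("Generalized ESD outlier capping\n")
  if (x$skipped) {
    cat("  skipped (sample too small)\n")
  } else {
    cat("  outliers flagged:", length(x$outliers),
        " capped:", length(x$capped), "\n")
    if (length(x$capped) > 0)
      cat("  cap value (95th pct):", format(x$cap_value), "\n")
  }
  invisible(x)
}
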