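# Between-subject scoring of titration outcomes and accuracy summaries.

#' Between-subject z-scores
#'
#' Standardises a vector of phase scores with the between-subject mean and
#' sample (n-1) standard deviation, preserving order.
#'
#' @param values numeric vector, length >= 2, non-zero spread.
#' @return Numeric vector with mean 0 and unit sample SD.
#' @examples
#' zscores(c(1, 2, 3))
#' @export
zscores <- function(values) {
  if (length(values) < 2L) {
    stop(errorCondition(
      "need at least two values to standardise",
      class = c("effortbf_degenerate_input", "error", "condition")
    ))
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop(errorCondition(
      "cannot z-score values with zero spread",
      class = c("effortbf_degenerate_input", "error", "condition")
    ))
  }
  (values - mean(values)) / s
}

#' Excess kurtosis
#'
#' Fisher (excess) kurtosis in the population-moment convention,
#' `m4 / m2^2 - 3`, so a normal distribution scores 0. Computed via
#' [e1071::kurtosis()] (type 1).
#'
#' @param values numeric vector, length >= 4.
#' @return Excess kurtosis.
#' @examples
#' excess_kurtosis(rep(c(-1, 1), 50))  # -2
#' @export
excess_kurtosis <- function(values) {
  if (length(values) < 4L) {
    stop(errorCondition(
      "need at least four values for kurtosis",
      class = c("effortbf_degenerate_input", "error", "condition")
    ))
  }
  e1071::kurtosis(values, type = 1)
}

#' Pearson correlation with input validation
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero spread.
#' @return Pearson's r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop(errorCondition(
      "x and y must have equal length >= 3",
      class = c("effortbf_degenerate_input", "error", "condition")
    ))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(errorCondition(
      "correlation undefined for zero-spread input",
      class = c("effortbf_degenerate_input", "error", "condition")
    ))
  }
  stats::cor(x, y, method = "pearson")
}

#' Reverse the demand-phase z-score scale
#'
#' On the raw scales a low reward score and a high demand score both mean the
#' participant stuck with the hybrid task; negating the demand z-scores puts
#' the two phases on a commensurable axis for side-by-side display.
#'
#' @param z numeric vector of z-scores.
#' @return `-z`.
#' @export
reverse_demand_scale <- function(z) -z

#' Per-option accuracy summary over a cohort
#'
#' @param profiles list of [performance_profile()] objects.
#' @return Data frame with one row per option: `option`, `mean`, `se`
#'   (sample SD / sqrt(n); `NA` when n = 1), `n`.
#' @export
accuracy_summary <- function(profiles) {
  if (length(profiles) < 1L) stop("need at least one profile")
  acc <- t(vapply(profiles, function(p) as_profile(p)$accuracy, numeric(6)))
  n <- nrow(acc)
  data.frame(
    option = option_ids(),
    mean = colMeans(acc),
    se = if (n > 1L) apply(acc, 2, stats::sd) / sqrt(n) else NA_real_,
    n = n,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
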