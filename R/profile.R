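#' Per-participant practice performance profile
#'
#' Stores the practice-phase accuracy of one participant on each of the six
#' task options (15 trials per option in the original design). Demand-related
#' preference models are deterministic functions of this profile.
#'
#' @param participant participant identifier (coerced to character).
#' @param accuracy named numeric vector of choice accuracies in `[0, 1]`,
#'   with one entry per option id (see [option_ids()]).
#' @param n_trials number of practice trials per option (default 15).
#' @return An object of class `performance_profile`.
#' @examples
#' acc <- c(memory_low = .837, memory_high = .709, motor_low = .883,
#'          motor_high = .757, hybrid_low = .842, hybrid_high = .625)
#' performance_profile("p1", acc)
#' @export
performance_profile <- function(participant, accuracy, n_trials = 15L) {
  ids <- option_ids()
  missing <- setdiff(ids, names(accuracy))
  if (length(missing) > 0L) {
    stop(errorCondition(
      sprintf("incomplete profile: missing option(s) %s", paste(missing, collapse = ", ")),
      class = c("effortbf_incomplete_profile", "effortbf_validation_error", "error", "condition")
    ))
  }
  assert_option(names(accuracy))
  accuracy <- accuracy[ids]
  if (anyNA(accuracy) || any(accuracy < 0) || any(accuracy > 1)) {
    stop(errorCondition(
      "accuracies must lie in [0, 1] and be non-missing",
      class = c("effortbf_validation_error", "error", "condition")
    ))
  }
  if (length(n_trials) != 1L || n_trials < 1L) {
    stop("n_trials must be a single positive integer")
  }
  structure(
    list(
      participant = as.character(participant),
      accuracy = accuracy,
      n_trials = as.integer(n_trials)
    ),
    class = "performance_profile"
  )
}

#' @export
print.performance_profile <- function(x, ...) {
  cat("Performance profile for participant", x$participant,
      sprintf("(%d practice trials/option)\n", x$n_trials))
  print(round(x$accuracy, 3))
  invisible(x)
}

as_profile <- function(x) {
  if (inherits(x, "performance_profile")) return(x)
  stop("expected a 'performance_profile' object")
}
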