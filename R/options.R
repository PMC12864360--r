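# Option layout: 3 cognitive tasks (memory, motor, hybrid) x 2 demand levels.

.TASKS <- c("memory", "motor", "hybrid")
.LEVELS <- c("low", "high")

#' Task option identifiers
#'
#' The experiment offers six task options: two demand levels (`low`, `high`)
#' of three cognitive tasks (`memory`, `motor`, `hybrid`). Options are
#' identified by strings of the form `"<task>_<level>"`, e.g. `"memory_low"`.
#'
#' @return `option_ids()` returns the six option identifiers in canonical
#'   order (task-major: memory, motor, hybrid; low before high).
#' @examples
#' option_ids()
#' @export
option_ids <- function() {
  paste(rep(.TASKS, each = 2L), rep(.LEVELS, 3L), sep = "_")
}

#' @rdname option_ids
#' @return `tasks()` returns the three task names.
#' @export
tasks <- function() .TASKS

#' @rdname option_ids
#' @param option character vector of option ids.
#' @return `option_task()` / `option_level()` return the task / demand-level
#'   component of each option id.
#' @export
option_task <- function(option) {
  sub("_(low|high)$", "", option)
}

#' @rdname option_ids
#' @export
option_level <- function(option) {
  sub("^.*_", "", option)
}

assert_option <- function(option) {
  bad <- setdiff(option, option_ids())
  if (length(bad) > 0L) {
    stop(errorCondition(
      sprintf("unknown option id(s): %s", paste(bad, collapse = ", ")),
      class = c("effortbf_unknown_option", "effortbf_validation_error", "error", "condition")
    ))
  }
  invisible(option)
}

#' All unordered option pairs
#'
#' The choice phase pairs every option with every other, giving
#' `choose(6, 2) = 15` unordered pairs; with six repetitions per pair a
#' participant makes 90 choices. Pairs are reported canonically:
#' `option1` precedes `option2` in the [option_ids()] ordering.
#'
#' @return A data frame with columns `option1` and `option2` (15 rows).
#' @examples
#' nrow(option_pairs())
#' @export
option_pairs <- function() {
  ids <- option_ids()
  idx <- utils::combn(6L, 2L)
  data.frame(
    option1 = ids[idx[1L, ]],
    option2 = ids[idx[2L, ]],
    stringsAsFactors = FALSE
  )
}

pair_key <- function(a, b) {
  ids <- option_ids()
  first <- ifelse(match(a, ids) < match(b, ids), a, b)
  second <- ifelse(match(a, ids) < match(b, ids), b, a)
  paste(first, second, sep = "|")
}

# TRUE for pairs whose two options belong to different tasks (12 of 15).
is_inter_task_pair <- function(option1, option2) {
  option_task(option1) != option_task(option2)
}
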