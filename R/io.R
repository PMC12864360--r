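# CSV interchange. UTF-8, comma-delimited, header mandatory. Readers validate
# and report offending row numbers; writers emit the same schemas.

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop(errorCondition(
      sprintf("file not found: %s", path),
      class = c("effortbf_validation_error", "error", "condition")
    ))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(errorCondition(
      sprintf("%s: missing column(s) %s", path, paste(missing, collapse = ", ")),
      class = c("effortbf_missing_column", "effortbf_validation_error", "error", "condition")
    ))
  }
  if (nrow(df) == 0L) {
    stop(errorCondition(
      sprintf("%s: empty cohort (no data rows)", path),
      class = c("effortbf_empty_cohort", "effortbf_validation_error", "error", "condition")
    ))
  }
  df
}

#' Read and write performance profiles
#'
#' Schema: `participant, option, accuracy, n_trials` — one row per
#' participant x option, all six options per participant.
#'
#' @param path CSV file path.
#' @return `read_performance()` returns a named list of
#'   [performance_profile()] objects.
#' @export
read_performance <- function(path) {
  df <- read_csv_checked(path, c("participant", "option", "accuracy", "n_trials"))
  bad <- which(!df$option %in% option_ids())
  if (length(bad) > 0L) {
    stop(errorCondition(
      sprintf("%s: unknown option id in row(s) %s", path,
              paste(bad, collapse = ", ")),
      class = c("effortbf_unknown_option", "effortbf_validation_error", "error", "condition")
    ))
  }
  out <- lapply(split(df, df$participant), function(d) {
    dup <- d$option[duplicated(d$option)]
    if (length(dup) > 0L) {
      stop(errorCondition(
        sprintf("%s: duplicate option(s) %s for participant %s", path,
                paste(dup, collapse = ", "), d$participant[1L]),
        class = c("effortbf_validation_error", "error", "condition")
      ))
    }
    performance_profile(d$participant[1L],
                        stats::setNames(d$accuracy, d$option),
                        d$n_trials[1L])
  })
  out[unique(df$participant)]
}

#' @rdname read_performance
#' @param profiles named list of [performance_profile()] objects.
#' @export
write_performance <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(participant = p$participant, option = option_ids(),
               accuracy = unname(p$accuracy[option_ids()]),
               n_trials = p$n_trials, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read and write pairwise choice data
#'
#' Schema: `participant, option1, option2, n, k` — one row per participant x
#' unordered pair; `k` counts choices of `option1`.
#'
#' @param path CSV file path.
#' @return `read_choices()` returns a named list of [pairwise_choices()].
#' @export
read_choices <- function(path) {
  df <- read_csv_checked(path, c("participant", "option1", "option2", "n", "k"))
  bad <- which(!(df$option1 %in% option_ids() & df$option2 %in% option_ids()))
  if (length(bad) > 0L) {
    stop(errorCondition(
      sprintf("%s: unknown option id in row(s) %s", path,
              paste(bad, collapse = ", ")),
      class = c("effortbf_unknown_option", "effortbf_validation_error", "error", "condition")
    ))
  }
  bad <- which(df$k > df$n | df$k < 0)
  if (length(bad) > 0L) {
    stop(errorCondition(
      sprintf("%s: k outside [0, n] in row(s) %s", path,
              paste(bad, collapse = ", ")),
      class = c("effortbf_validation_error", "error", "condition")
    ))
  }
  key <- paste(df$participant, pair_key(df$option1, df$option2))
  bad <- which(duplicated(key))
  if (length(bad) > 0L) {
    stop(errorCondition(
      sprintf("%s: duplicate (participant, pair) in row(s) %s", path,
              paste(bad, collapse = ", ")),
      class = c("effortbf_duplicate_pair", "effortbf_validation_error", "error", "condition")
    ))
  }
  out <- lapply(split(df, df$participant), function(d) {
    pairwise_choices(d$participant[1L],
                     d[, c("option1", "option2", "n", "k")])
  })
  out[unique(df$participant)]
}

#' @rdname read_choices
#' @param choices named list of [pairwise_choices()] objects.
#' @export
write_choices <- function(choices, path) {
  rows <- do.call(rbind, lapply(choices, function(ch) {
    cbind(data.frame(participant = ch$participant, stringsAsFactors = FALSE),
          ch$counts)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read and write titration traces
#'
#' Schema: `participant, condition, phase, set, decision, secondary_offer,
#' choice, performed`. A trace read back is re-attached to the default
#' [titration_config()] of its phase.
#'
#' @param path CSV file path.
#' @return `read_titration()` returns a named list (one entry per
#'   participant) of lists with `reward` and/or `demand` traces.
#' @export
read_titration <- function(path) {
  df <- read_csv_checked(path, c("participant", "condition", "phase", "set",
                                 "decision", "secondary_offer", "choice",
                                 "performed"))
  bad <- which(!df$choice %in% c("hybrid", "secondary"))
  if (length(bad) > 0L) {
    stop(errorCondition(
      sprintf("%s: invalid choice value in row(s) %s", path,
              paste(bad, collapse = ", ")),
      class = c("effortbf_validation_error", "error", "condition")
    ))
  }
  lapply(split(df, df$participant), function(d) {
    phases <- lapply(split(d, d$phase), function(ph) {
      ph <- ph[order(ph$set, ph$decision), ]
      rownames(ph) <- NULL
      structure(ph, class = c("titration_trace", "data.frame"),
                config = titration_config(ph$phase[1L]))
    })
    phases
  })[unique(df$participant)]
}

#' @rdname read_titration
#' @param traces named list as returned by [read_titration()] or built by
#'   [gen_cohort()].
#' @export
write_titration <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(ph) {
    do.call(rbind, lapply(ph, as.data.frame))
  }))
  rownames(rows) <- NULL
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a cohort's fixture files
#'
#' Emits `performance.csv`, `choices.csv`, `titration.csv`, `truth.csv` and a
#' `manifest.json` recording the master seed, into `dir`. Regenerating the
#' same [cohort_config()] reproduces the files byte for byte.
#'
#' @param cohort a [gen_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_performance(cohort$profiles, file.path(dir, "performance.csv"))
  if (length(cohort$choices) > 0L) {
    write_choices(cohort$choices, file.path(dir, "choices.csv"))
  }
  if (length(cohort$traces) > 0L) {
    write_titration(cohort$traces, file.path(dir, "titration.csv"))
  }
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         n_per_policy = as.list(cohort$config$n_per_policy),
         mean_low = cohort$config$mean_low,
         mean_high = cohort$config$mean_high,
         concentration = cohort$config$concentration,
         lapse = cohort$config$lapse),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
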