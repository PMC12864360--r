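# End-to-end drivers: the choice-phase model-selection pipeline and the
# titration scoring pipeline.

#' Choice-phase model-selection pipeline
#'
#' For every participant with both a performance profile and pairwise choice
#' data: builds the 12-model battery, fits encompassing-prior Bayes factors,
#' classifies with the two evidence criteria, and runs the single-task bias
#' test on the three tasks for participants left without a best-fitting
#' model. Participants missing either input are dropped with a logged reason,
#' never silently.
#'
#' @param profiles named list of [performance_profile()] objects.
#' @param choices named list of [pairwise_choices()] objects.
#' @param threshold strict evidence threshold for both criteria.
#' @param verbose emit one message per participant.
#' @return An object of class `exp1_result`: `fits` (long data frame:
#'   participant, model_id, family, bf, n_constraints, tie_flag),
#'   `classifications` (one row per participant), `bias` (one row per
#'   no-best-fit participant x task), `counts` (table over categories),
#'   `dropped` (participants excluded, with reasons).
#' @examples
#' coh <- gen_cohort(cohort_config(n_per_policy = c(demand_ranked = 2), seed = 5))
#' run_exp1_pipeline(coh$profiles, coh$choices)
#' @export
run_exp1_pipeline <- function(profiles, choices, threshold = 3.12,
                              verbose = FALSE) {
  ids <- union(names(profiles), names(choices))
  usable <- intersect(names(profiles), names(choices))
  dropped <- data.frame(
    participant = setdiff(ids, usable),
    reason = ifelse(setdiff(ids, usable) %in% names(profiles),
                    "no choice data", "no performance profile"),
    stringsAsFactors = FALSE
  )
  for (d in seq_len(nrow(dropped))) {
    message(sprintf("dropping participant %s: %s",
                    dropped$participant[d], dropped$reason[d]))
  }
  fits <- NULL
  cls_rows <- NULL
  bias_rows <- NULL
  for (id in usable) {
    fit <- fit_preferences(choices[[id]], profile = profiles[[id]],
                           threshold = threshold)
    fits <- rbind(fits, fit$fits)
    cl <- fit$classification
    cls_rows <- rbind(cls_rows, data.frame(
      participant = id, category = cl$category,
      best_model = cl$best_model, best_bf = cl$best_bf,
      runnerup_bf = cl$runnerup_bf, stringsAsFactors = FALSE
    ))
    if (verbose) {
      message(sprintf("%s: %s%s", id, cl$category,
                      if (is.na(cl$best_model)) "" else
                        sprintf(" (%s, BF %.3g)", cl$best_model, cl$best_bf)))
    }
    if (cl$category == "no_best_fit") {
      for (tk in tasks()) {
        b <- task_bias_test(choices[[id]], tk, threshold = threshold)
        bias_rows <- rbind(bias_rows, data.frame(
          participant = id, task = tk, K = b$K, N = b$N,
          bf_for = b$bf_for, bf_against = b$bf_against,
          direction = b$direction, stringsAsFactors = FALSE
        ))
      }
    }
  }
  counts <- table(factor(cls_rows$category,
                         levels = c("demand_related", "task_driven",
                                    "no_best_fit")))
  structure(
    list(fits = fits, classifications = cls_rows, bias = bias_rows,
         counts = counts, dropped = dropped, threshold = threshold),
    class = "exp1_result"
  )
}

#' @export
print.exp1_result <- function(x, ...) {
  cat(sprintf("Choice-phase pipeline: %d participants (threshold %.3g)\n",
              nrow(x$classifications), x$threshold))
  print(x$counts)
  if (!is.null(x$bias)) {
    biased <- x$bias[x$bias$direction != "none", ]
    cat(sprintf("Single-task biases among no-best-fit participants: %d\n",
                nrow(biased)))
  }
  if (nrow(x$dropped) > 0L) {
    cat(sprintf("Dropped: %d participant(s)\n", nrow(x$dropped)))
  }
  invisible(x)
}

#' Titration scoring pipeline
#'
#' For each participant, averages the final (sixth-decision) secondary offers
#' of the three sets in each incentive phase, standardises the per-phase
#' scores across participants, and reports the Pearson correlation between
#' reward and demand z-scores together with each phase's excess kurtosis.
#'
#' @param traces named list: one entry per participant holding
#'   `list(reward = <trace>, demand = <trace>)` (the [gen_cohort()] /
#'   [read_titration()] layout).
#' @param reverse_demand also report demand z-scores on the reversed scale
#'   (`z_demand_reversed` column); the correlation is always computed on the
#'   unreversed scale.
#' @return An object of class `exp2_result`: `scores` (participant,
#'   condition, final offers and z-scores per phase), `r`
#'   (reward vs. demand z-score correlation), `kurtosis` (named vector,
#'   one entry per phase).
#' @examples
#' coh <- gen_cohort(cohort_config(n_per_policy = c(titration_value = 6),
#'                                 seed = 9))
#' run_exp2_pipeline(coh$traces)
#' @export
run_exp2_pipeline <- function(traces, reverse_demand = TRUE) {
  if (length(traces) < 2L) {
    stop(errorCondition(
      "need at least two participants with titration traces",
      class = c("effortbf_degenerate_input", "error", "condition")
    ))
  }
  scores <- do.call(rbind, lapply(names(traces), function(id) {
    tr <- traces[[id]]
    if (is.null(tr$reward) || is.null(tr$demand)) {
      stop(errorCondition(
        sprintf("participant %s lacks a reward or demand trace", id),
        class = c("effortbf_validation_error", "error", "condition")
      ))
    }
    data.frame(
      participant = id,
      condition = tr$reward$condition[1L],
      final_reward = final_offer_average(tr$reward),
      final_demand = final_offer_average(tr$demand),
      stringsAsFactors = FALSE
    )
  }))
  scores$z_reward <- zscores(scores$final_reward)
  scores$z_demand <- zscores(scores$final_demand)
  if (reverse_demand) {
    scores$z_demand_reversed <- reverse_demand_scale(scores$z_demand)
  }
  r <- pearson_r(scores$z_reward, scores$z_demand)
  kurt <- c(reward = excess_kurtosis(scores$final_reward),
            demand = excess_kurtosis(scores$final_demand))
  structure(
    list(scores = scores, r = r, kurtosis = kurt),
    class = "exp2_result"
  )
}

#' @export
print.exp2_result <- function(x, ...) {
  cat(sprintf("Titration pipeline: %d participants\n", nrow(x$scores)))
  cat(sprintf("  Pearson r (reward vs demand z-scores): %.3f\n", x$r))
  cat(sprintf("  Excess kurtosis: reward %.3f, demand %.3f\n",
              x$kurtosis[["reward"]], x$kurtosis[["demand"]]))
  invisible(x)
}
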