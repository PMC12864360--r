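# Per-participant model selection: fit the 12-model battery, apply the two
# selection criteria (absolute Bayes factor and best/second-best ratio, both
# strictly above the threshold), and classify the participant.

#' Fit the preference-model battery to one participant
#'
#' The main fitting function. Builds (or accepts) the battery of preference
#' models, computes the encompassing-prior Bayes factor of each on the
#' participant's pairwise choices, and classifies the participant as
#' `demand_related`, `task_driven` or `no_best_fit` using two criteria:
#' the best model's Bayes factor must strictly exceed `threshold`, and the
#' ratio of the best to the second-best Bayes factor must strictly exceed
#' `threshold` (default 3.12, the conventional bound for substantial
#' evidence).
#'
#' @param data a [pairwise_choices()] object.
#' @param profile a [performance_profile()]; required unless `models` is
#'   supplied, since the six demand-related models depend on practice
#'   accuracy.
#' @param models optional list of `preference_model` objects; defaults to
#'   [build_model_battery()] on `profile`.
#' @param threshold strict evidence threshold for both criteria.
#' @return An object of class `pref_fit` with components `fits` (the
#'   [fit_models()] table), `classification` (list: `category`,
#'   `best_model`, `best_bf`, `runnerup_bf`), `threshold`, `participant`,
#'   and `models`.
#' @seealso [classify()], [task_bias_test()], [run_exp1_pipeline()]
#' @examples
#' acc <- c(memory_low = .837, memory_high = .709, motor_low = .883,
#'          motor_high = .757, hybrid_low = .842, hybrid_high = .625)
#' prof <- performance_profile("p1", acc)
#' agent <- agent_spec("demand_ranked", direction = "DA", heuristic = "all",
#'                     lapse = 0)
#' dat <- gen_choice_data(agent, prof, seed = 7)
#' fit <- fit_preferences(dat, prof)
#' fit
#' @export
fit_preferences <- function(data, profile = NULL, models = NULL,
                            threshold = 3.12) {
  data <- as_choices(data)
  if (is.null(models)) {
    if (is.null(profile)) {
      stop("supply either a performance profile or an explicit model list")
    }
    models <- build_model_battery(profile)
  }
  fits <- fit_models(models, data)
  cls <- classify(fits, threshold = threshold)
  structure(
    list(
      participant = data$participant,
      fits = fits,
      classification = cls,
      threshold = threshold,
      models = models,
      data = data
    ),
    class = "pref_fit"
  )
}

#' Classify a participant from fitted Bayes factors
#'
#' Applies the two selection criteria: the best model's Bayes factor must be
#' strictly above `threshold` and the best/second-best ratio strictly above
#' `threshold`. If both hold, the category is the winning model's family
#' (`demand_related` or `task_driven`); otherwise `no_best_fit`.
#'
#' @param fit a `pref_fit`, or a data frame with columns `model_id`,
#'   `family`, `bf` (as returned by [fit_models()]).
#' @param threshold strict evidence threshold.
#' @return A list with `category`, `best_model`, `best_bf`, `runnerup_bf`.
#' @export
classify <- function(fit, threshold = 3.12) {
  fits <- if (inherits(fit, "pref_fit")) fit$fits else fit
  if (!is.data.frame(fits) || nrow(fits) < 1L) {
    stop("need a non-empty fit table")
  }
  ord <- order(fits$bf, decreasing = TRUE)
  best <- fits[ord[1L], ]
  runnerup_bf <- if (nrow(fits) > 1L) fits$bf[ord[2L]] else NA_real_
  ratio_ok <- if (is.na(runnerup_bf)) TRUE else {
    if (runnerup_bf == 0) best$bf > 0 else best$bf / runnerup_bf > threshold
  }
  if (best$bf > threshold && ratio_ok) {
    category <- switch(best$family,
                       demand = "demand_related",
                       task = "task_driven",
                       stop("unknown model family: ", best$family))
    list(category = category, best_model = best$model_id,
         best_bf = best$bf, runnerup_bf = runnerup_bf)
  } else {
    list(category = "no_best_fit", best_model = NA_character_,
         best_bf = NA_real_, runnerup_bf = NA_real_)
  }
}

#' Single-task bias test
#'
#' For participants not captured by any ranking model, tests whether choices
#' are biased for or against one task: the eight inter-task pairs involving
#' the task are pooled (48 choices at the default six presentations per
#' pair), and `K`, the number of choices of that task's options, is compared
#' against chance. The operative Bayes factors compare a directional
#' hypothesis (choice rate uniform on (1/2, 1) for a bias *for* the task, on
#' (0, 1/2) for a bias *against*) to the point null `p = 1/2`. The simple
#' encompassing ratios `P(p > 1/2 | data) / (1/2)` (and its mirror) are
#' retained as diagnostic fields `bf_enc_for` / `bf_enc_against`; they are
#' bounded by 2 and cannot clear a 3.12 threshold at this pooled sample size.
#'
#' @param data a [pairwise_choices()] object.
#' @param task one of `"memory"`, `"motor"`, `"hybrid"`.
#' @param threshold strict evidence threshold.
#' @return An object of class `bias_result`: list with `participant`,
#'   `task`, `K`, `N`, `bf_for`, `bf_against`, `bf_enc_for`,
#'   `bf_enc_against`, `direction` (`"for"`, `"against"` or `"none"`).
#' @examples
#' agent <- agent_spec("single_task_bias", biased_task = "motor", lapse = 0.05)
#' task_bias_test(gen_choice_data(agent, seed = 3), "motor")
#' @export
task_bias_test <- function(data, task, threshold = 3.12) {
  data <- as_choices(data)
  if (!task %in% tasks()) stop("unknown task: ", task)
  counts <- data$counts
  involves <- (option_task(counts$option1) == task) !=
    (option_task(counts$option2) == task)
  rows <- counts[involves, ]
  K <- sum(ifelse(option_task(rows$option1) == task, rows$k, rows$n - rows$k))
  N <- sum(rows$n)
  # marginal likelihood under p ~ Uniform(1/2, 1) (density 2), over p = 1/2;
  # the binomial coefficient cancels
  log_bf_dir <- function(upper) {
    tail_log <- stats::pbeta(0.5, K + 1, N - K + 1,
                             lower.tail = !upper, log.p = TRUE)
    log(2) + lbeta(K + 1, N - K + 1) + tail_log + N * log(2)
  }
  bf_for <- exp(log_bf_dir(upper = TRUE))
  bf_against <- exp(log_bf_dir(upper = FALSE))
  p_gt <- pair_posterior_prob(K, N)
  direction <- if (bf_for > threshold && bf_for >= bf_against) {
    "for"
  } else if (bf_against > threshold) {
    "against"
  } else {
    "none"
  }
  structure(
    list(participant = data$participant, task = task, K = K, N = N,
         bf_for = bf_for, bf_against = bf_against,
         bf_enc_for = p_gt / 0.5, bf_enc_against = (1 - p_gt) / 0.5,
         direction = direction, threshold = threshold),
    class = "bias_result"
  )
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("Task bias test (%s): %d/%d choices; BF for = %.3g, against = %.3g -> %s\n",
              x$task, x$K, x$N, x$bf_for, x$bf_against, x$direction))
  invisible(x)
}

#' @export
print.pref_fit <- function(x, ...) {
  cls <- x$classification
  cat(sprintf("Preference-model fit for participant %s (%d models)\n",
              x$participant, nrow(x$fits)))
  if (cls$category == "no_best_fit") {
    cat(sprintf("  classification: no_best_fit (threshold %.3g)\n", x$threshold))
  } else {
    cat(sprintf("  classification: %s via %s (BF = %.3g, runner-up %.3g)\n",
                cls$category, cls$best_model, cls$best_bf, cls$runnerup_bf))
  }
  invisible(x)
}

#' @export
summary.pref_fit <- function(object, ...) {
  fits <- object$fits[order(object$fits$bf, decreasing = TRUE), ]
  rownames(fits) <- NULL
  out <- list(participant = object$participant, fits = fits,
              classification = object$classification,
              threshold = object$threshold)
  class(out) <- "summary.pref_fit"
  out
}

#' @export
print.summary.pref_fit <- function(x, ...) {
  cat(sprintf("Participant %s — Bayes factors (threshold %.3g):\n",
              x$participant, x$threshold))
  tab <- x$fits[, c("model_id", "family", "bf", "n_constraints")]
  tab$bf <- signif(tab$bf, 4)
  print(tab, row.names = FALSE)
  cls <- x$classification
  cat(sprintf("Category: %s%s\n", cls$category,
              if (is.na(cls$best_model)) "" else paste0(" (", cls$best_model, ")")))
  invisible(x)
}

#' @export
coef.pref_fit <- function(object, ...) {
  stats::setNames(object$fits$bf, object$fits$model_id)
}

#' @export
plot.pref_fit <- function(x, ...) {
  bf <- coef(x)
  op <- graphics::par(mar = c(8, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(log10(pmax(bf, 1e-12)), las = 2,
                    ylab = "log10 Bayes factor",
                    main = paste("Participant", x$participant), ...)
  graphics::abline(h = log10(x$threshold), lty = 2)
  invisible(x)
}

#' Simulate choice data from a fitted preference model
#'
#' Draws replicate pairwise-choice datasets from the fitted participant's
#' best model (with a lapse rate on constrained pairs and chance on
#' unconstrained pairs). If the fit is `no_best_fit`, replicates are drawn
#' from the random (chance-everywhere) policy.
#'
#' @param object a `pref_fit`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param lapse lapse rate applied to constrained pairs.
#' @param ... unused.
#' @return A list of `nsim` [pairwise_choices()] objects.
#' @export
simulate.pref_fit <- function(object, nsim = 1, seed = 1L, lapse = 0.05, ...) {
  best <- object$classification$best_model
  agent <- if (is.na(best)) {
    agent_spec("random")
  } else {
    agent_spec("model", model = object$models[[best]], lapse = lapse)
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seeds, function(s) gen_choice_data(agent, seed = s,
                                            participant = object$participant))
}
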