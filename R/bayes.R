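# Encompassing-prior Bayes factors for order-constrained binary choice models.
#
# Each unordered pair has an unknown choice probability p with an independent
# Uniform(0,1) prior. A preference model asserts p > 1/2 in the winner's
# direction on each constrained pair ("modal choice"). The Bayes factor of a
# constrained model against the encompassing (unconstrained) model is the
# posterior probability mass of the constraint region divided by its prior
# mass; under independence both factorise over pairs.

#' Posterior probability that a choice rate exceeds one half
#'
#' With `k` successes in `n` Bernoulli trials and a Uniform(0,1) prior, the
#' posterior is Beta(1 + k, 1 + n - k); this returns the posterior probability
#' that the underlying choice probability exceeds 1/2 — the per-pair building
#' block of the encompassing-prior Bayes factor.
#'
#' @param k number of choices of the focal option (0 <= k <= n).
#' @param n number of presentations of the pair.
#' @return Probability in `[0, 1]`. Vectorised over `k` and `n`.
#' @examples
#' pair_posterior_prob(6, 6)  # 1 - (1/2)^7
#' pair_posterior_prob(3, 6)  # exactly 1/2
#' @export
pair_posterior_prob <- function(k, n) {
  if (any(k < 0) || any(n < 0) || any(k > n)) {
    stop(errorCondition(
      "require 0 <= k <= n",
      class = c("effortbf_domain_error", "error", "condition")
    ))
  }
  stats::pbeta(0.5, 1 + k, 1 + n - k, lower.tail = FALSE)
}

#' Prior mass of a model's constraint region
#'
#' Under independent Uniform(0,1) priors on the 15 pair probabilities, each
#' constraint `p > 1/2` carves off half the mass, so a model with `m`
#' constraints has prior mass `(1/2)^m`.
#'
#' @param model a `preference_model`.
#' @return `(1/2)^m` where `m = nrow(model$constraints)`.
#' @export
prior_mass <- function(model) {
  0.5^nrow(model$constraints)
}

#' Encompassing-prior Bayes factor of a preference model
#'
#' `BF = [prod over constrained pairs of P(winner's rate > 1/2 | data)] /
#' prior_mass(model)`. Unconstrained pairs contribute nothing; the empty
#' model has `BF = 1` exactly. Values above 1 mean the data concentrate
#' posterior mass inside the model's preference region beyond what its prior
#' size predicts.
#'
#' @param model a `preference_model`.
#' @param data a [pairwise_choices()] object.
#' @return A non-negative number.
#' @examples
#' prs <- option_pairs(); prs$n <- 6L; prs$k <- 3L
#' bayes_factor(build_task_models()[[1]], pairwise_choices("p", prs))
#' @export
bayes_factor <- function(model, data) {
  data <- as_choices(data)
  cons <- model$constraints
  if (nrow(cons) == 0L) return(1)
  post <- vapply(seq_len(nrow(cons)), function(i) {
    nk <- pair_counts_for(data, cons$winner[i], cons$loser[i])
    pair_posterior_prob(nk[["k"]], nk[["n"]])
  }, numeric(1))
  prod(post) / prior_mass(model)
}

#' Monte-Carlo oracle for the encompassing-prior Bayes factor
#'
#' Estimates the same quantity as [bayes_factor()] by brute force: the
#' fraction of joint posterior draws (independent Beta samples per
#' constrained pair) that fall inside the constraint region, divided by the
#' fraction of uniform prior draws inside it. Used as an independent
#' cross-check of the closed form; deterministic given `seed`.
#'
#' @inheritParams bayes_factor
#' @param n_samples number of draws for each of the two fractions
#'   (at least 1e4).
#' @param seed integer seed.
#' @return A list with elements `bf` (the estimate), `se` (delta-method
#'   standard error), and the raw fractions `post_frac`, `prior_frac`.
#' @export
mc_oracle_bayes_factor <- function(model, data, n_samples = 1e5, seed = 1L) {
  data <- as_choices(data)
  if (n_samples < 1e4) stop("n_samples must be at least 1e4")
  cons <- model$constraints
  if (nrow(cons) == 0L) {
    return(list(bf = 1, se = 0, post_frac = 1, prior_frac = 1))
  }
  # Beta posterior parameters per constraint, oriented so the constraint is
  # "winner's probability > 1/2".
  pars <- t(vapply(seq_len(nrow(cons)), function(i) {
    nk <- pair_counts_for(data, cons$winner[i], cons$loser[i])
    c(shape1 = 1 + nk[["k"]], shape2 = 1 + nk[["n"]] - nk[["k"]])
  }, numeric(2)))
  m <- nrow(pars)
  set.seed(seed)
  hits_post <- 0
  hits_prior <- 0
  chunk <- 1e5
  done <- 0
  while (done < n_samples) {
    nc <- min(chunk, n_samples - done)
    inside_post <- rep(TRUE, nc)
    inside_prior <- rep(TRUE, nc)
    for (j in seq_len(m)) {
      inside_post <- inside_post &
        (stats::rbeta(nc, pars[j, 1L], pars[j, 2L]) > 0.5)
      inside_prior <- inside_prior & (stats::runif(nc) > 0.5)
    }
    hits_post <- hits_post + sum(inside_post)
    hits_prior <- hits_prior + sum(inside_prior)
    done <- done + nc
  }
  if (hits_prior == 0L) {
    stop(errorCondition(
      "no prior draws fell inside the constraint region; increase n_samples",
      class = c("effortbf_mc_error", "error", "condition")
    ))
  }
  f_post <- hits_post / n_samples
  f_prior <- hits_prior / n_samples
  bf <- f_post / f_prior
  # delta method on the ratio of two independent binomial fractions
  var_term <- function(f) f * (1 - f) / (n_samples * f^2)
  se <- if (f_post == 0) {
    # zero posterior hits: report the scale of a one-hit change
    3 / (n_samples * f_prior)
  } else {
    bf * sqrt(var_term(f_post) + var_term(f_prior))
  }
  list(bf = bf, se = se, post_frac = f_post, prior_frac = f_prior)
}

#' Fit a set of preference models to one participant's choices
#'
#' Computes the encompassing-prior Bayes factor of every model on the same
#' data. Order-independent and pure: the same model always receives the same
#' Bayes factor.
#'
#' @param models a list of `preference_model` objects.
#' @param data a [pairwise_choices()] object.
#' @return A data frame with one row per model: `model_id`, `family`, `bf`,
#'   `n_constraints`, `tie_flag`.
#' @export
fit_models <- function(models, data) {
  if (inherits(models, "preference_model")) models <- list(models)
  if (length(models) < 1L) stop("need at least one model")
  data <- as_choices(data)
  data.frame(
    participant = data$participant,
    model_id = vapply(models, `[[`, "", "model_id"),
    family = vapply(models, `[[`, "", "family"),
    bf = vapply(models, bayes_factor, numeric(1), data = data),
    n_constraints = vapply(models, function(m) nrow(m$constraints), integer(1)),
    tie_flag = vapply(models, function(m) isTRUE(m$tie_flag), logical(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
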