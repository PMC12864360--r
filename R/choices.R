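#' Pairwise choice data for one participant
#'
#' The choice phase presents every pair of the six options six times, for 90
#' choices in total. Counts are stored per unordered pair in canonical order
#' (see [option_pairs()]): `k` is the number of times `option1` was chosen
#' out of the pair's `n` presentations.
#'
#' @param participant participant identifier.
#' @param counts data frame with columns `option1`, `option2`, `n`, `k`;
#'   one row per unordered pair, all 15 pairs present. Rows whose options
#'   arrive in non-canonical order are flipped (with `k -> n - k`).
#' @return An object of class `pairwise_choices`.
#' @examples
#' prs <- option_pairs()
#' prs$n <- 6L; prs$k <- 3L
#' pairwise_choices("p1", prs)
#' @export
pairwise_choices <- function(participant, counts) {
  counts <- as.data.frame(counts, stringsAsFactors = FALSE)
  need <- c("option1", "option2", "n", "k")
  if (!all(need %in% names(counts))) {
    stop(errorCondition(
      sprintf("choice counts need columns %s", paste(need, collapse = ", ")),
      class = c("effortbf_validation_error", "error", "condition")
    ))
  }
  assert_option(counts$option1)
  assert_option(counts$option2)
  ids <- option_ids()
  flip <- match(counts$option1, ids) > match(counts$option2, ids)
  if (any(flip)) {
    tmp <- counts$option1[flip]
    counts$option1[flip] <- counts$option2[flip]
    counts$option2[flip] <- tmp
    counts$k[flip] <- counts$n[flip] - counts$k[flip]
  }
  key <- pair_key(counts$option1, counts$option2)
  if (anyDuplicated(key)) {
    stop(errorCondition(
      sprintf("duplicate pair(s): %s", paste(unique(key[duplicated(key)]), collapse = ", ")),
      class = c("effortbf_duplicate_pair", "effortbf_validation_error", "error", "condition")
    ))
  }
  all_keys <- pair_key(option_pairs()$option1, option_pairs()$option2)
  missing <- setdiff(all_keys, key)
  if (length(missing) > 0L) {
    stop(errorCondition(
      sprintf("incomplete choice data: missing pair(s) %s", paste(missing, collapse = ", ")),
      class = c("effortbf_incomplete_choices", "effortbf_validation_error", "error", "condition")
    ))
  }
  if (any(counts$k < 0) || any(counts$k > counts$n) || any(counts$n < 1)) {
    stop(errorCondition(
      "choice counts must satisfy 0 <= k <= n, n >= 1",
      class = c("effortbf_validation_error", "error", "condition")
    ))
  }
  counts <- counts[match(all_keys, key), need]
  rownames(counts) <- NULL
  counts$n <- as.integer(counts$n)
  counts$k <- as.integer(counts$k)
  structure(
    list(participant = as.character(participant), counts = counts),
    class = "pairwise_choices"
  )
}

#' @export
print.pairwise_choices <- function(x, ...) {
  cat(sprintf("Pairwise choices for participant %s: %d pairs, %d choices\n",
              x$participant, nrow(x$counts), sum(x$counts$n)))
  invisible(x)
}

as_choices <- function(x) {
  if (inherits(x, "pairwise_choices")) return(x)
  stop("expected a 'pairwise_choices' object")
}

# (n, k) for the unordered pair containing both options, expressed so that k
# counts choices of `first`.
pair_counts_for <- function(choices, first, second) {
  counts <- choices$counts
  key <- pair_key(counts$option1, counts$option2)
  row <- counts[match(pair_key(first, second), key), ]
  k <- if (row$option1 == first) row$k else row$n - row$k
  c(n = row$n, k = k)
}
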