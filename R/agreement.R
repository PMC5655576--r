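# Inter-rater agreement on the common scenarios.
#
# Ratings are held long (rater_id, scenario_id, rating) and aggregated
# to a per-scenario count matrix with one column per category
# (S, M-DA, S-DA). Agreement statistics follow the classical
# multi-rater formulation: per-scenario pairwise agreement Pr, overall
# category proportions Pc, and Fleiss' kappa.

#' Validate a long-format rating table
#'
#' @param ratings Data frame with columns `rater_id`, `scenario_id`,
#'   `rating` (tokens `S`, `M-DA`, `S-DA`).
#' @return The validated data frame, with `rating` as a factor over the
#'   three categories.
#' @export
validate_ratings <- function(ratings) {
  if (!is.data.frame(ratings)) abort_invalid("`ratings` must be a data frame")
  needed <- c("rater_id", "scenario_id", "rating")
  if (!all(needed %in% names(ratings))) {
    abort_invalid("ratings need columns rater_id, scenario_id, rating")
  }
  sid <- ratings$scenario_id
  if (anyNA(sid) || any(sid != round(sid)) || any(sid < 1) || any(sid > 243)) {
    abort_invalid("scenario_id must be an integer in [1, 243]")
  }
  bad <- !(as.character(ratings$rating) %in% RATING_LEVELS)
  if (any(bad)) {
    abort_invalid(paste0(
      "unknown rating token(s) at row(s) ",
      paste(utils::head(which(bad), 5L), collapse = ", "),
      "; expected S, M-DA or S-DA"
    ))
  }
  if (anyDuplicated(ratings[c("rater_id", "scenario_id")])) {
    abort_invalid("duplicate (rater_id, scenario_id) pair in rating table")
  }
  ratings$rating <- factor(as.character(ratings$rating), levels = RATING_LEVELS)
  ratings
}

#' Tabulate ratings into a per-scenario count matrix
#'
#' @inheritParams validate_ratings
#' @param scenario_ids Scenarios to tabulate, in output order; defaults
#'   to all scenarios present, sorted. Every listed scenario must have
#'   been rated by the same number of raters.
#' @return Integer matrix (scenarios x 3 categories) with scenario ids
#'   as row names; the common rater count is attached as attribute
#'   `n_raters`.
#' @export
tabulate_ratings <- function(ratings, scenario_ids = NULL) {
  ratings <- validate_ratings(ratings)
  if (is.null(scenario_ids)) scenario_ids <- sort(unique(ratings$scenario_id))
  if (length(scenario_ids) == 0L) {
    out <- matrix(0L, 0L, 3L, dimnames = list(NULL, RATING_LEVELS))
    attr(out, "n_raters") <- 0L
    return(out)
  }
  keep <- ratings$scenario_id %in% scenario_ids
  tab <- table(
    factor(ratings$scenario_id[keep], levels = scenario_ids),
    ratings$rating[keep]
  )
  out <- matrix(as.integer(tab), nrow = length(scenario_ids),
                dimnames = list(as.character(scenario_ids), RATING_LEVELS))
  n <- rowSums(out)
  if (length(unique(n)) != 1L) {
    abort_invalid(
      "unbalanced table: listed scenarios were rated by differing numbers of raters"
    )
  }
  attr(out, "n_raters") <- as.integer(n[1L])
  out
}

check_count_matrix <- function(cm) {
  cm <- as.matrix(cm)
  if (ncol(cm) != 3L) abort_invalid("count matrix must have 3 category columns")
  if (anyNA(cm) || any(cm < 0) || any(cm != round(cm))) {
    abort_invalid("count matrix entries must be non-negative integers")
  }
  n <- rowSums(cm)
  if (nrow(cm) > 0L && length(unique(n)) != 1L) {
    abort_invalid("count matrix rows must all sum to the same rater count")
  }
  cm
}

#' Per-scenario pairwise agreement (Pr)
#'
#' The proportion of rater pairs in agreement on a scenario relative to
#' all possible pairs: `Pr = sum_j n_j (n_j - 1) / (n (n - 1))` for a
#' count row summing to `n` raters. 1 is complete agreement.
#'
#' @param cm Count matrix (scenarios x 3), e.g. from
#'   [tabulate_ratings()], or a single count row.
#' @return Numeric vector of Pr values in \[0, 1\].
#' @examples
#' per_scenario_agreement(rbind(c(17, 4, 0))) # 0.676 with 21 raters
#' @export
per_scenario_agreement <- function(cm) {
  if (is.null(dim(cm))) cm <- matrix(cm, nrow = 1L)
  cm <- check_count_matrix(cm)
  n <- rowSums(cm)
  if (any(n < 2)) abort_invalid("pairwise agreement needs at least 2 raters")
  unname(rowSums(cm * (cm - 1)) / (n * (n - 1)))
}

#' Overall category proportions (Pc)
#'
#' The share of all assessments assigned to each category:
#' `Pc_j = sum_i n_ij / (N * n)`.
#'
#' @inheritParams per_scenario_agreement
#' @return Named numeric vector of 3 proportions summing to 1.
#' @export
category_proportions <- function(cm) {
  cm <- check_count_matrix(cm)
  total <- sum(cm)
  if (nrow(cm) == 0L || total == 0) abort_invalid("empty count matrix")
  out <- colSums(cm) / total
  names(out) <- RATING_LEVELS
  out
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement across scenarios:
#' `kappa = (Pbar - Pe) / (1 - Pe)` where `Pbar` is the mean
#' per-scenario pairwise agreement and `Pe = sum_j Pc_j^2` is the
#' agreement expected if every assessment were drawn independently from
#' the marginal category distribution.
#'
#' @inheritParams per_scenario_agreement
#' @return Fleiss' kappa (at most 1; 0 is chance-level agreement).
#' @examples
#' fleiss_kappa(rbind(c(5, 0, 0), c(0, 5, 0))) # 1: unanimous rows
#' @export
fleiss_kappa <- function(cm) {
  cm <- check_count_matrix(cm)
  if (nrow(cm) < 2L) abort_invalid("Fleiss' kappa needs at least 2 scenarios")
  pbar <- mean(per_scenario_agreement(cm))
  pe <- sum(category_proportions(cm)^2)
  if (pe >= 1) {
    abort_invalid("degenerate kappa: all assessments fall in one category",
                  class = "acrodat_degenerate")
  }
  (pbar - pe) / (1 - pe)
}

#' Full agreement summary for a rating table
#'
#' @inheritParams tabulate_ratings
#' @return List with `counts` (the count matrix), `pr` (per-scenario
#'   agreement), `pc` (category proportions) and `kappa`.
#' @export
agreement_summary <- function(ratings, scenario_ids = NULL) {
  cm <- tabulate_ratings(ratings, scenario_ids)
  list(
    counts = cm,
    pr = per_scenario_agreement(cm),
    pc = category_proportions(cm),
    kappa = fleiss_kappa(cm)
  )
}

#' Leave-one-rater-out sensitivity of Fleiss' kappa
#'
#' Recomputes kappa on the common scenarios after dropping each rater
#' in turn, the standard sensitivity check for a single outlying rater.
#' Requires the long-format table (counts alone cannot attribute
#' ratings to raters).
#'
#' @inheritParams tabulate_ratings
#' @param scenario_ids Scenarios on which agreement is assessed;
#'   default all scenarios rated by every rater.
#' @return Data frame with columns `excluded_rater` and `kappa`.
#' @export
leave_one_rater_out <- function(ratings, scenario_ids = NULL) {
  ratings <- validate_ratings(ratings)
  raters <- unique(ratings$rater_id)
  if (length(raters) < 3L) {
    abort_invalid("leave-one-rater-out needs at least 3 raters")
  }
  if (is.null(scenario_ids)) {
    tab <- table(ratings$scenario_id)
    scenario_ids <- as.integer(names(tab)[tab == length(raters)])
    if (length(scenario_ids) < 2L) {
      abort_invalid("no common scenario set rated by every rater")
    }
  }
  kap <- vapply(raters, function(r) {
    fleiss_kappa(tabulate_ratings(ratings[ratings$rater_id != r, ],
                                  scenario_ids))
  }, numeric(1))
  data.frame(excluded_rater = raters, kappa = kap)
}
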