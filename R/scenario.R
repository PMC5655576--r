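# The 243-scenario space and the validation-survey design arithmetic.
#
# A scenario is a vector of five severity levels in the fixed order
# (IGF-I, tumor, comorbidity, symptoms, QoL). Scenario ids index the
# full 3^5 grid with the rightmost (QoL) digit varying fastest, so
# [1,1,1,1,1] is scenario 1 and [3,3,3,3,3] is scenario 243.

#' Encode five-parameter level vectors as scenario ids
#'
#' The id is the mixed-radix (base-3) rank of the level vector plus
#' one: `id = 1 + sum_k (level_k - 1) * 3^(5-k)` with parameters in the
#' order IGF-I, tumor, comorbidity, symptoms, QoL. This convention
#' reproduces the printed id/bracket-code pairs of the validation
#' survey, e.g. \[3,1,1,2,1\] is scenario 166.
#'
#' @param levels Length-5 level vector, or a matrix/data frame of level
#'   vectors (columns `igf`, `tumor`, `comorbidity`, `symptoms`,
#'   `qol`).
#' @return Integer scenario id(s) in 1..243.
#' @examples
#' encode_scenario(c(1, 1, 1, 1, 1)) # 1
#' encode_scenario(c(3, 1, 1, 2, 1)) # 166
#' @export
encode_scenario <- function(levels) {
  m <- as_level_matrix(levels)
  as.integer(1L + (m - 1L) %*% 3L^(4:0))
}

#' Decode scenario ids to five-parameter level vectors
#'
#' Inverse of [encode_scenario()].
#'
#' @param id Integer scenario id(s) in 1..243.
#' @return Data frame with one row per id and columns `igf`, `tumor`,
#'   `comorbidity`, `symptoms`, `qol`.
#' @examples
#' decode_scenario(122) # all levels 2
#' @export
decode_scenario <- function(id) {
  id <- as.numeric(id)
  if (anyNA(id) || any(id != round(id)) || any(id < 1) || any(id > 243)) {
    abort_invalid("scenario id must be an integer in [1, 243]")
  }
  rem <- as.integer(id) - 1L
  out <- matrix(0L, nrow = length(id), ncol = 5L,
                dimnames = list(NULL, PARAM_NAMES))
  for (k in 5:1) {
    out[, k] <- rem %% 3L + 1L
    rem <- rem %/% 3L
  }
  as.data.frame(out)
}

#' Enumerate all 243 scenarios
#'
#' @return Data frame of 243 rows: `id` (1..243, increasing) and the
#'   five level columns.
#' @export
enumerate_scenarios <- function() {
  out <- decode_scenario(1:243)
  cbind(id = 1:243, out)
}

#' Format a level vector as a bracket code
#'
#' @param levels As in [encode_scenario()].
#' @return Character vector like `"[31121]"`.
#' @export
scenario_code <- function(levels) {
  m <- as_level_matrix(levels)
  paste0("[", apply(m, 1L, paste0, collapse = ""), "]")
}

#' Minimum survey size from an events-per-variable rule
#'
#' Multivariable logistic models are conventionally sized at no fewer
#' than 10 outcome events per model variable. With an assumed event
#' rate per category and an inflation factor for non-independence of
#' ratings from the same rater, the minimum number of rated scenarios
#' and the per-rater workload follow directly:
#' `min_observations = inflation * events_per_var * n_vars / event_rate`
#' and `min_per_rater = ceiling(min_observations / n_raters)`.
#'
#' @param events_per_var Required events per model variable (typically
#'   10).
#' @param n_vars Number of model variables (10 for five 3-level
#'   parameters coded as indicator pairs).
#' @param event_rate Assumed probability of an event per observation.
#' @param inflation Multiplier compensating for clustered
#'   (rater-correlated) observations; 2 doubles the dataset.
#' @param n_raters Number of participating raters.
#' @return Named list with `min_observations` and `min_per_rater`.
#' @examples
#' required_design_size(10, 10, 1 / 3, 2, 21) # 600 observations, 29 each
#' @export
required_design_size <- function(events_per_var, n_vars, event_rate,
                                 inflation, n_raters) {
  vals <- c(events_per_var, n_vars, event_rate, inflation, n_raters)
  if (anyNA(vals) || any(vals <= 0) || event_rate > 1) {
    abort_invalid("all design inputs must be positive, with event_rate in (0, 1]")
  }
  min_obs <- inflation * events_per_var * n_vars / event_rate
  list(
    min_observations = min_obs,
    min_per_rater = ceiling(min_obs / n_raters)
  )
}

#' Default common-scenario set
#'
#' The ten panel-chosen common scenarios rated by every participant,
#' spanning fairly good health (scenario 1, all levels 1) to very poor
#' health (scenario 243, all levels 3).
#'
#' @return Integer vector of ten scenario ids.
#' @export
common_scenario_ids <- function() {
  c(1L, 5L, 11L, 59L, 92L, 122L, 166L, 203L, 230L, 243L)
}

#' Build a survey design assigning scenarios to raters
#'
#' Every rater receives the full common-scenario set plus a fill of
#' scenarios drawn without replacement from the remaining ids. With
#' `method = "stratified"` (default) the fill favours the scenarios
#' least often assigned so far, keeping per-scenario assignment counts
#' as even as possible across the 243; `method = "simple"` samples the
#' fill uniformly. The design is deterministic given `seed`.
#'
#' @param n_raters Number of raters.
#' @param per_rater Scenarios rated by each rater (including the common
#'   set); at most 243.
#' @param common_ids Scenario ids rated by everyone; default
#'   [common_scenario_ids()].
#' @param seed Integer seed making the design reproducible.
#' @param method `"stratified"` or `"simple"` fill.
#' @return Object of class `survey_design`: a list with the call
#'   parameters, `assignments` (a list of sorted id vectors, one per
#'   rater) and `coverage` (assignment count per scenario id).
#' @examples
#' d <- build_survey_design(21, 52, seed = 1)
#' lengths(d$assignments)[1:3]
#' @export
build_survey_design <- function(n_raters, per_rater,
                                common_ids = common_scenario_ids(),
                                seed = 1L,
                                method = c("stratified", "simple")) {
  method <- match.arg(method)
  common_ids <- sort(unique(as.integer(common_ids)))
  if (length(common_ids) > 0 &&
      (min(common_ids) < 1L || max(common_ids) > 243L)) {
    abort_invalid("common_ids must lie in [1, 243]")
  }
  if (n_raters < 1L) abort_invalid("need at least one rater")
  if (per_rater > 243L) {
    abort_invalid("per_rater cannot exceed the 243 distinct scenarios")
  }
  if (per_rater < length(common_ids)) {
    abort_invalid("per_rater must be at least the number of common scenarios")
  }
  pool <- setdiff(1:243, common_ids)
  n_fill <- per_rater - length(common_ids)
  counts <- integer(243)
  counts[common_ids] <- n_raters
  assignments <- with_seed(seed, {
    lapply(seq_len(n_raters), function(r) {
      fill <- if (n_fill == 0L) {
        integer(0)
      } else if (method == "simple") {
        sample(pool, n_fill)
      } else {
        # least-assigned-first, ties broken at random
        ord <- order(counts[pool], sample.int(length(pool)))
        pool[ord[seq_len(n_fill)]]
      }
      counts[fill] <<- counts[fill] + 1L
      sort(c(common_ids, fill))
    })
  })
  structure(
    list(
      n_raters = as.integer(n_raters), per_rater = as.integer(per_rater),
      common_ids = common_ids, seed = as.integer(seed), method = method,
      assignments = assignments, coverage = counts
    ),
    class = "survey_design"
  )
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf(
    "Survey design: %d raters x %d scenarios (%d common), %s fill, seed %d\n",
    x$n_raters, x$per_rater, length(x$common_ids), x$method, x$seed
  ))
  cat(sprintf(
    "Coverage: %d of 243 scenarios assigned (counts %d-%d)\n",
    sum(x$coverage > 0), min(x$coverage), max(x$coverage)
  ))
  invisible(x)
}
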