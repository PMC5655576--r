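# Packaged reference data: the published count table for the ten
# common scenarios of the clinician validation survey (21 raters each),
# together with the printed reference statistics.
#
# The survey report prints each row's three category counts as a
# concatenated digit string followed by Pr. The counts shipped here are
# the unique 3-part composition of 21 that both matches the printed
# digit string and reproduces the printed Pr; uniqueness is verified by
# exhaustive search in the test-suite (see partition_candidates()).

#' Load the common-scenario reference count table
#'
#' Ten common scenarios, each rated by all 21 survey participants, with
#' the published per-scenario category counts. The printed reference
#' statistics ride along so downstream checks can compare recomputed
#' values against them.
#'
#' @return List with:
#'   \describe{
#'     \item{table}{data frame: `scenario_id`, `code`, `n_s`, `n_mda`,
#'       `n_sda`, `pr_printed`.}
#'     \item{counts}{10 x 3 integer count matrix (rows sum to 21),
#'       rows named by scenario id.}
#'     \item{pc_printed}{printed category proportions (0.295, 0.305,
#'       0.400).}
#'     \item{kappa_printed}{printed Fleiss' kappa, 0.526.}
#'   }
#' @examples
#' fx <- load_common_scenario_fixture()
#' fleiss_kappa(fx$counts)
#' @export
load_common_scenario_fixture <- function() {
  path <- system.file("extdata", "common_scenario_counts.csv",
                      package = "acrodat", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, c("n_s", "n_mda", "n_sda")])
  dimnames(counts) <- list(as.character(tab$scenario_id), RATING_LEVELS)
  stopifnot(all(rowSums(counts) == 21L))
  list(
    table = tab,
    counts = counts,
    pc_printed = c(`S` = 0.295, `M-DA` = 0.305, `S-DA` = 0.400),
    kappa_printed = 0.526
  )
}

#' Enumerate count rows consistent with a printed digit string and Pr
#'
#' The published table concatenates each scenario's three category
#' counts into a single digit string, which is ambiguous (e.g.
#' `"1911"` could be 19/1/1 or 1/9/11). This utility enumerates every
#' composition of `n` raters into three counts whose concatenation
#' equals the digit string and whose pairwise agreement matches the
#' printed Pr within `tol`. A unique candidate disambiguates the row.
#'
#' @param digits Digit string as printed, e.g. `"1911"`.
#' @param pr Printed per-scenario agreement.
#' @param n Raters per scenario (21).
#' @param tol Absolute tolerance on Pr (printed to 3 decimals).
#' @return Matrix of candidate count rows (possibly zero rows).
#' @export
partition_candidates <- function(digits, pr, n = 21L, tol = 5e-4) {
  out <- NULL
  for (a in 0:n) for (b in 0:(n - a)) {
    cc <- c(a, b, n - a - b)
    if (paste(cc, collapse = "") != digits) next
    if (abs(sum(cc * (cc - 1)) / (n * (n - 1)) - pr) < tol) {
      out <- rbind(out, cc)
    }
  }
  if (is.null(out)) out <- matrix(integer(0), 0L, 3L)
  dimnames(out) <- list(NULL, RATING_LEVELS)
  out
}
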