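# The disease-activity algorithm: non-compensatory gate, indicator
# coding, two-stage logistic model, probability combination, the 0-1
# activity score, and final classification.
#
# The gate encodes the validated non-compensatory finding: IGF-I at
# level 3 or tumor status at level 3 classifies the patient as S-DA
# outright, with no opportunity for the remaining parameters to
# compensate. Below the gate the parameters act compensatorily and a
# two-stage logistic model supplies the class probabilities:
# Model 1 predicts "stable vs not stable"; Model 2, fitted on the
# not-stable subset, predicts "significant vs mild disease activity".

gate_triggered <- function(levels) {
  m <- as_level_matrix(levels)
  m[, "igf"] == 3L | m[, "tumor"] == 3L
}

#' Indicator coding for the three-level parameters
#'
#' Builds the covariate coding used by the logistic submodels: for each
#' included parameter, indicator columns for levels 2 and 3 (level 1 is
#' the referent and is not coded). The default `"three_param"` coding
#' uses comorbidity, symptoms and QoL - the parameters that behave
#' compensatorily below the gate. `"five_param"` adds IGF-I and tumor
#' indicators as well (their level-3 indicators are constant zero on
#' gate-excluded data and fit to essentially nothing under the ridge);
#' the full five-parameter coding has 2 x 5 = 10 columns.
#'
#' @param coding `"three_param"`, `"five_param"`, or a character vector
#'   of parameter names to include.
#' @return Object of class `activity_coding` (list with `params`).
#' @export
activity_coding <- function(coding = c("three_param", "five_param")) {
  if (inherits(coding, "activity_coding")) return(coding)
  if (length(coding) == 1L && coding %in% c("three_param", "five_param")) {
    params <- if (coding == "three_param") {
      c("comorbidity", "symptoms", "qol")
    } else {
      PARAM_NAMES
    }
  } else if (length(coding) == 0L) {
    params <- character(0) # intercept-only models
  } else {
    params <- match.arg(coding, PARAM_NAMES, several.ok = TRUE)
  }
  structure(list(params = params), class = "activity_coding")
}

#' Expand level vectors into indicator covariates
#'
#' @param levels Level vector(s); see [encode_scenario()].
#' @param coding An [activity_coding()] (or its shorthand string).
#' @param intercept Prepend an intercept column.
#' @return Numeric matrix with two indicator columns (`<param>2`,
#'   `<param>3`) per included parameter.
#' @examples
#' code_covariates(c(1, 1, 1, 1, 1), "five_param") # all indicators 0
#' @export
code_covariates <- function(levels, coding = "three_param",
                            intercept = FALSE) {
  coding <- activity_coding(coding)
  m <- as_level_matrix(levels)
  cols <- lapply(coding$params, function(p) {
    out <- cbind(as.numeric(m[, p] == 2L), as.numeric(m[, p] == 3L))
    colnames(out) <- paste0(p, 2:3)
    out
  })
  X <- matrix(numeric(0), nrow = nrow(m), ncol = 0L)
  if (length(cols) > 0L) X <- do.call(cbind, cols)
  if (intercept) {
    X <- cbind(`(Intercept)` = rep(1, nrow(m)), X)
  }
  X
}

#' Fit the two-stage disease-activity model
#'
#' Rows that trigger the non-compensatory gate (IGF-I or tumor at
#' level 3) are excluded before fitting - the decision there is not
#' probabilistic. On the retained rows, Model 1 is a penalized
#' logistic regression of "stable" (S) against the indicator
#' covariates; Model 2 is fitted on the not-stable subset and predicts
#' S-DA against M-DA.
#'
#' @param levels Level vectors (matrix/data frame, one row per rated
#'   scenario presentation).
#' @param class Observed rating per row: `S`, `M-DA` or `S-DA`.
#' @param coding Covariate coding; see [activity_coding()].
#' @param ridge Ridge penalty for both submodels (default `1e-6`;
#'   guards against separation on small rating datasets).
#' @param mode Default probability-combination mode stored with the
#'   model; see [combine_probabilities()].
#' @return Object of class `activity_model`: gate rule, the two fitted
#'   submodels, coding and mode.
#' @export
fit_two_stage <- function(levels, class, coding = "three_param",
                          ridge = 1e-6, mode = c("literal", "conditional")) {
  mode <- match.arg(mode)
  coding <- activity_coding(coding)
  m <- as_level_matrix(levels)
  class <- as.character(class)
  if (length(class) != nrow(m)) abort_invalid("levels and class sizes disagree")
  if (!all(class %in% RATING_LEVELS)) {
    abort_invalid("class must be one of S, M-DA, S-DA")
  }
  keep <- !gate_triggered(m)
  if (!any(keep)) abort_invalid("no observations below the gate to fit on")
  m <- m[keep, , drop = FALSE]
  class <- class[keep]
  X <- code_covariates(m, coding, intercept = TRUE)
  model1 <- ridge_logistic(X, as.numeric(class == "S"), ridge = ridge)
  not_s <- class != "S"
  if (!any(not_s)) {
    abort_invalid("all retained ratings are S: Model 2 is degenerate",
                  class = "acrodat_degenerate")
  }
  model2 <- ridge_logistic(X[not_s, , drop = FALSE],
                           as.numeric(class[not_s] == "S-DA"), ridge = ridge)
  structure(
    list(
      coding = coding, model1 = model1, model2 = model2,
      mode = mode, ridge = ridge,
      n_fit = nrow(m), n_gate_excluded = sum(!keep)
    ),
    class = "activity_model"
  )
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf(
    "Two-stage disease-activity model (%s combination)\n", x$mode
  ))
  cat(sprintf(
    "Gate: IGF-I or tumor at level 3 -> S-DA (%d rows excluded from fit)\n",
    x$n_gate_excluded
  ))
  cat(sprintf(
    "Fitted on %d below-gate ratings; covariates: %s\n",
    x$n_fit, paste(x$coding$params, collapse = ", ")
  ))
  cat("Model 1 (S vs not-S) coefficients:\n")
  print(round(x$model1$coefficients, 4))
  cat("Model 2 (S-DA vs M-DA) coefficients:\n")
  print(round(x$model2$coefficients, 4))
  invisible(x)
}

#' Combine the two submodel predictions into class probabilities
#'
#' In `"literal"` mode, P(S) is Model 1's prediction, P(S-DA) is Model
#' 2's prediction taken unconditionally, and P(M-DA) is one minus the
#' other two; because the two submodels are fitted on different
#' subsets, that remainder can be negative, in which case it is clamped
#' to zero, the triple renormalized, and the row flagged in the
#' `clamped` attribute. In `"conditional"` mode Model 2's prediction is
#' treated as P(S-DA | not S), so P(S-DA) = (1 - P(S)) x Model 2 and
#' the remainder is never negative.
#'
#' @param model Fitted [fit_two_stage()] model.
#' @param levels Level vector(s); must not trigger the gate.
#' @param mode Override the model's stored combination mode.
#' @return Data frame with columns `p_s`, `p_mda`, `p_sda` (rows sum to
#'   1) and attribute `clamped` (logical per row, literal mode only).
#' @export
combine_probabilities <- function(model, levels, mode = NULL) {
  if (!inherits(model, "activity_model")) {
    abort_invalid("`model` must come from fit_two_stage()")
  }
  mode <- if (is.null(mode)) model$mode else
    match.arg(mode, c("literal", "conditional"))
  m <- as_level_matrix(levels)
  if (any(gate_triggered(m))) {
    abort_invalid(
      "gate-triggering level vector: use classify_activity(), not the probability model",
      class = "acrodat_gate"
    )
  }
  X <- code_covariates(m, model$coding, intercept = TRUE)
  p_s <- predict_logistic(model$model1, X)
  p2 <- predict_logistic(model$model2, X)
  clamped <- rep(FALSE, nrow(m))
  if (mode == "literal") {
    p_sda <- p2
    p_mda <- 1 - p_s - p_sda
    clamped <- p_mda < 0
    if (any(clamped)) {
      warning(sprintf(
        "%d row(s) produced a negative mild-activity remainder; clamped and renormalized",
        sum(clamped)
      ), call. = FALSE)
      p_mda[clamped] <- 0
      tot <- p_s + p_mda + p_sda
      p_s <- p_s / tot
      p_mda <- p_mda / tot
      p_sda <- p_sda / tot
    }
  } else {
    p_sda <- (1 - p_s) * p2
    p_mda <- (1 - p_s) * (1 - p2)
  }
  out <- data.frame(p_s = p_s, p_mda = p_mda, p_sda = p_sda)
  attr(out, "clamped") <- clamped
  out
}

#' The continuous 0-1 disease-activity score
#'
#' A weighted average of the class probabilities rescaled to the unit
#' interval: `score = ((1 * p_s + 2 * p_mda + 3 * p_sda) - 1) / 2`.
#' 0 is certainly stable, 1 certainly significant activity, and a
#' point mass on mild activity scores 0.5.
#'
#' @param p Probability triple(s): a length-3 vector `(p_s, p_mda,
#'   p_sda)`, a 3-column matrix, or the data frame returned by
#'   [combine_probabilities()].
#' @return Numeric score(s) in \[0, 1\].
#' @examples
#' acrodat_score(c(0, 1, 0)) # 0.5
#' @export
acrodat_score <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("p_s", "p_mda", "p_sda")])
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  if (ncol(p) != 3L) abort_invalid("probability input must have 3 components")
  if (anyNA(p) || any(p < -1e-9) ||
      any(abs(rowSums(p) - 1) > 1e-6)) {
    abort_invalid("probabilities must be non-negative and sum to 1")
  }
  as.numeric((p %*% c(1, 2, 3) - 1) / 2)
}

#' Classify disease activity for level vectors
#'
#' The full algorithm: level vectors with IGF-I or tumor status at
#' level 3 are classified S-DA immediately by the non-compensatory
#' gate (reported with score 1 and no probability triple). Below the
#' gate, class probabilities come from the two-stage model and the
#' class is M-DA when P(M-DA) exceeds P(S), S when P(S) exceeds
#' P(M-DA), and M-DA on an exact tie (the cautious direction: further
#' evaluation).
#'
#' @inheritParams combine_probabilities
#' @return Data frame with columns `class`, `gate` (logical), `p_s`,
#'   `p_mda`, `p_sda` (NA on gate rows) and `score`.
#' @export
classify_activity <- function(model, levels, mode = NULL) {
  if (!inherits(model, "activity_model")) {
    abort_invalid("`model` must come from fit_two_stage()")
  }
  m <- as_level_matrix(levels)
  gate <- gate_triggered(m)
  out <- data.frame(
    class = character(nrow(m)), gate = gate,
    p_s = NA_real_, p_mda = NA_real_, p_sda = NA_real_,
    score = NA_real_
  )
  out$class[gate] <- "S-DA"
  out$score[gate] <- 1
  if (any(!gate)) {
    pr <- combine_probabilities(model, m[!gate, , drop = FALSE], mode = mode)
    out[!gate, c("p_s", "p_mda", "p_sda")] <- pr
    out$score[!gate] <- acrodat_score(pr)
    out$class[!gate] <- ifelse(pr$p_s > pr$p_mda, "S", "M-DA")
  }
  out
}

#' Score the full 243-scenario grid
#'
#' @inheritParams combine_probabilities
#' @return Data frame of 243 rows: `scenario_id`, the five levels, and
#'   the [classify_activity()] columns.
#' @export
score_all_scenarios <- function(model, mode = NULL) {
  grid <- enumerate_scenarios()
  res <- classify_activity(model, grid[PARAM_NAMES], mode = mode)
  cbind(scenario_id = grid$id, grid[PARAM_NAMES], res)
}
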