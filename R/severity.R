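# Severity grading of the five health-status parameters.
#
# Each classifier maps raw clinical measurements to an ordinal severity
# level: 1 = adequately controlled, 2 = mild disease activity (further
# evaluation), 3 = significant disease activity (clinical action).
# All classifiers are vectorized over patients and refuse missing input:
# a scorer intended for clinical decision support must not impute.

#' Grade IGF-I relative to the assay normal range
#'
#' IGF-I is graded against the age-adjusted assay normal range:
#' level 1 when the value lies within \[LLN, ULN\]; level 2 when it
#' exceeds the ULN by no more than 20\% (value <= 1.2 x ULN) or falls
#' below the LLN; level 3 when it exceeds 1.2 x ULN. The value
#' 1.2 x ULN itself is level 2 (the level-3 inequality is strict), and
#' a value exactly at the ULN is level 1 (within normal limits).
#'
#' @param value IGF-I concentration(s), same units as the limits.
#' @param lln,uln Lower/upper limit of the assay's age-adjusted normal
#'   range; recycled against `value`.
#' @return Integer vector of severity levels in \{1, 2, 3\}.
#' @examples
#' classify_igf(250, lln = 100, uln = 200) # 1.25 x ULN -> 3
#' classify_igf(240, lln = 100, uln = 200) # exactly 1.2 x ULN -> 2
#' classify_igf(c(150, 90), lln = 100, uln = 200)
#' @export
classify_igf <- function(value, lln, uln) {
  n <- max(length(value), length(lln), length(uln))
  value <- rep_len(as.numeric(value), n)
  lln <- rep_len(as.numeric(lln), n)
  uln <- rep_len(as.numeric(uln), n)
  if (anyNA(value) || anyNA(lln) || anyNA(uln)) {
    abort_invalid("IGF-I measurement contains missing values")
  }
  if (any(value <= 0)) abort_invalid("IGF-I value must be positive")
  if (any(lln <= 0) || any(lln >= uln)) {
    abort_invalid("IGF-I limits must satisfy 0 < LLN < ULN")
  }
  ifelse(value > 1.2 * uln, 3L,
    ifelse(value > uln | value < lln, 2L, 1L)
  )
}

#' Grade tumor status from the most current MRI
#'
#' Level 3 when a clinically significant change is seen: growth of more
#' than 20\% versus the prior MRI, increased invasiveness, or worsening
#' vision. Level 2 for a slight increase in size (0 < change <= 20\%).
#' Level 1 when the tumor is not visible, unchanged, or smaller
#' (a reduction is an improvement, not mild activity).
#'
#' @param visible Logical; is the tumor visible on MRI?
#' @param size_change_pct Signed percent change in tumor size versus the
#'   prior MRI; must be `NA` when `visible` is `FALSE` (no mass to
#'   measure) and may be `NA` when no prior MRI exists (treated as no
#'   documented change).
#' @param invasiveness_increased Logical; increased invasiveness since
#'   the prior MRI.
#' @param vision_worsened Logical; worsening of vision attributable to
#'   mass effect.
#' @return Integer vector of severity levels in \{1, 2, 3\}.
#' @examples
#' classify_tumor(TRUE, 25, FALSE, FALSE)  # >20% growth -> 3
#' classify_tumor(TRUE, 10, FALSE, FALSE)  # slight increase -> 2
#' classify_tumor(FALSE, NA, FALSE, FALSE) # not visible -> 1
#' @export
classify_tumor <- function(visible, size_change_pct = NA_real_,
                           invasiveness_increased = FALSE,
                           vision_worsened = FALSE) {
  n <- max(
    length(visible), length(size_change_pct),
    length(invasiveness_increased), length(vision_worsened)
  )
  visible <- rep_len(as.logical(visible), n)
  size_change_pct <- rep_len(as.numeric(size_change_pct), n)
  invasiveness_increased <- rep_len(as.logical(invasiveness_increased), n)
  vision_worsened <- rep_len(as.logical(vision_worsened), n)
  if (anyNA(visible) || anyNA(invasiveness_increased) || anyNA(vision_worsened)) {
    abort_invalid("tumor assessment flags must not be missing")
  }
  if (any(!visible & !is.na(size_change_pct))) {
    abort_invalid("size_change_pct must be NA when the tumor is not visible")
  }
  change <- ifelse(is.na(size_change_pct), 0, size_change_pct)
  ifelse(change > 20 | invasiveness_increased | vision_worsened, 3L,
    ifelse(visible & change > 0, 2L, 1L)
  )
}

COMORBIDITY_CODES <- list(
  diabetes = c("none", "controlled", "uncontrolled"),
  sleep_apnea = c("absent", "mild", "moderate_severe"),
  cardiac = c("absent", "controlled", "uncontrolled")
)

#' Grade the comorbidity profile
#'
#' Considers the three acromegaly-associated comorbidities the tool
#' tracks: diabetes, sleep apnea and cardiac disease. Any of
#' uncontrolled diabetes, moderate-to-severe sleep apnea or
#' uncontrolled cardiac disease forces level 3. Level 1 requires no
#' diabetes diagnosis, no sleep apnea complaints and cardiac disease
#' (if present) well controlled. Everything in between - controlled
#' diabetes, mild sleep apnea - is level 2.
#'
#' @param diabetes One of `"none"`, `"controlled"`, `"uncontrolled"`.
#' @param sleep_apnea One of `"absent"`, `"mild"`, `"moderate_severe"`.
#' @param cardiac One of `"absent"`, `"controlled"`, `"uncontrolled"`.
#' @return Integer vector of severity levels in \{1, 2, 3\}.
#' @examples
#' classify_comorbidity("none", "absent", "controlled")      # 1
#' classify_comorbidity("controlled", "absent", "controlled") # 2
#' classify_comorbidity("uncontrolled", "absent", "absent")   # 3
#' @export
classify_comorbidity <- function(diabetes, sleep_apnea, cardiac) {
  n <- max(length(diabetes), length(sleep_apnea), length(cardiac))
  diabetes <- rep_len(as.character(diabetes), n)
  sleep_apnea <- rep_len(as.character(sleep_apnea), n)
  cardiac <- rep_len(as.character(cardiac), n)
  check_codes <- function(x, field) {
    if (anyNA(x) || !all(x %in% COMORBIDITY_CODES[[field]])) {
      abort_invalid(paste0(
        "`", field, "` must be one of: ",
        paste(COMORBIDITY_CODES[[field]], collapse = ", ")
      ))
    }
  }
  check_codes(diabetes, "diabetes")
  check_codes(sleep_apnea, "sleep_apnea")
  check_codes(cardiac, "cardiac")
  level3 <- diabetes == "uncontrolled" | sleep_apnea == "moderate_severe" |
    cardiac == "uncontrolled"
  level1 <- diabetes == "none" & sleep_apnea == "absent" &
    cardiac %in% c("absent", "controlled")
  ifelse(level3, 3L, ifelse(level1, 1L, 2L))
}

validate_sss <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) == 1L && nrow(items) == 5L) items <- t(items)
  if (ncol(items) != 5L) {
    abort_invalid("SSS responses must have exactly 5 items")
  }
  if (anyNA(items) || any(items != round(items)) ||
      any(items < 0) || any(items > 8)) {
    abort_invalid("SSS items must be integers in [0, 8]")
  }
  storage.mode(items) <- "integer"
  items
}

#' Total the Signs and Symptoms Score
#'
#' The SSS is a five-item disease-specific questionnaire (headache,
#' perspiration, joint pain, fatigue, soft-tissue swelling), each item
#' scored 0-8. The total ranges 0-40; 40 indicates severe signs and
#' symptoms.
#'
#' @param items Integer vector of 5 item scores, or a matrix/data frame
#'   with one row per patient and 5 columns.
#' @return Integer total(s) in \[0, 40\].
#' @examples
#' sss_total(c(8, 8, 8, 8, 8)) # 40
#' @export
sss_total <- function(items) {
  as.integer(rowSums(validate_sss(items)))
}

#' Grade symptoms from the SSS
#'
#' Level 3 when symptoms are significant: mean item score above 4 or
#' any single item above 6. Level 1 when all items are rated 2 or less.
#' Level 2 otherwise (some symptoms present, none exceeding 6, mean at
#' most 4). The level-3 test takes precedence, then level 1.
#'
#' @inheritParams sss_total
#' @return Integer vector of severity levels in \{1, 2, 3\}.
#' @examples
#' classify_sss(c(2, 2, 1, 0, 2)) # 1
#' classify_sss(c(3, 3, 3, 3, 3)) # 2
#' classify_sss(c(0, 0, 0, 0, 7)) # 3
#' @export
classify_sss <- function(items) {
  items <- validate_sss(items)
  mean_score <- rowMeans(items)
  max_score <- apply(items, 1L, max)
  ifelse(mean_score > 4 | max_score > 6, 3L,
    ifelse(max_score <= 2, 1L, 2L)
  )
}

validate_acroqol <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) == 1L && nrow(items) == 22L) items <- t(items)
  if (ncol(items) != 22L) {
    abort_invalid("AcroQoL responses must have exactly 22 items")
  }
  if (anyNA(items) || any(items != round(items)) ||
      any(items < 1) || any(items > 5)) {
    abort_invalid("AcroQoL items must be integers in [1, 5]")
  }
  storage.mode(items) <- "integer"
  items
}

#' Standardize an AcroQoL raw total to a 0-100 percentage
#'
#' AcroQoL has 22 items scored 1-5, so raw totals span 22-110, with 110
#' the best possible quality of life. The standardized score is the
#' linear rescaling of that range to 0-100:
#' `100 * (raw - 22) / (110 - 22)`.
#'
#' @param items Integer vector of 22 item scores, or a matrix/data
#'   frame with one row per patient and 22 columns.
#' @return Numeric percentage(s) in \[0, 100\].
#' @examples
#' acroqol_standardize(rep(5, 22)) # 100
#' acroqol_standardize(rep(3, 22)) # 50
#' @export
acroqol_standardize <- function(items) {
  raw <- rowSums(validate_acroqol(items))
  100 * (raw - 22) / 88
}

#' Grade quality-of-life impairment from a standardized AcroQoL score
#'
#' Level 1 (no or minimal impairment) at 60 or above, level 2 (mild to
#' moderate) in \[40, 60), level 3 (significant impairment) below 40.
#' Both printed thresholds are inclusive on the milder side: exactly 60
#' is level 1 and exactly 40 is level 2.
#'
#' @param pct Standardized AcroQoL percentage(s) in \[0, 100\].
#' @return Integer vector of severity levels in \{1, 2, 3\}.
#' @examples
#' classify_qol(c(60, 40, 39.9)) # 1 2 3
#' @export
classify_qol <- function(pct) {
  pct <- as.numeric(pct)
  if (anyNA(pct) || any(pct < 0) || any(pct > 100)) {
    abort_invalid("standardized QoL score must be in [0, 100]")
  }
  ifelse(pct >= 60, 1L, ifelse(pct >= 40, 2L, 3L))
}

PATIENT_COLUMNS <- c(
  "igf_value", "igf_lln", "igf_uln",
  "tumor_visible", "tumor_change_pct", "tumor_invasive", "vision_worse",
  "diabetes", "sleep_apnea", "cardiac",
  paste0("sss_", 1:5), paste0("qol_", 1:22)
)

#' Assess complete patient records into five-parameter level vectors
#'
#' Applies the five severity classifiers in the canonical parameter
#' order (IGF-I, tumor, comorbidity, symptoms, QoL) to a data frame of
#' complete patient records and attaches the scenario index of each
#' resulting level vector. Partial records are refused: every scoring
#' component must be present.
#'
#' @param patients Data frame with one row per patient and the columns
#'   `igf_value`, `igf_lln`, `igf_uln`, `tumor_visible`,
#'   `tumor_change_pct`, `tumor_invasive`, `vision_worse`, `diabetes`,
#'   `sleep_apnea`, `cardiac`, `sss_1`..`sss_5`, `qol_1`..`qol_22`
#'   (see [read_patients()]).
#' @return Data frame with columns `igf`, `tumor`, `comorbidity`,
#'   `symptoms`, `qol` (each in 1..3) and `scenario_id` (1..243).
#' @seealso [classify_igf()], [classify_tumor()],
#'   [classify_comorbidity()], [classify_sss()], [classify_qol()],
#'   [encode_scenario()]
#' @export
assess_patients <- function(patients) {
  if (!is.data.frame(patients)) {
    abort_invalid("`patients` must be a data frame")
  }
  missing_cols <- setdiff(PATIENT_COLUMNS, names(patients))
  if (length(missing_cols) > 0L) {
    abort_invalid(paste0(
      "incomplete patient record: missing column(s) ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  sss_items <- as.matrix(patients[paste0("sss_", 1:5)])
  qol_items <- as.matrix(patients[paste0("qol_", 1:22)])
  levels <- data.frame(
    igf = classify_igf(patients$igf_value, patients$igf_lln, patients$igf_uln),
    tumor = classify_tumor(
      patients$tumor_visible, patients$tumor_change_pct,
      patients$tumor_invasive, patients$vision_worse
    ),
    comorbidity = classify_comorbidity(
      patients$diabetes, patients$sleep_apnea, patients$cardiac
    ),
    symptoms = classify_sss(sss_items),
    qol = classify_qol(acroqol_standardize(qol_items))
  )
  levels$scenario_id <- encode_scenario(levels)
  levels
}
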