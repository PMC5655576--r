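# Synthetic physician-rating simulator.
#
# Each rating comes from a latent-Gaussian ordinal model: a scenario's
# latent severity is u = sum_k w_k (level_k - 1) + rater bias + noise,
# and the rating is S below the first cutpoint, M-DA between the two,
# S-DA above the second. Rater heterogeneity is an additive Gaussian
# bias per rater; everything else is i.i.d. Gaussian noise, so the
# marginal class probabilities have a closed form through the combined
# standard deviation sqrt(rater_bias_sd^2 + noise_sd^2). With
# gate_in_truth the generative process itself applies the
# non-compensatory rule: IGF-I or tumor at level 3 forces S-DA.

#' Simulator configuration
#'
#' Defaults emulate the validation survey's shape (21 raters, 52
#' scenarios each including the 10 common ones) with severity weights
#' and noise chosen so that common-scenario agreement lands in the
#' moderate kappa band typical of clinician vignette studies.
#'
#' @param n_raters Number of simulated raters.
#' @param per_rater Scenarios per rater (including the common set).
#' @param common_ids Common scenarios rated by everyone.
#' @param weights Five non-negative per-parameter weights on
#'   `level - 1`, in canonical parameter order.
#' @param gate_in_truth Force S-DA for IGF-I/tumor level-3 scenarios in
#'   the generative truth.
#' @param cutpoints Two increasing latent thresholds (S / M-DA and
#'   M-DA / S-DA).
#' @param rater_bias_sd SD of the per-rater additive bias.
#' @param noise_sd SD of the per-rating noise.
#' @param seed Integer seed; fully determines the simulated dataset.
#' @param design_method Fill method for [build_survey_design()].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_raters = 21L, per_rater = 52L,
                       common_ids = common_scenario_ids(),
                       weights = c(0.8, 0.8, 0.5, 0.5, 0.5),
                       gate_in_truth = TRUE,
                       cutpoints = c(0.7, 1.9),
                       rater_bias_sd = 0.3, noise_sd = 0.85,
                       seed = 1L,
                       design_method = c("stratified", "simple")) {
  if (length(weights) != 5L || anyNA(weights) || any(weights < 0)) {
    abort_invalid("weights must be 5 non-negative numbers")
  }
  if (length(cutpoints) != 2L || !(cutpoints[1] < cutpoints[2])) {
    abort_invalid("cutpoints must be two strictly increasing numbers")
  }
  if (rater_bias_sd < 0 || noise_sd < 0) {
    abort_invalid("standard deviations must be non-negative")
  }
  structure(
    list(
      n_raters = as.integer(n_raters), per_rater = as.integer(per_rater),
      common_ids = as.integer(common_ids),
      weights = as.numeric(weights),
      gate_in_truth = isTRUE(gate_in_truth),
      cutpoints = as.numeric(cutpoints),
      rater_bias_sd = as.numeric(rater_bias_sd),
      noise_sd = as.numeric(noise_sd),
      seed = as.integer(seed),
      design_method = match.arg(design_method)
    ),
    class = "sim_config"
  )
}

latent_mean <- function(cfg, levels) {
  drop(as_level_matrix(levels) %*% cfg$weights) - sum(cfg$weights)
}

#' Closed-form true class probabilities per scenario
#'
#' Marginal probabilities of each rating under the latent-Gaussian
#' model, for all 243 scenarios: with combined SD
#' `sigma = sqrt(rater_bias_sd^2 + noise_sd^2)` and latent mean `mu`,
#' `P(S) = Phi((c1 - mu)/sigma)`, `P(S-DA) = 1 - Phi((c2 - mu)/sigma)`
#' and `P(M-DA)` the remainder. When both SDs are zero the
#' probabilities are degenerate 0/1 indicators of the interval
#' containing `mu`. Gate scenarios are a point mass on S-DA when
#' `gate_in_truth` is set.
#'
#' @param cfg A [sim_config()].
#' @return 243 x 3 matrix of probabilities (rows sum to 1), rows named
#'   by scenario id.
#' @export
truth_probabilities <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  grid <- enumerate_scenarios()
  mu <- latent_mean(cfg, grid[PARAM_NAMES])
  sigma <- sqrt(cfg$rater_bias_sd^2 + cfg$noise_sd^2)
  if (sigma == 0) {
    p_s <- as.numeric(mu < cfg$cutpoints[1])
    p_sda <- as.numeric(mu >= cfg$cutpoints[2])
  } else {
    p_s <- stats::pnorm((cfg$cutpoints[1] - mu) / sigma)
    p_sda <- stats::pnorm((cfg$cutpoints[2] - mu) / sigma,
                          lower.tail = FALSE)
  }
  P <- cbind(p_s, 1 - p_s - p_sda, p_sda)
  if (cfg$gate_in_truth) {
    gate <- gate_triggered(grid[PARAM_NAMES])
    P[gate, ] <- rep(c(0, 0, 1), each = sum(gate))
  }
  dimnames(P) <- list(as.character(grid$id), RATING_LEVELS)
  P
}

#' Simulate a physician rating dataset
#'
#' Draws a survey design via [build_survey_design()], one Gaussian bias
#' per rater and one Gaussian noise term per rating, then thresholds
#' the latent severity at the configured cutpoints. Identical seeds
#' give identical datasets.
#'
#' @param cfg A [sim_config()].
#' @return List with `ratings` (long data frame: `rater_id`,
#'   `scenario_id`, `rating`), `design` (the survey design) and
#'   `truth` (the [truth_probabilities()] matrix).
#' @export
simulate_ratings <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  design <- build_survey_design(
    cfg$n_raters, cfg$per_rater, cfg$common_ids,
    seed = cfg$seed, method = cfg$design_method
  )
  grid <- enumerate_scenarios()
  mu_all <- latent_mean(cfg, grid[PARAM_NAMES])
  gate_all <- gate_triggered(grid[PARAM_NAMES])
  ratings <- with_seed(cfg$seed + 1L, {
    bias <- stats::rnorm(cfg$n_raters, 0, cfg$rater_bias_sd)
    rows <- lapply(seq_len(cfg$n_raters), function(r) {
      ids <- design$assignments[[r]]
      u <- mu_all[ids] + bias[r] +
        stats::rnorm(length(ids), 0, cfg$noise_sd)
      rating <- ifelse(u < cfg$cutpoints[1], "S",
        ifelse(u < cfg$cutpoints[2], "M-DA", "S-DA")
      )
      if (cfg$gate_in_truth) rating[gate_all[ids]] <- "S-DA"
      data.frame(rater_id = r, scenario_id = ids, rating = rating)
    })
    do.call(rbind, rows)
  })
  ratings <- validate_ratings(ratings)
  list(ratings = ratings, design = design,
       truth = truth_probabilities(cfg))
}
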