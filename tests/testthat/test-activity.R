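# The activity algorithm: covariate coding, the two-stage logistic
# model, probability combination, the 0-1 score, and classification.

test_that("indicator coding produces two columns per parameter with level 1 as referent", {
  X <- code_covariates(c(1, 1, 1, 1, 1), "five_param")
  expect_identical(ncol(X), 10L)
  expect_true(all(X == 0))
  X3 <- code_covariates(c(2, 2, 3, 2, 1), "three_param")
  expect_identical(colnames(X3),
                   c("comorbidity2", "comorbidity3", "symptoms2",
                     "symptoms3", "qol2", "qol3"))
  expect_identical(as.numeric(X3), c(0, 1, 1, 0, 0, 0))
  # one-hot sanity over the full grid: each parameter contributes
  # exactly one active indicator at levels 2 and 3, none at level 1
  grid <- enumerate_scenarios()
  Xg <- code_covariates(grid[-1], "five_param")
  expect_true(all(rowSums(Xg) == rowSums(grid[-1] > 1)))
})

test_that("ridge IRLS agrees with glm on clean data and flags separation without ridge", {
  set.seed(10)
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(500), x2 = rbinom(500, 1, 0.4))
  eta <- -0.5 + 0.8 * X[, 2] - 1.2 * X[, 3]
  y <- rbinom(500, 1, plogis(eta))
  ours <- acrodat:::ridge_logistic(X, y, ridge = 0)
  ref <- glm.fit(X, y, family = binomial())
  expect_equal(unname(ours$coefficients), unname(ref$coefficients),
               tolerance = 1e-6)
  # complete separation: unpenalized fit refuses, ridge survives
  ysep <- as.numeric(X[, 2] > 0)
  expect_error(acrodat:::ridge_logistic(X, ysep, ridge = 0),
               class = "acrodat_nonconvergence")
  fit <- acrodat:::ridge_logistic(X, ysep, ridge = 1e-2)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("gate rows are excluded from both submodel fits", {
  set.seed(2)
  grid <- enumerate_scenarios()
  lv <- grid[rep(1:243, 4), -1]
  cls <- sample(c("S", "M-DA", "S-DA"), nrow(lv), replace = TRUE)
  fit <- fit_two_stage(lv, cls)
  expect_identical(fit$n_gate_excluded, 4L * 135L)
  expect_identical(fit$n_fit, 4L * 108L)
})

test_that("intercept-only two-stage fit reproduces closed-form empirical proportions", {
  set.seed(5)
  n <- 2000
  lv <- matrix(sample(1:2, n * 5, replace = TRUE), ncol = 5) # no gate rows
  cls <- sample(c("S", "M-DA", "S-DA"), n, replace = TRUE,
                prob = c(0.5, 0.3, 0.2))
  fit <- fit_two_stage(lv, cls, coding = character(0), ridge = 0)
  p_s_hat <- plogis(fit$model1$coefficients[["(Intercept)"]])
  expect_equal(p_s_hat, mean(cls == "S"), tolerance = 1e-6)
  p2_hat <- plogis(fit$model2$coefficients[["(Intercept)"]])
  expect_equal(p2_hat, mean(cls[cls != "S"] == "S-DA"), tolerance = 1e-6)
})

test_that("covariate-independent outcomes give near-zero slopes and base-rate intercept", {
  set.seed(6)
  n <- 4000
  lv <- cbind(
    sample(1:2, n, TRUE), sample(1:2, n, TRUE),
    sample(1:3, n, TRUE), sample(1:3, n, TRUE), sample(1:3, n, TRUE)
  )
  cls <- sample(c("S", "M-DA", "S-DA"), n, replace = TRUE)
  fit <- fit_two_stage(lv, cls)
  slopes <- fit$model1$coefficients[-1]
  expect_lt(max(abs(slopes)), 3.5 * max(fit$model1$se[-1]))
  # the intercept estimates P(S) at the reference cell; under
  # independence that is the overall base rate, up to sampling noise
  expect_equal(plogis(fit$model1$coefficients[["(Intercept)"]]), 1 / 3,
               tolerance = 0.1)
})

test_that("known two-stage logistic coefficients are recovered within 3 standard errors", {
  # generate straight from the fitted family so the generator's
  # coefficients are the estimand
  set.seed(77)
  n <- 5000
  lv <- cbind(1L, 1L,
              sample(1:3, n, TRUE), sample(1:3, n, TRUE),
              sample(1:3, n, TRUE))
  X <- code_covariates(lv, "three_param", intercept = TRUE)
  b1 <- c(0.8, -0.6, -1.2, -0.5, -1.0, -0.4, -0.8)
  b2 <- c(-1.5, 0.7, 1.4, 0.6, 1.1, 0.5, 0.9)
  p_s <- plogis(drop(X %*% b1))
  s <- rbinom(n, 1, p_s)
  p2 <- plogis(drop(X %*% b2))
  cls <- ifelse(s == 1, "S", ifelse(rbinom(n, 1, p2) == 1, "S-DA", "M-DA"))
  fit <- fit_two_stage(lv, cls, coding = "three_param")
  expect_true(all(abs(fit$model1$coefficients - b1) < 3 * fit$model1$se))
  expect_true(all(abs(fit$model2$coefficients - b2) < 3 * fit$model2$se))
})

test_that("probability combination follows the stated arithmetic in both modes", {
  # build a model with hand-set coefficients so submodel outputs are known
  fit <- structure(list(
    coding = activity_coding(character(0)),
    model1 = list(coefficients = c(`(Intercept)` = qlogis(0.5))),
    model2 = list(coefficients = c(`(Intercept)` = qlogis(0.2))),
    mode = "literal", ridge = 0
  ), class = "activity_model")
  v <- c(1, 1, 1, 1, 1)
  p <- combine_probabilities(fit, v, mode = "literal")
  expect_equal(as.numeric(p), c(0.5, 0.3, 0.2))
  p <- combine_probabilities(fit, v, mode = "conditional")
  expect_equal(as.numeric(p), c(0.5, 0.4, 0.1))
  # incoherent literal case: clamp, renormalize, warn
  fit$model1$coefficients <- c(`(Intercept)` = qlogis(0.9))
  fit$model2$coefficients <- c(`(Intercept)` = qlogis(0.4))
  expect_warning(p <- combine_probabilities(fit, v, mode = "literal"),
                 "clamped")
  expect_equal(p$p_mda, 0)
  expect_equal(rowSums(p), 1, ignore_attr = TRUE)
  expect_true(attr(p, "clamped")[1])
  # gate rows are refused by the probability path
  expect_error(combine_probabilities(fit, c(3, 1, 1, 1, 1)),
               class = "acrodat_gate")
})

test_that("combined probabilities sum to one in both modes for random submodels", {
  set.seed(14)
  v <- as.matrix(expand.grid(igf = 1:2, tumor = 1:2, comorbidity = 1:3,
                             symptoms = 1:3, qol = 1:3))
  for (i in 1:20) {
    fit <- structure(list(
      coding = activity_coding("three_param"),
      model1 = list(coefficients = rnorm(7, 0, 2)),
      model2 = list(coefficients = rnorm(7, 0, 2)),
      mode = "literal", ridge = 0
    ), class = "activity_model")
    names(fit$model1$coefficients) <- names(fit$model2$coefficients) <-
      c("(Intercept)", colnames(code_covariates(v[1, ], "three_param")))
    for (mode in c("literal", "conditional")) {
      p <- suppressWarnings(combine_probabilities(fit, v, mode = mode))
      expect_equal(rowSums(p), rep(1, nrow(v)), tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_true(all(as.matrix(p) >= -1e-12))
    }
  }
})

test_that("the 0-1 score is the stated linear functional of the probability triple", {
  expect_equal(acrodat_score(c(1, 0, 0)), 0)
  expect_equal(acrodat_score(c(0, 1, 0)), 0.5)
  expect_equal(acrodat_score(c(0, 0, 1)), 1)
  expect_equal(acrodat_score(c(0.25, 0.5, 0.25)), 0.5)
  # linearity over the simplex: score = 0.5 p_mda + 1 p_sda
  set.seed(31)
  raw <- matrix(rexp(3000), ncol = 3)
  p <- raw / rowSums(raw)
  expect_equal(acrodat_score(p), 0.5 * p[, 2] + p[, 3])
  expect_true(all(acrodat_score(p) >= 0 & acrodat_score(p) <= 1))
  expect_error(acrodat_score(c(0.5, 0.2, 0.2)), class = "acrodat_invalid")
})

test_that("classification applies the gate first, then the P(S) vs P(M-DA) comparison", {
  set.seed(50)
  sim <- simulate_ratings(sim_config(n_raters = 40L, per_rater = 100L,
                                     seed = 13L))
  lv <- decode_scenario(sim$ratings$scenario_id)
  fit <- fit_two_stage(lv, sim$ratings$rating)
  out <- classify_activity(fit, rbind(c(3, 1, 1, 1, 1), c(1, 3, 1, 1, 1)))
  expect_identical(out$class, c("S-DA", "S-DA"))
  expect_identical(out$score, c(1, 1))
  expect_true(all(out$gate))
  # the mildest profile is rated stable by a model fitted to a
  # generator that rates it S with high probability
  expect_gt(sim$truth["1", "S"], 0.75)
  out1 <- classify_activity(fit, c(1, 1, 1, 1, 1))
  expect_identical(out1$class, "S")
  expect_false(out1$gate)
})

test_that("the full-grid report flags all 135 gate scenarios and keeps scores in range", {
  sim <- simulate_ratings(sim_config(n_raters = 30L, per_rater = 80L,
                                     seed = 17L))
  fit <- fit_two_stage(decode_scenario(sim$ratings$scenario_id),
                       sim$ratings$rating)
  rep <- score_all_scenarios(fit)
  expect_identical(nrow(rep), 243L)
  expect_identical(sum(rep$igf == 3), 81L)
  expect_identical(sum(rep$tumor == 3), 81L)
  expect_identical(sum(rep$gate), 135L) # 81 + 81 - 27
  expect_true(all(rep$class[rep$gate] == "S-DA"))
  expect_true(all(rep$score >= 0 & rep$score <= 1))
  expect_identical(rep$class[rep$scenario_id == 243], "S-DA")
})
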