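# Ridge-penalized logistic regression by iteratively reweighted least
# squares. A small default ridge keeps the fit defined under complete
# separation, which is routine on vignette-sized rating datasets where
# some covariate cells are unanimous. The intercept is never penalized.

ridge_logistic <- function(X, y, weights = NULL, ridge = 1e-6,
                           max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (is.null(weights)) weights <- rep(1, length(y))
  if (nrow(X) != length(y)) abort_invalid("X and y sizes disagree")
  if (ridge < 0) abort_invalid("ridge penalty must be non-negative")
  p <- ncol(X)
  penalty <- diag(rep(ridge, p), p)
  if ("(Intercept)" %in% colnames(X)) {
    penalty[which(colnames(X) == "(Intercept)"), ] <- 0
  }
  beta <- rep(0, p)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    # penalized log-likelihood, with probabilities clamped for stability
    mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    ll <- sum(weights * (y * log(mu_c) + (1 - y) * log(1 - mu_c))) -
      0.5 * drop(t(beta) %*% penalty %*% beta)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    w <- weights * mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / (mu * (1 - mu) + 1e-10)
    XtW <- t(X * w)
    beta <- tryCatch(
      drop(solve(XtW %*% X + penalty, XtW %*% z)),
      error = function(e) {
        abort_invalid(
          "logistic fit failed (singular system); increase `ridge`",
          class = "acrodat_nonconvergence"
        )
      }
    )
  }
  if (!converged && ridge == 0) {
    abort_invalid(
      "logistic fit did not converge (possible complete separation); set ridge > 0",
      class = "acrodat_nonconvergence"
    )
  }
  names(beta) <- colnames(X)
  # observed-information covariance at the solution (penalty included)
  mu <- stats::plogis(drop(X %*% beta))
  info <- t(X * (weights * mu * (1 - mu))) %*% X + penalty
  vcov <- tryCatch(solve(info), error = function(e) NULL)
  se <- if (is.null(vcov)) rep(NA_real_, p) else sqrt(diag(vcov))
  names(se) <- colnames(X)
  list(
    coefficients = beta, se = se, converged = converged, iterations = it,
    loglik = ll, ridge = ridge
  )
}

predict_logistic <- function(fit, X) {
  as.numeric(stats::plogis(as.matrix(X) %*% fit$coefficients))
}
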