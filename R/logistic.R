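# Internal logistic-regression workhorses.
#
# All engines take an explicit design matrix (intercept included by the
# caller) and a 0/1 outcome. Maximum-likelihood fits go through
# stats::glm.fit; complete or quasi-complete separation is detected from
# runaway coefficients and handled by a Firth-type penalized fit so that
# sparse genotype cells (a handful of familial cases) still yield finite
# estimates.

logit_fit <- function(X, y) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  beta <- fit$coefficients
  p <- fit$fitted.values
  eps <- 1e-12
  ll <- sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  w <- p * (1 - p)
  cov <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e) NULL)
  separated <- !fit$converged || anyNA(beta) ||
    max(abs(beta[is.finite(beta)])) > 10 || is.null(cov)
  se <- if (is.null(cov)) rep(NA_real_, ncol(X)) else sqrt(diag(cov))
  list(coef = beta, se = se, loglik = ll, fitted = p,
       converged = fit$converged, separated = separated, firth = FALSE)
}

firth_fit <- function(X, y, maxit = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  inv <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    XW <- X * sqrt(w)
    inv <- tryCatch(solve(crossprod(XW)), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((XW %*% inv) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    delta <- drop(inv %*% U)
    # dampen large steps for stability
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta))
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  p <- plogis(drop(X %*% beta))
  eps <- 1e-12
  ll <- sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  se <- if (is.null(inv)) rep(NA_real_, ncol(X)) else sqrt(diag(inv))
  list(coef = beta, se = se, loglik = ll, fitted = p,
       converged = TRUE, separated = FALSE, firth = TRUE)
}

# ML fit with automatic Firth fallback on separation
logit_fit_safe <- function(X, y) {
  fit <- logit_fit(X, y)
  if (fit$separated) {
    fb <- firth_fit(X, y)
    fb$ml_loglik <- fit$loglik
    fb$firth <- TRUE
    fb
  } else {
    fit$ml_loglik <- fit$loglik
    fit
  }
}

# Fitted probabilities of the null logistic model y ~ 1 (+ sex).
# With a single binary covariate the model is saturated, so the MLE
# fitted values are the per-stratum affection rates.
null_probs <- function(y, sex) {
  if (is.null(sex) || length(unique(sex)) < 2) rep(mean(y), length(y))
  else ave(y, sex, FUN = mean)
}

# Rao score test for adding a binary indicator x to the null model with
# design Z (intercept + optional sex), evaluated at the null fit p0.
# Returns the chi-square statistic, its p-value and the score direction.
score_test_indicator <- function(x, y, p0, Z) {
  w <- p0 * (1 - p0)
  U <- sum(x * (y - p0))
  A <- crossprod(Z, Z * w)
  b <- crossprod(Z, w * x)
  quad <- tryCatch(drop(t(b) %*% solve(A, b)), error = function(e) NA_real_)
  V <- sum(w * x * x) - quad
  if (is.na(V) || V <= 1e-12)
    return(list(stat = 0, p = 1, direction = 0))
  stat <- U^2 / V
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       direction = sign(U))
}

# Wald test of a binary indicator in a sex-adjusted logistic model.
# Drops the sex column when it is constant (or absent). Falls back to a
# Firth fit under separation; the returned statistic is then the Firth
# Wald statistic and `firth` is flagged.
wald_indicator_test <- function(x, y, sex) {
  X <- cbind(`(Intercept)` = 1, x = x)
  if (!is.null(sex) && length(unique(sex)) > 1)
    X <- cbind(`(Intercept)` = 1, sex = sex, x = x)
  fit <- logit_fit_safe(X, y)
  j <- ncol(X)
  b <- unname(fit$coef[j])
  se <- unname(fit$se[j])
  if (is.na(b) || is.na(se) || se <= 0)
    return(list(stat = 0, p = 1, or = NA_real_, ci = c(NA_real_, NA_real_),
                firth = fit$firth))
  z <- b / se
  list(stat = z^2, p = pchisq(z^2, df = 1, lower.tail = FALSE),
       or = exp(b), ci = exp(b + c(-1, 1) * qnorm(0.975) * se),
       coef = b, se = se, firth = fit$firth)
}
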