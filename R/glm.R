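#' GLM family/link specification for payment models
#'
#' The three condition-specific pairs used by the payment measures are
#' allowed by default: inverse Gaussian with log link (AMI), Gamma with log
#' link (HF), Gamma with identity link (pneumonia). Other combinations are
#' opt-in via `allow_other`.
#'
#' @param family `"gamma"` or `"inverse_gaussian"`.
#' @param link `"log"` or `"identity"`.
#' @param allow_other allow pairs outside the three defaults.
#' @return object of class `glm_spec`.
#' @export
glm_spec <- function(family = c("gamma", "inverse_gaussian"),
                     link = c("log", "identity"), allow_other = FALSE) {
  family <- match.arg(family)
  link <- match.arg(link)
  allowed <- list(c("inverse_gaussian", "log"), c("gamma", "log"),
                  c("gamma", "identity"))
  if (!allow_other &&
      !any(vapply(allowed, function(p) all(p == c(family, link)), logical(1))))
    stop2("family/link pair (", family, ", ", link, ") is not one of the ",
          "payment-model defaults; set allow_other = TRUE to use it")
  structure(list(family = family, link = link), class = "glm_spec")
}

#' Default family/link per condition
#'
#' @param condition `"AMI"`, `"HF"` or `"PN"`.
#' @return a [glm_spec()].
#' @export
default_glm_spec <- function(condition) {
  switch(condition,
         AMI = glm_spec("inverse_gaussian", "log"),
         HF = glm_spec("gamma", "log"),
         PN = glm_spec("gamma", "identity"),
         stop2("no default family/link for condition '", condition, "'"))
}

family_object <- function(spec) {
  if (spec$family == "gamma") stats::Gamma(link = spec$link)
  else stats::inverse.gaussian(link = spec$link)
}

#' @exportS3Method base::print
print.glm_spec <- function(x, ...) {
  cat("<glm_spec> ", x$family, " family, ", x$link, " link\n", sep = "")
  invisible(x)
}

#' Log-likelihood of a payment GLM at given means and dispersion
#'
#' Sum of log-densities under the (mean, dispersion) parameterization that
#' matches the GLM variance functions: Gamma with shape \eqn{1/\phi} and
#' scale \eqn{\phi\mu} (variance \eqn{\phi\mu^2}); inverse Gaussian with
#' variance \eqn{\phi\mu^3}.
#'
#' @param spec a [glm_spec()].
#' @param y positive observations.
#' @param mu positive fitted means (recycled if scalar).
#' @param phi positive dispersion.
#' @return scalar log-likelihood.
#' @export
glm_loglik <- function(spec, y, mu, phi) {
  stopifnot(all(y > 0), all(mu > 0), phi > 0)
  if (length(mu) == 1) mu <- rep(mu, length(y))
  if (spec$family == "gamma") {
    sum((1 / phi) * log(y / (phi * mu)) - y / (phi * mu) - log(y) -
          lgamma(1 / phi))
  } else {
    sum(-0.5 * log(2 * pi * phi * y^3) - (y - mu)^2 / (2 * phi * mu^2 * y))
  }
}

# IRLS with step-halving that keeps eta/mu in the family's valid region;
# fallback for identity-link fits where stats::glm.fit steps outside mu > 0.
irls_fit <- function(x, y, fam, maxit = 100L, tol = 1e-9, start = NULL) {
  p <- ncol(x)
  beta <- start %||% {
    ls <- stats::lm.fit(x, fam$linkfun(pmax(y, 1e-8)))
    ls$coefficients
  }
  beta[is.na(beta)] <- 0
  eta <- drop(x %*% beta)
  if (fam$link == "identity" && any(eta <= 0)) {
    beta <- c(mean(y), rep(0, p - 1))
    eta <- drop(x %*% beta)
  }
  mu <- fam$linkinv(eta)
  dev <- sum(fam$dev.resids(y, mu, rep(1, length(y))))
  step_norm <- Inf
  for (it in seq_len(maxit)) {
    mu_eta <- fam$mu.eta(eta)
    w <- mu_eta^2 / fam$variance(mu)
    z <- eta + (y - mu) / mu_eta
    fit <- stats::lm.wfit(x, z, w)
    if (any(is.na(fit$coefficients)))
      stop2("design matrix is rank deficient")
    beta_new <- fit$coefficients
    # step-halve until eta (hence mu) is valid and deviance non-increasing
    lam <- 1
    repeat {
      bb <- beta + lam * (beta_new - beta)
      eta_try <- drop(x %*% bb)
      mu_try <- fam$linkinv(eta_try)
      ok <- all(is.finite(mu_try)) && all(mu_try > 0)
      if (ok) {
        dev_try <- sum(fam$dev.resids(y, mu_try, rep(1, length(y))))
        if (is.finite(dev_try) && dev_try <= dev * (1 + 1e-8)) break
      }
      lam <- lam / 2
      if (lam < 1e-10)
        stop2("IRLS step-halving failed to find a valid step ",
              "(mean constrained positive); iteration ", it)
    }
    step_norm <- sqrt(sum((bb - beta)^2)) / max(1, sqrt(sum(beta^2)))
    delta_dev <- abs(dev - dev_try) / (abs(dev) + 0.1)
    beta <- bb; eta <- eta_try; mu <- mu_try; dev <- dev_try
    if (step_norm < tol || delta_dev < tol)
      return(list(coefficients = beta, fitted.values = mu,
                  linear.predictors = eta,
                  weights = fam$mu.eta(eta)^2 / fam$variance(mu),
                  iter = it, converged = TRUE, step_norm = step_norm))
  }
  list(coefficients = beta, fitted.values = mu, linear.predictors = eta,
       weights = fam$mu.eta(eta)^2 / fam$variance(mu),
       iter = maxit, converged = FALSE, step_norm = step_norm)
}

#' Fit a payment GLM
#'
#' Fits the specified family/link GLM by iteratively reweighted least
#' squares. Identity-link fits guard the positivity of the mean: the primary
#' solver is `stats::glm.fit`, and if it fails or leaves the valid region an
#' internal IRLS with step-halving (initialized at the least-squares solution
#' clipped to positive means) takes over. The dispersion is estimated by
#' Pearson \eqn{\chi^2/(n-p)}; the null (intercept-only) log-likelihood is
#' evaluated at the full model's dispersion so that the McFadden ratio
#' reflects mean-structure improvement only.
#'
#' @param X a [build_design()] result, or a numeric matrix of covariates
#'   (no intercept column; one is added).
#' @param y positive payments, aligned with the rows of `X`.
#' @param spec a [glm_spec()].
#' @param offset optional offset on the link scale.
#' @return object of class `payment_glm`: coefficients, `dispersion`,
#'   `loglik`, `null_loglik`, `vcov`, `fitted`, and a `convergence` record
#'   (iterations, converged flag, final relative step norm).
#' @export
fit_payment_glm <- function(X, y, spec, offset = NULL) {
  xm <- if (inherits(X, "design_matrix")) as.matrix(X$x) else as.matrix(X)
  if (length(y) != nrow(xm)) stop2("length(y) must match nrow(X)")
  if (any(y <= 0)) stop2("payments must be positive")
  full <- cbind(`(Intercept)` = 1, xm)
  fam <- family_object(spec)
  n <- length(y); p <- ncol(full)
  if (qr(full)$rank < p)
    stop2("design matrix is rank deficient (duplicate or collinear columns)")

  fit <- NULL
  used_fallback <- FALSE
  mustart <- if (spec$link == "identity") {
    ls <- stats::lm.fit(full, y)
    pmax(ls$fitted.values, 0.05 * mean(y))
  } else NULL
  fit <- tryCatch({
    f <- suppressWarnings(stats::glm.fit(
      full, y, family = fam, mustart = mustart, offset = offset,
      control = stats::glm.control(maxit = 100)))
    if (!f$converged || any(!is.finite(f$fitted.values)) ||
        any(f$fitted.values <= 0) || any(is.na(f$coefficients))) NULL else f
  }, error = function(e) NULL)
  if (is.null(fit)) {
    used_fallback <- TRUE
    if (!is.null(offset)) stop2("GLM with offset failed to converge")
    fit <- irls_fit(full, y, fam)
    if (!fit$converged)
      stop2("GLM failed to converge after ", fit$iter,
            " iterations (final step norm ", signif(fit$step_norm, 3), ")")
  }
  beta <- fit$coefficients
  mu <- fit$fitted.values
  w <- fit$weights
  phi <- sum((y - mu)^2 / fam$variance(mu)) / (n - p)
  xw <- full * sqrt(w)
  vcov <- tryCatch(phi * chol2inv(chol(crossprod(xw))),
                   error = function(e) phi * solve(crossprod(xw)))
  dimnames(vcov) <- list(names(beta), names(beta))
  ll <- glm_loglik(spec, y, mu, phi)
  mu0 <- mean(y)  # intercept-only MLE for all three family/link pairs
  ll0 <- glm_loglik(spec, y, mu0, phi)
  structure(list(
    spec = spec, coefficients = beta, dispersion = phi,
    loglik = ll, null_loglik = ll0, vcov = vcov, fitted = mu,
    offset = offset, n = n, p = p,
    convergence = list(iterations = fit$iter,
                       converged = isTRUE(fit$converged) || !used_fallback,
                       step_norm = fit$step_norm %||% NA_real_,
                       solver = if (used_fallback) "irls_stephalve" else "glm.fit")),
    class = "payment_glm")
}

#' @exportS3Method base::print
print.payment_glm <- function(x, ...) {
  cat("<payment_glm> ", x$spec$family, "/", x$spec$link, ", ",
      x$p - 1, " covariates, n = ", x$n, "\n", sep = "")
  cat("  dispersion ", signif(x$dispersion, 4),
      ", pseudo R2 ", round(pseudo_r2(x), 4), "\n", sep = "")
  invisible(x)
}

#' Predict mean payments from a fitted payment GLM
#'
#' @param object a `payment_glm`.
#' @param newdata a `design_matrix` or covariate matrix with the columns the
#'   model was fitted on.
#' @param ... unused.
#' @return vector of predicted mean payments.
#' @export
predict.payment_glm <- function(object, newdata, ...) {
  xm <- if (inherits(newdata, "design_matrix")) as.matrix(newdata$x)
        else as.matrix(newdata)
  cols <- names(object$coefficients)[-1]
  missing_cols <- setdiff(cols, colnames(xm))
  if (length(missing_cols))
    stop2("newdata lacks column(s): ", paste(missing_cols, collapse = ", "))
  eta <- drop(cbind(1, xm[, cols, drop = FALSE]) %*% object$coefficients)
  family_object(object$spec)$linkinv(eta)
}

# Two-sided Wald p-values from the refit GLM's coefficient covariance.
coef_pvalues <- function(fit) {
  se <- sqrt(diag(fit$vcov))
  z <- fit$coefficients / se
  stats::setNames(2 * stats::pnorm(-abs(z)), names(fit$coefficients))
}

#' McFadden pseudo R-squared
#'
#' \eqn{1 - \ell_{model}/\ell_{null}}, both log-likelihoods evaluated at the
#' full model's dispersion (so the ratio reflects mean-structure improvement
#' only); clipped to `[0, 1]` for reporting. Zero for the null model,
#' increasing as the model improves.
#'
#' @param fit a `payment_glm`.
#' @return scalar in `[0, 1]`.
#' @export
pseudo_r2 <- function(fit) {
  if (fit$null_loglik == 0) stop2("null log-likelihood is zero; undefined")
  min(max(1 - fit$loglik / fit$null_loglik, 0), 1)
}

#' Root mean square prediction error
#'
#' @param pred predicted payments.
#' @param actual observed payments (same length).
#' @return \eqn{\sqrt{\mathrm{mean}((pred-actual)^2)}}.
#' @export
rmse <- function(pred, actual) {
  if (!length(pred)) stop2("empty input")
  if (length(pred) != length(actual)) stop2("length mismatch")
  sqrt(mean((pred - actual)^2))
}
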