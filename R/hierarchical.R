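#' Hierarchical payment GLM with hospital random intercepts
#'
#' Fits \eqn{g(\mu_{ij}) = x_{ij}'\beta + \alpha_i}, \eqn{\alpha_i \sim
#' N(0, \tau^2)} on the link scale, by alternating penalized IRLS: given the
#' random intercepts, \eqn{\beta} is updated by a GLM step with the
#' intercepts as offset; given \eqn{\beta}, each hospital's intercept is the
#' ridge-shrunk weighted mean of its working residuals,
#' \eqn{\hat\alpha_i = m_i / (S_i + 1/\tau^2)}; and \eqn{\tau^2} is updated
#' by a method-of-moments step on the raw (unshrunk) per-hospital intercept
#' estimates — their precision-weighted dispersion minus its sampling
#' expectation, truncated at zero (the DerSimonian-Laird estimator applied
#' to the working model). This is the standard estimator class for
#' payment-measure profiling; a full integrated likelihood is intentionally
#' out of scope.
#'
#' @param X a [build_design()] result or covariate matrix.
#' @param y positive payments.
#' @param hospital_ids hospital of each row.
#' @param spec a [glm_spec()].
#' @param control list: `max_iter` (default 50), `tol` (1e-6, coefficient
#'   and intercept steps), `tol_tau` (1e-4; the moment update for tau
#'   contracts only quadratically near the tau = 0 boundary, so the
#'   between-hospital SD gets its own, looser stopping rule).
#' @param init optional warm start `list(beta, tau2, phi)` (used by the
#'   bootstrap to skip the flat initial fit).
#' @return object of class `hier_glm`: `beta`, `alpha` (named, link scale),
#'   `tau`, `dispersion`, `spec`, convergence record.
#' @export
fit_hierarchical <- function(X, y, hospital_ids, spec,
                             control = list(), init = NULL) {
  xm <- if (inherits(X, "design_matrix")) as.matrix(X$x) else as.matrix(X)
  if (any(y <= 0)) stop2("payments must be positive")
  hosp <- as.character(hospital_ids)
  levels_h <- unique(hosp)
  if (length(levels_h) < 2) stop2("need at least 2 hospitals")
  max_iter <- control$max_iter %||% 50L
  tol <- control$tol %||% 1e-6
  tol_tau <- control$tol_tau %||% 1e-4
  fam <- family_object(spec)
  full <- cbind(`(Intercept)` = 1, xm)
  n <- length(y); p <- ncol(full)
  hi <- match(hosp, levels_h)

  if (is.null(init)) {
    flat <- fit_payment_glm(xm, y, spec)
    beta <- flat$coefficients
    phi <- flat$dispersion
    tau2 <- 0
  } else {
    beta <- init$beta; phi <- init$phi; tau2 <- init$tau2
  }
  alpha <- stats::setNames(rep(0, length(levels_h)), levels_h)

  eta_fix <- drop(full %*% beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- eta_fix + alpha[hi]
    mu <- fam$linkinv(eta)
    if (any(!is.finite(mu)) || any(mu <= 0))
      stop2("hierarchical fit left the valid mean region (iteration ", it, ")")
    me <- fam$mu.eta(eta)
    w <- me^2 / fam$variance(mu)          # unit-dispersion IRLS weights
    r <- alpha[hi] + (y - mu) / me        # working residual net of x'beta
    S <- as.numeric(rowsum(w, hi)) / phi  # per-hospital information
    m <- as.numeric(rowsum(w * r, hi)) / phi
    # moment step on the raw intercepts: precision-weighted dispersion of
    # a_raw minus its sampling expectation, truncated at zero
    a_raw <- m / S
    abar <- sum(S * a_raw) / sum(S)
    Q <- sum(S * (a_raw - abar)^2)
    k <- length(S)
    tau2_new <- max((Q - (k - 1)) / (sum(S) - sum(S^2) / sum(S)), 0)
    if (tau2_new < 1e-12) {
      alpha_new <- stats::setNames(rep(0, length(levels_h)), levels_h)
      v <- rep(0, k)  # conditional on tau = 0 the intercepts are degenerate
      tau2_new <- 0
    } else {
      alpha_new <- stats::setNames(m / (S + 1 / tau2_new), levels_h)
      v <- 1 / (S + 1 / tau2_new)
    }

    refit <- tryCatch(suppressWarnings(stats::glm.fit(
      full, y, family = fam, offset = alpha_new[hi],
      etastart = eta_fix,
      control = stats::glm.control(maxit = 50))),
      error = function(e) NULL)
    if (is.null(refit) || any(is.na(refit$coefficients)) ||
        any(refit$fitted.values <= 0))
      stop2("beta update failed to converge in hierarchical fit")
    beta_new <- refit$coefficients
    eta_fix_new <- drop(full %*% beta_new)
    mu_new <- fam$linkinv(eta_fix_new + alpha_new[hi])
    phi_new <- sum((y - mu_new)^2 / fam$variance(mu_new)) / (n - p)

    delta <- max(max(abs(beta_new - beta)) / (1 + max(abs(beta))),
                 max(abs(alpha_new - alpha)) / (1 + max(abs(alpha))))
    delta_tau <- abs(sqrt(tau2_new) - sqrt(tau2)) / (1 + sqrt(tau2))
    beta <- beta_new; alpha <- alpha_new; tau2 <- tau2_new
    phi <- phi_new; eta_fix <- eta_fix_new
    if (delta < tol && delta_tau < tol_tau) { converged <- TRUE; break }
  }
  structure(list(beta = beta, alpha = alpha, alpha_var = stats::setNames(v, levels_h),
                 tau = sqrt(tau2), dispersion = phi, spec = spec,
                 hospitals = levels_h, iterations = it, converged = converged),
            class = "hier_glm")
}

#' @exportS3Method base::print
print.hier_glm <- function(x, ...) {
  cat("<hier_glm> ", x$spec$family, "/", x$spec$link, ", ",
      length(x$hospitals), " hospitals\n", sep = "")
  cat("  tau = ", signif(x$tau, 4), ", dispersion = ",
      signif(x$dispersion, 4), ", ", x$iterations, " iterations",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Risk-standardized payments per hospital
#'
#' For each hospital, the predicted total \eqn{P_i = \sum_j
#' g^{-1}(x_j'\beta + \alpha_i)} uses the hospital's own random intercept;
#' the expected total \eqn{E_i = \sum_j g^{-1}(x_j'\beta)} sets the random
#' effect to its prior mean (an average hospital with the same case mix);
#' and \eqn{RSP_i = (P_i/E_i) \times} the national mean payment.
#'
#' @param fit a [fit_hierarchical()] result.
#' @param X design used for the fit (or compatible).
#' @param hospital_ids hospital of each row.
#' @param national_mean observed mean (winsorized) payment over the cohort.
#' @return object of class `hospital_profiles`: data.frame with
#'   `hospital_id`, `n_cases`, `predicted_total`, `expected_total`, `rsp`.
#' @export
rsp <- function(fit, X, hospital_ids, national_mean) {
  xm <- if (inherits(X, "design_matrix")) as.matrix(X$x) else as.matrix(X)
  stopifnot(national_mean > 0)
  fam <- family_object(fit$spec)
  hosp <- as.character(hospital_ids)
  eta_fix <- drop(cbind(1, xm[, names(fit$beta)[-1], drop = FALSE]) %*% fit$beta)
  mu_p <- fam$linkinv(eta_fix + fit$alpha[hosp])
  mu_e <- fam$linkinv(eta_fix)
  hi <- match(hosp, fit$hospitals)
  P <- as.numeric(rowsum(mu_p, hi))
  E <- as.numeric(rowsum(mu_e, hi))
  ncase <- as.numeric(rowsum(rep(1, length(hosp)), hi))
  if (any(E <= 0) || any(P <= 0))
    stop2("non-positive predicted/expected totals (identity-link pathology)")
  out <- data.frame(hospital_id = fit$hospitals[sort(unique(hi))],
                    stringsAsFactors = FALSE)
  out$n_cases <- ncase
  out$predicted_total <- P
  out$expected_total <- E
  out$rsp <- P / E * national_mean
  structure(out, national_mean = national_mean,
            class = c("hospital_profiles", "data.frame"))
}

#' Cluster-bootstrap confidence intervals for hospital RSPs
#'
#' Resamples hospitals (clusters) with replacement and refits the
#' hierarchical GLM on each replicate. Within a replicate, each sampled
#' hospital's intercept is drawn from its estimated conditional (posterior)
#' distribution \eqn{N(\hat\alpha_i, v_i)} — the standard practice in
#' hospital-profiling bootstraps, without which a hospital's own fixed data
#' would make its replicate RSPs degenerate — and its RSP is computed
#' against the original cohort's national mean. A hospital's 95% CI is the
#' 2.5/97.5 percentile of the RSP values collected over all replicates in
#' which it was sampled (each occurrence in a replicate contributes one
#' value). Hospitals never sampled get `NA` limits and are flagged.
#'
#' @param X design matrix (or [build_design()] result).
#' @param y positive payments.
#' @param hospital_ids hospital of each row.
#' @param spec a [glm_spec()].
#' @param national_mean fixed national mean payment (from the original
#'   cohort).
#' @param n_boot number of replicates (the measure methodology uses 2000;
#'   tests in this package run reduced scales).
#' @param seed seed for the resampling stream.
#' @param control passed to [fit_hierarchical()] for the replicate refits.
#' @param warm_start optional `hier_glm` fit used to warm-start replicates.
#' @return data.frame `hospital_id`, `ci_lower`, `ci_upper`, `n_sampled`.
#' @export
bootstrap_rsp <- function(X, y, hospital_ids, spec, national_mean,
                          n_boot = 2000, seed = 1,
                          control = list(max_iter = 30), warm_start = NULL) {
  if (n_boot < 2) stop2("n_boot must be at least 2")
  xm <- if (inherits(X, "design_matrix")) as.matrix(X$x) else as.matrix(X)
  hosp <- as.character(hospital_ids)
  levels_h <- unique(hosp)
  rows_h <- split(seq_along(hosp), factor(hosp, levels = levels_h))
  init <- if (!is.null(warm_start))
    list(beta = warm_start$beta, tau2 = warm_start$tau^2,
         phi = warm_start$dispersion) else NULL
  acc <- stats::setNames(vector("list", length(levels_h)), levels_h)
  with_substream(seed, "bootstrap", {
    for (b in seq_len(n_boot)) {
      samp <- sample(levels_h, replace = TRUE)
      rows <- unlist(rows_h[samp], use.names = FALSE)
      pseudo <- rep(seq_along(samp), lengths(rows_h[samp]))
      bf <- fit_hierarchical(xm[rows, , drop = FALSE], y[rows],
                             pseudo, spec, control = control, init = init)
      bf$alpha <- stats::rnorm(length(bf$alpha), bf$alpha,
                               sqrt(bf$alpha_var))
      names(bf$alpha) <- bf$hospitals
      prof <- rsp(bf, xm[rows, , drop = FALSE], pseudo, national_mean)
      orig <- samp[as.integer(prof$hospital_id)]
      for (u in unique(orig)) {
        vals <- prof$rsp[orig == u]
        acc[[u]] <- c(acc[[u]], vals)
      }
    }
  })
  ci <- t(vapply(levels_h, function(h) {
    v <- acc[[h]]
    if (is.null(v)) c(NA_real_, NA_real_, 0)
    else c(stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 1),
           length(v))
  }, numeric(3)))
  data.frame(hospital_id = levels_h, ci_lower = ci[, 1], ci_upper = ci[, 2],
             n_sampled = as.integer(ci[, 3]), stringsAsFactors = FALSE)
}

#' Categorize hospitals against the national mean payment
#'
#' Hospitals with at least `min_cases` cases and a defined CI are assigned
#' one of three performance categories: `higher` if the RSP's lower 95%
#' limit exceeds the national mean, `lower` if the upper limit is below it,
#' `no_different` otherwise. Smaller or CI-less hospitals are left
#' uncategorized (`NA`).
#'
#' @param profiles a [rsp()] result merged with CI columns (`ci_lower`,
#'   `ci_upper`), or the result of merging with [bootstrap_rsp()] output.
#' @param national_mean national mean payment.
#' @param min_cases eligibility threshold (default 25).
#' @return `profiles` with `eligible` and `category` columns.
#' @export
categorize_hospitals <- function(profiles, national_mean, min_cases = 25) {
  stopifnot(all(c("ci_lower", "ci_upper") %in% names(profiles)))
  eligible <- profiles$n_cases >= min_cases & !is.na(profiles$ci_lower)
  category <- rep(NA_character_, nrow(profiles))
  category[eligible & profiles$ci_lower > national_mean] <- "higher"
  category[eligible & profiles$ci_upper < national_mean] <- "lower"
  category[eligible & is.na(category)] <- "no_different"
  profiles$eligible <- eligible
  profiles$category <- category
  profiles
}

cat_levels <- c("lower", "no_different", "higher")

#' Category shift table between two models
#'
#' Cross-classifies hospitals by their performance category under model A vs
#' model B and reports the percentage reclassified (off-diagonal share).
#'
#' @param categories_a,categories_b named character vectors (names =
#'   hospital ids) or aligned unnamed vectors of categories (`lower`,
#'   `no_different`, `higher`); `NA` (uncategorized) hospitals are excluded
#'   and must be uncategorized under both models.
#' @return object of class `shift_table`: list with the 3x3 `table`,
#'   `pct_reclassified`, and `n` (eligible hospitals).
#' @export
shift_table <- function(categories_a, categories_b) {
  if (length(categories_a) != length(categories_b))
    stop2("mismatched hospital sets")
  if (!is.null(names(categories_a)) && !is.null(names(categories_b))) {
    if (!setequal(names(categories_a), names(categories_b)))
      stop2("mismatched hospital sets")
    categories_b <- categories_b[names(categories_a)]
  }
  ok <- !is.na(categories_a) & !is.na(categories_b)
  bad_a <- setdiff(unique(categories_a[ok]), cat_levels)
  if (length(bad_a) || length(setdiff(unique(categories_b[ok]), cat_levels)))
    stop2("unknown category label")
  tab <- table(factor(categories_a[ok], levels = cat_levels),
               factor(categories_b[ok], levels = cat_levels),
               dnn = c("model_a", "model_b"))
  n <- sum(tab)
  off <- n - sum(diag(tab))
  structure(list(table = tab, pct_reclassified = 100 * off / n, n = n),
            class = "shift_table")
}

#' @exportS3Method base::print
print.shift_table <- function(x, ...) {
  cat("<shift_table> ", x$n, " hospitals, ",
      round(x$pct_reclassified, 1), "% reclassified\n", sep = "")
  print(x$table)
  invisible(x)
}
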