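#' Penalized variable selection with a count cap and significance constraint
#'
#' Selects individual-code risk variables the way the payment models do:
#' an L1 (LASSO) path is computed for the matched family/link over a
#' log-spaced penalty grid; the smallest penalty whose active set (excluding
#' forced, unpenalized columns) holds `max_vars` or fewer variables is
#' taken; the selected set is refitted as an unpenalized GLM; and backward
#' elimination then repeatedly drops the least significant non-forced column
#' with two-sided Wald p at or above `alpha` and refits, so that every
#' variable in the final model satisfies p < `alpha`.
#'
#' Columns are standardized internally for penalization; coefficients are
#' reported on the original scale. The age-band columns are typically forced
#' (unpenalized and exempt from pruning).
#'
#' @param X a [build_design()] result or covariate matrix.
#' @param y positive payments.
#' @param spec a [glm_spec()].
#' @param max_vars cap on the number of selected non-forced variables
#'   (default 200).
#' @param alpha significance level each surviving variable must beat
#'   (default 0.005).
#' @param forced character vector of column names always kept (default: the
#'   age-band columns present in `X`).
#' @param nlambda number of penalty-grid points (default 100).
#' @param gaussian_approx use a Gaussian working-response LASSO instead of
#'   the matched family (faster; the matched family is the default).
#' @return object of class `selection_result`: `selected` (non-forced
#'   survivors), `forced`, `path` (lambda grid with nonzero counts),
#'   `pruning_log`, and `fit`, the final unpenalized `payment_glm`.
#' @export
lasso_select <- function(X, y, spec, max_vars = 200, alpha = 0.005,
                         forced = NULL, nlambda = 100,
                         gaussian_approx = FALSE) {
  xm <- if (inherits(X, "design_matrix")) X$x else X
  if (is.null(forced) && inherits(X, "design_matrix"))
    forced <- intersect(c("age_75_84", "age_85p"), colnames(xm))
  forced <- intersect(forced %||% character(), colnames(xm))
  cand <- setdiff(colnames(xm), forced)

  path <- data.frame(lambda = numeric(), nonzero = integer())
  if (max_vars > 0 && length(cand) > 1) {
    pf <- as.numeric(colnames(xm) %in% cand)
    fam <- if (gaussian_approx) stats::gaussian() else family_object(spec)
    gfit <- glmnet::glmnet(
      xm, y, family = fam, nlambda = nlambda, penalty.factor = pf,
      dfmax = max_vars + length(forced) + 10L, standardize = TRUE)
    bmat <- gfit$beta != 0
    nonzero <- Matrix::colSums(bmat[cand, , drop = FALSE])
    path <- data.frame(lambda = gfit$lambda, nonzero = as.integer(nonzero))
    ok <- which(nonzero <= max_vars)
    if (length(ok)) {
      pick <- ok[which.max(nonzero[ok])]        # most variables under the cap
      pick <- max(ok[nonzero[ok] == nonzero[pick]])  # tie: smallest penalty
      selected <- cand[bmat[cand, pick]]
    } else selected <- character()  # unreachable: large penalty empties the set
  } else if (max_vars > 0 && length(cand) == 1) {
    selected <- cand  # single candidate: let the significance rule decide
  } else selected <- character()

  # Backward elimination: drop the least significant non-forced column with
  # p >= alpha and refit, until every survivor beats alpha. Refits are
  # warm-started at the previous coefficients so each costs a couple of IRLS
  # iterations.
  initial_selected <- selected
  pruning_log <- data.frame(column = character(), p_value = numeric(),
                            stage = integer())
  fam <- family_object(spec)
  start <- NULL
  while (length(selected)) {
    xs <- cbind(`(Intercept)` = 1,
                as.matrix(xm[, c(forced, selected), drop = FALSE]))
    gf <- tryCatch(suppressWarnings(stats::glm.fit(
      xs, y, family = fam, start = start,
      control = stats::glm.control(maxit = 100))), error = function(e) NULL)
    if (is.null(gf) || any(is.na(gf$coefficients)) ||
        any(gf$fitted.values <= 0)) {
      f2 <- fit_payment_glm(xm[, c(forced, selected), drop = FALSE], y, spec)
      pv_all <- coef_pvalues(f2)
      gf <- NULL
    } else {
      p <- ncol(xs)
      phi <- sum((y - gf$fitted.values)^2 /
                   fam$variance(gf$fitted.values)) / (length(y) - p)
      piv <- gf$qr$pivot
      cov <- matrix(NA_real_, p, p)
      cov[piv, piv] <- chol2inv(gf$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
      se <- sqrt(diag(cov) * phi)
      z <- gf$coefficients / se
      pv_all <- stats::setNames(2 * stats::pnorm(-abs(z)), colnames(xs))
    }
    pv <- pv_all[selected]
    worst <- which.max(pv)
    if (pv[worst] < alpha) break
    pruning_log <- rbind(pruning_log, data.frame(
      column = selected[worst], p_value = unname(pv[worst]),
      stage = nrow(pruning_log) + 1L))
    keep <- setdiff(names(if (is.null(gf)) pv_all else
      stats::setNames(gf$coefficients, colnames(xs))), selected[worst])
    start <- if (!is.null(gf))
      gf$coefficients[colnames(xs) %in% keep] else NULL
    selected <- selected[-worst]
  }
  fit <- fit_payment_glm(xm[, c(forced, selected), drop = FALSE], y, spec)
  structure(list(selected = selected, initial_selected = initial_selected,
                 forced = forced, path = path,
                 pruning_log = pruning_log, fit = fit,
                 max_vars = max_vars, alpha = alpha),
            class = "selection_result")
}

#' @exportS3Method base::print
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", length(x$selected), " variables selected (cap ",
      x$max_vars, "), ", nrow(x$pruning_log), " pruned at p >= ", x$alpha,
      "; ", length(x$forced), " forced\n", sep = "")
  invisible(x)
}

# Disjoint fold assignment by admission, covering the cohort exactly once.
make_folds <- function(n, k, seed) {
  if (n < k) stop2("cohort smaller than the number of folds")
  with_substream(seed, "cv_folds", sample(rep(seq_len(k), length.out = n)))
}

#' Cross-validated model comparison metrics for one scheme
#'
#' Computes the Table-2-style metrics for a (condition cohort, covariate
#' scheme, family/link) triple: the McFadden pseudo R-squared of a
#' full-cohort selection-and-fit, and the out-of-sample RMSE from k-fold
#' cross-validation in which candidate construction (frequency filter),
#' variable selection and GLM training are all repeated on each set of
#' training folds and error is measured on the held-out fold.
#'
#' @param cohort a [build_cohort()] result.
#' @param bundle the source `claims_bundle`.
#' @param scheme an [rv_scheme()] or scheme name.
#' @param spec a [glm_spec()]; default is the cohort condition's.
#' @param maps a [code_maps()].
#' @param k number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @param select run LASSO + significance selection (default: only for the
#'   individual-code schemes, matching the payment-model methodology).
#' @param max_vars,alpha selection constraints, see [lasso_select()].
#' @return object of class `cv_result`: `pseudo_r2_full`, `rmse_folds`,
#'   `rmse_mean`, `rmse_sd`, `full_fit`, and the full-cohort
#'   `selection` when selection ran.
#' @export
cross_validate <- function(cohort, bundle, scheme, spec = NULL,
                           maps = toy_code_maps(), k = 5, seed = 1,
                           select = NULL, max_vars = 200, alpha = 0.005) {
  if (is.character(scheme)) scheme <- rv_scheme(scheme)
  spec <- spec %||% default_glm_spec(cohort$condition[1])
  select <- select %||% (scheme$name %in% c("codes_index", "codes_index_history"))
  n <- nrow(cohort)
  fold <- make_folds(n, k, seed)

  fit_one <- function(rows) {
    coh <- cohort[rows, , drop = FALSE]
    des <- build_design(coh, bundle, scheme, maps)
    if (select) {
      sel <- lasso_select(des, coh$payment_w, spec,
                          max_vars = max_vars, alpha = alpha)
      list(fit = sel$fit, info = des$info, selection = sel)
    } else {
      list(fit = fit_payment_glm(des, coh$payment_w, spec), info = des$info,
           selection = NULL)
    }
  }

  full <- fit_one(seq_len(n))
  rmse_folds <- vapply(seq_len(k), function(f) {
    test <- which(fold == f)
    if (!length(test)) stop2("fold ", f, " has no test rows")
    train <- fit_one(which(fold != f))
    test_coh <- cohort[test, , drop = FALSE]
    test_des <- build_design(test_coh, bundle, scheme, maps,
                             columns = train$info)
    pred <- predict(train$fit, test_des)
    rmse(pred, test_coh$payment_w)
  }, numeric(1))

  structure(list(
    scheme = scheme$name, spec = spec,
    pseudo_r2_full = pseudo_r2(full$fit),
    rmse_folds = rmse_folds, rmse_mean = mean(rmse_folds),
    rmse_sd = stats::sd(rmse_folds), k = k, fold = fold,
    full_fit = full$fit, selection = full$selection),
    class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat("<cv_result> scheme=", x$scheme, " (", x$spec$family, "/", x$spec$link,
      ")\n  pseudo R2 (full cohort): ", round(x$pseudo_r2_full, 4),
      "\n  RMSE (", x$k, "-fold CV): ", round(x$rmse_mean, 1), " (SD ",
      round(x$rmse_sd, 1), ")\n", sep = "")
  invisible(x)
}
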