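#' Default synthetic diagnosis-code catalog
#'
#' A deterministic catalog of candidate diagnosis codes with per-channel
#' prevalences and per-code present-on-admission (POA) flag probabilities.
#' Prevalences are log-spaced so that the catalog straddles the 0.5%
#' candidate-frequency filter: some codes are common comorbidities, some are
#' rare enough to be filtered out of individual-code models.
#'
#' @param n_codes number of codes (ids `C01`, `C02`, ...).
#' @param p_range range of per-channel prevalences (log-spaced across codes).
#' @param poa_probs length-3 numeric, probabilities of POA flag
#'   `Y` / `N` / `missing` applied to every code (override columns to vary
#'   per code).
#' @return data.frame with columns `code`, `p_index`, `p_history`,
#'   `poa_y`, `poa_n`, `poa_missing`.
#' @export
default_code_catalog <- function(n_codes = 60, p_range = c(0.002, 0.12),
                                 poa_probs = c(0.75, 0.15, 0.10)) {
  stopifnot(n_codes >= 2, length(p_range) == 2, all(p_range > 0))
  assert_prob(poa_probs, "poa_probs")
  if (abs(sum(poa_probs) - 1) > 1e-8) stop2("poa_probs must sum to 1")
  i <- seq_len(n_codes)
  # descending log-spaced index prevalence; history prevalence offset by one
  # third of the grid so the two channels differ code-by-code
  lp <- seq(log(p_range[2]), log(p_range[1]), length.out = n_codes)
  p_index <- exp(lp)
  p_history <- exp(lp[((i + floor(n_codes / 3) - 1) %% n_codes) + 1])
  data.frame(
    code = sprintf("C%02d", i),
    p_index = p_index,
    p_history = p_history,
    poa_y = poa_probs[1],
    poa_n = poa_probs[2],
    poa_missing = poa_probs[3],
    stringsAsFactors = FALSE
  )
}

default_true_beta <- function(catalog) {
  codes <- catalog$code
  k <- min(8L, length(codes))
  eff <- codes[seq_len(k)]
  # log-link effects (multiplicative); identity-link effects in dollars
  mk_log <- function(b0, idx, hist) {
    b <- c(b0, 0.08, 0.15,
           idx * seq(1, 0.4, length.out = k),
           hist * seq(1, 0.4, length.out = k))
    names(b) <- c("(Intercept)", "age_75_84", "age_85p",
                  paste0("index:", eff), paste0("history:", eff))
    b
  }
  b_pn <- c(14500, 900, 1600,
            4500 * seq(1, 0.4, length.out = k),
            1800 * seq(1, 0.4, length.out = k))
  names(b_pn) <- names(mk_log(0, 1, 1))
  list(
    AMI = mk_log(log(20500), 0.30, 0.12),
    HF  = mk_log(log(14500), 0.28, 0.12),
    PN  = b_pn
  )
}

#' Simulation configuration for the synthetic claims generator
#'
#' Collects every knob of the generative model: cohort sizes, the hospital
#' volume distribution (which by default places about 20% of hospitals under
#' the 25-case profiling threshold), the condition mix, the diagnosis-code
#' catalog with POA flag probabilities, the true payment model per condition
#' (family/link, coefficients on the link scale, dispersion, hospital
#' random-intercept SD), and the enrollment/exclusion fractions.
#'
#' Payments are drawn from the configured family with mean
#' \eqn{g^{-1}(x'\beta + \alpha_h)}; the Gamma family is parameterized by
#' (mean, dispersion) with variance \eqn{\phi\mu^2} and the inverse Gaussian
#' with variance \eqn{\phi\mu^3}, matching the GLM variance functions used by
#' the estimators.
#'
#' @param n_patients number of patients (one index admission each).
#' @param n_hospitals number of hospitals.
#' @param hospital_volume list(frac_small, mean_small): fraction of hospitals
#'   given a small expected volume (default mean 12 cases, under the 25-case
#'   threshold); the remainder share the remaining admissions evenly.
#' @param condition_mix named proportions over AMI/HF/PN, summing to 1.
#' @param code_catalog data.frame as from [default_code_catalog()].
#' @param poa_exempt_codes character vector of codes on the POA-exempt list.
#' @param true_beta named list per condition of named coefficient vectors on
#'   the link scale; names are `(Intercept)`, `age_75_84`, `age_85p`, and
#'   `index:<code>` / `history:<code>`.
#' @param family_link named list per condition, each a [glm_spec()].
#' @param dispersion named positive dispersions per condition.
#' @param re_sd named hospital random-intercept SDs (link scale) per
#'   condition; a scalar is recycled.
#' @param frac_short_enrollment fraction of patients given fewer than 12
#'   months of continuous prior fee-for-service enrollment (exact count).
#' @param frac_under65 fraction of admissions with age below 65, so the
#'   inclusion filter is exercised.
#' @param death_prob probability of the 30-day death flag (independent of
#'   payment; decedent payments are not prorated).
#' @param seed master seed; every table draws from its own substream.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 10000,
                       n_hospitals = 100,
                       hospital_volume = list(frac_small = 0.2, mean_small = 12),
                       condition_mix = c(AMI = 0.18, HF = 0.35, PN = 0.47),
                       code_catalog = default_code_catalog(),
                       poa_exempt_codes = default_code_catalog()$code[seq(7, 60, by = 7)],
                       true_beta = default_true_beta(code_catalog),
                       family_link = list(AMI = glm_spec("inverse_gaussian", "log"),
                                          HF = glm_spec("gamma", "log"),
                                          PN = glm_spec("gamma", "identity")),
                       dispersion = c(AMI = 2.7e-5, HF = 0.55, PN = 0.45),
                       re_sd = c(AMI = 0.08, HF = 0.08, PN = 1300),
                       frac_short_enrollment = 0.10,
                       frac_under65 = 0.02,
                       death_prob = 0.08,
                       seed = 1L) {
  conds <- names(condition_mix)
  if (is.null(conds) || any(conds == ""))
    stop2("condition_mix must be a named vector")
  assert_prob(condition_mix, "condition_mix")
  if (abs(sum(condition_mix) - 1) > 1e-8) stop2("condition_mix must sum to 1")
  assert_prob(c(frac_short_enrollment, frac_under65, death_prob,
                hospital_volume$frac_small), "fractions")
  if (frac_short_enrollment >= 1) stop2("frac_short_enrollment must be < 1")
  stopifnot(n_patients >= 1, n_hospitals >= 1)
  req <- c("code", "p_index", "p_history", "poa_y", "poa_n", "poa_missing")
  if (!all(req %in% names(code_catalog)))
    stop2("code_catalog lacks columns: ",
          paste(setdiff(req, names(code_catalog)), collapse = ", "))
  assert_prob(unlist(code_catalog[c("p_index", "p_history")]), "catalog prevalences")
  if (any(abs(rowSums(code_catalog[c("poa_y", "poa_n", "poa_missing")]) - 1) > 1e-8))
    stop2("per-code POA probabilities must sum to 1")
  if (length(re_sd) == 1L) re_sd <- stats::setNames(rep(re_sd, length(conds)), conds)
  for (cn in conds) {
    if (is.null(true_beta[[cn]]) || is.null(family_link[[cn]]) ||
        is.na(dispersion[cn]) || is.na(re_sd[cn]))
      stop2("missing true_beta/family_link/dispersion/re_sd for condition ", cn)
    if (dispersion[cn] <= 0) stop2("dispersion must be > 0")
    if (re_sd[cn] < 0) stop2("re_sd must be >= 0")
    if (!inherits(family_link[[cn]], "glm_spec"))
      stop2("family_link entries must be glm_spec objects")
  }
  cfg <- structure(list(
    n_patients = as.integer(n_patients), n_hospitals = as.integer(n_hospitals),
    hospital_volume = hospital_volume, condition_mix = condition_mix,
    code_catalog = code_catalog, poa_exempt_codes = poa_exempt_codes,
    true_beta = true_beta, family_link = family_link,
    dispersion = dispersion, re_sd = re_sd[conds],
    frac_short_enrollment = frac_short_enrollment,
    frac_under65 = frac_under65, death_prob = death_prob,
    seed = as.integer(seed)), class = "sim_config")
  check_identity_positivity(cfg)
  cfg
}

# Identity-link configurations whose linear predictor could plausibly go
# non-positive are rejected up front: worst case is every negative effect on,
# no positive effect, and a 6-sigma random intercept.
check_identity_positivity <- function(cfg) {
  for (cn in names(cfg$condition_mix)) {
    sp <- cfg$family_link[[cn]]
    if (sp$link != "identity") next
    b <- cfg$true_beta[[cn]]
    eta_min <- b["(Intercept)"] + sum(pmin(b[names(b) != "(Intercept)"], 0)) -
      6 * cfg$re_sd[cn]
    if (!is.finite(eta_min) || eta_min <= 0)
      stop2("identity-link configuration for ", cn,
            " admits a non-positive linear predictor (worst case ",
            signif(eta_min, 4), "); increase the intercept or shrink ",
            "negative effects / re_sd")
  }
  invisible(cfg)
}

# Inverse-Gaussian sampler, (mean mu, shape lambda) parameterization with
# Var = mu^3 / lambda (Michael-Schucany-Haas transform).
rinvgauss <- function(n, mu, lambda) {
  stopifnot(all(mu > 0), all(lambda > 0))
  v <- stats::rnorm(n)^2
  x <- mu + (mu^2 * v) / (2 * lambda) -
    (mu / (2 * lambda)) * sqrt(4 * mu * lambda * v + mu^2 * v^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' Generate a synthetic claims bundle
#'
#' Draws linked index-admission, diagnosis and enrollment tables from the
#' generative model in a [sim_config()], and records the ground truth
#' (coefficients, hospital effects, dispersions) for parameter-recovery
#' tests. Each table consumes its own random substream derived from the
#' master seed, so regenerating one table's draws never perturbs another's.
#'
#' @param config a [sim_config()].
#' @return object of class `claims_bundle`: list with data.frames
#'   `index_admissions` (admission_id, patient_id, hospital_id, condition,
#'   age_years, payment_30d, died_30d), `diagnoses` (admission_id, code,
#'   role, poa, window), `enrollment` (patient_id, prior_ff_months), and
#'   `truth` (see [sim_config()]).
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_patients
  conds <- names(cfg$condition_mix)

  admission_id <- sprintf("A%07d", seq_len(n))
  patient_id <- sprintf("P%07d", seq_len(n))
  hospital_id <- sprintf("H%04d", seq_len(cfg$n_hospitals))

  adm <- with_substream(cfg$seed, "admissions", {
    condition <- sample(conds, n, replace = TRUE, prob = cfg$condition_mix)
    n_small <- round(cfg$hospital_volume$frac_small * cfg$n_hospitals)
    w <- rep(n / cfg$n_hospitals, cfg$n_hospitals)  # expected volumes
    if (n_small > 0 && n_small < cfg$n_hospitals) {
      w[seq_len(n_small)] <- cfg$hospital_volume$mean_small
      w[-seq_len(n_small)] <-
        max((n - n_small * cfg$hospital_volume$mean_small) /
              (cfg$n_hospitals - n_small), 1)
    }
    hosp <- sample(hospital_id, n, replace = TRUE, prob = w)
    age <- 65L + stats::rgeom(n, prob = 0.105)
    age <- pmin(age, 105L)
    under <- stats::runif(n) < cfg$frac_under65
    age[under] <- sample(60:64, sum(under), replace = TRUE)
    data.frame(admission_id = admission_id, patient_id = patient_id,
               hospital_id = hosp, condition = condition,
               age_years = as.integer(age), stringsAsFactors = FALSE)
  })

  dx <- with_substream(cfg$seed, "diagnoses", {
    cat <- cfg$code_catalog
    m <- nrow(cat)
    idx_mat <- matrix(stats::runif(n * m), n, m) <
      matrix(cat$p_index, n, m, byrow = TRUE)
    his_mat <- matrix(stats::runif(n * m), n, m) <
      matrix(cat$p_history, n, m, byrow = TRUE)
    ii <- which(idx_mat, arr.ind = TRUE)
    hh <- which(his_mat, arr.ind = TRUE)
    u <- stats::runif(nrow(ii))
    cum <- cbind(cat$poa_y, cat$poa_y + cat$poa_n)[ii[, 2], , drop = FALSE]
    poa <- ifelse(u < cum[, 1], "Y", ifelse(u < cum[, 2], "N", "missing"))
    principal <- data.frame(
      admission_id = admission_id, code = paste0(adm$condition, "_P"),
      role = "principal", poa = "Y", window = "index",
      stringsAsFactors = FALSE)
    secondary <- data.frame(
      admission_id = admission_id[ii[, 1]], code = cat$code[ii[, 2]],
      role = rep("secondary", nrow(ii)), poa = poa,
      window = rep("index", nrow(ii)), stringsAsFactors = FALSE)
    history <- data.frame(
      admission_id = admission_id[hh[, 1]], code = cat$code[hh[, 2]],
      role = rep("secondary", nrow(hh)), poa = rep(NA_character_, nrow(hh)),
      window = rep("history", nrow(hh)), stringsAsFactors = FALSE)
    out <- rbind(principal, secondary, history)
    out[order(out$admission_id, out$window, out$code), , drop = FALSE]
  })
  rownames(dx) <- NULL

  enr <- with_substream(cfg$seed, "enrollment", {
    n_short <- floor(cfg$frac_short_enrollment * n)
    short <- sample(n, n_short)
    months <- integer(n)
    long_idx <- setdiff(seq_len(n), short)
    months[long_idx] <- sample(12:60, length(long_idx), replace = TRUE)
    if (n_short > 0) months[short] <- sample(0:11, n_short, replace = TRUE)
    data.frame(patient_id = patient_id, prior_ff_months = months,
               stringsAsFactors = FALSE)
  })

  alpha <- with_substream(cfg$seed, "hospital_effects", {
    lapply(stats::setNames(conds, conds), function(cn)
      stats::setNames(stats::rnorm(cfg$n_hospitals, 0, cfg$re_sd[cn]),
                      hospital_id))
  })

  payment <- with_substream(cfg$seed, "payments", {
    pay <- numeric(n)
    for (cn in conds) {
      rows <- which(adm$condition == cn)
      if (!length(rows)) next
      eta <- truth_linear_predictor(adm[rows, , drop = FALSE], dx,
                                    cfg$true_beta[[cn]]) +
        alpha[[cn]][adm$hospital_id[rows]]
      sp <- cfg$family_link[[cn]]
      mu <- if (sp$link == "log") exp(eta) else eta
      if (any(mu <= 0))
        stop2("non-positive mean payment generated for ", cn,
              " (identity-link overflow); reject this configuration")
      phi <- cfg$dispersion[cn]
      pay[rows] <- if (sp$family == "gamma")
        stats::rgamma(length(rows), shape = 1 / phi, scale = phi * mu)
      else rinvgauss(length(rows), mu, lambda = 1 / phi)
    }
    pay
  })
  adm$payment_30d <- payment
  adm$died_30d <- with_substream(cfg$seed, "deaths",
    as.integer(stats::runif(n) < cfg$death_prob))
  adm <- adm[c("admission_id", "patient_id", "hospital_id", "condition",
               "age_years", "payment_30d", "died_30d")]

  truth <- structure(list(true_beta = cfg$true_beta, hospital_effects = alpha,
                          dispersion = cfg$dispersion, re_sd = cfg$re_sd),
                     class = "sim_truth")
  bundle <- structure(list(index_admissions = adm, diagnoses = dx,
                           enrollment = enr, truth = truth),
                      class = "claims_bundle")
  validate_bundle(bundle)
  bundle
}

# Linear predictor of the generative truth model for a block of admissions:
# intercept + age-band effects + per-(channel, code) indicator effects.
truth_linear_predictor <- function(adm, dx, beta) {
  eta <- rep(beta[["(Intercept)"]], nrow(adm))
  ab <- age_band(adm$age_years)
  if (!is.na(beta["age_75_84"])) eta <- eta + beta[["age_75_84"]] * (ab == "75-84")
  if (!is.na(beta["age_85p"])) eta <- eta + beta[["age_85p"]] * (ab == ">=85")
  code_terms <- setdiff(names(beta), c("(Intercept)", "age_75_84", "age_85p"))
  if (!length(code_terms)) return(eta)
  dx_sub <- dx[dx$admission_id %in% adm$admission_id, , drop = FALSE]
  key <- paste0(dx_sub$window, ":", dx_sub$code)
  for (term in code_terms) {
    hit <- unique(dx_sub$admission_id[key == term])
    eta <- eta + beta[[term]] * (adm$admission_id %in% hit)
  }
  eta
}

#' Validate a claims bundle's structural invariants
#'
#' Checks that tables carry the required columns, that every diagnosis row
#' references an existing admission, that payments are positive, and that POA
#' flags are populated exactly on index-window rows.
#'
#' @param bundle a `claims_bundle`.
#' @return the bundle, invisibly; stops with a named violation otherwise.
#' @export
validate_bundle <- function(bundle) {
  if (!is.list(bundle)) stop2("bundle must be a list")
  need <- list(
    index_admissions = c("admission_id", "patient_id", "hospital_id",
                         "condition", "age_years", "payment_30d", "died_30d"),
    diagnoses = c("admission_id", "code", "role", "poa", "window"),
    enrollment = c("patient_id", "prior_ff_months"))
  for (tb in names(need)) {
    if (is.null(bundle[[tb]])) stop2("bundle lacks table ", tb)
    missing_cols <- setdiff(need[[tb]], names(bundle[[tb]]))
    if (length(missing_cols))
      stop2("table ", tb, " lacks column(s): ",
            paste(missing_cols, collapse = ", "))
  }
  adm <- bundle$index_admissions
  dx <- bundle$diagnoses
  if (any(!(dx$admission_id %in% adm$admission_id)))
    stop2("diagnoses reference unknown admission_id (orphan rows)")
  if (any(!is.finite(adm$payment_30d)) || any(adm$payment_30d <= 0))
    stop2("payment_30d must be positive")
  if (nrow(dx)) {
    idx <- dx$window == "index"
    if (any(is.na(dx$poa[idx])))
      stop2("index-window diagnoses must carry a poa flag")
    if (any(!is.na(dx$poa[!idx])))
      stop2("history-window diagnoses must not carry a poa flag")
    bad <- setdiff(unique(dx$poa[idx]), c("Y", "N", "missing"))
    if (length(bad)) stop2("unknown poa token(s): ", paste(bad, collapse = ", "))
    if (any(!dx$window %in% c("index", "history")))
      stop2("window must be 'index' or 'history'")
    if (any(!dx$role %in% c("principal", "secondary")))
      stop2("role must be 'principal' or 'secondary'")
  }
  if (any(!(adm$patient_id %in% bundle$enrollment$patient_id)))
    stop2("admissions reference patients missing from enrollment")
  invisible(structure(bundle, class = "claims_bundle"))
}

#' Write / read a claims bundle as delimited text
#'
#' `write_bundle()` writes `index_admissions.csv`, `diagnoses.csv` and
#' `enrollment.csv` (UTF-8, header row) under `path`, plus a `truth.json`
#' sidecar when generator ground truth is present. `read_bundle()` reads them
#' back, validating the schema; `read_bundle(write_bundle(b))` reproduces the
#' bundle field-for-field.
#'
#' @param bundle a `claims_bundle`.
#' @param path directory to write to / read from (created if needed).
#' @return `write_bundle()`: `path`, invisibly. `read_bundle()`: a
#'   `claims_bundle`.
#' @export
write_bundle <- function(bundle, path) {
  validate_bundle(bundle)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$index_admissions,
                   file.path(path, "index_admissions.csv"), row.names = FALSE)
  utils::write.csv(bundle$diagnoses, file.path(path, "diagnoses.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$enrollment, file.path(path, "enrollment.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$truth)) {
    tr <- bundle$truth
    jsonlite::write_json(
      list(true_beta = lapply(tr$true_beta, as.list),
           hospital_effects = lapply(tr$hospital_effects, as.list),
           dispersion = as.list(tr$dispersion),
           re_sd = as.list(tr$re_sd)),
      file.path(path, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  fp <- function(f) file.path(path, f)
  for (f in c("index_admissions.csv", "diagnoses.csv", "enrollment.csv"))
    if (!file.exists(fp(f))) stop2("missing file: ", f)
  adm <- utils::read.csv(fp("index_admissions.csv"), stringsAsFactors = FALSE,
                         colClasses = c(payment_30d = "numeric"))
  dx <- utils::read.csv(fp("diagnoses.csv"), stringsAsFactors = FALSE)
  enr <- utils::read.csv(fp("enrollment.csv"), stringsAsFactors = FALSE)
  if (nrow(dx) && "poa" %in% names(dx)) dx$poa <- as.character(dx$poa)
  truth <- NULL
  if (file.exists(fp("truth.json"))) {
    j <- jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE)
    truth <- structure(list(
      true_beta = lapply(j$true_beta, unlist),
      hospital_effects = lapply(j$hospital_effects, unlist),
      dispersion = unlist(j$dispersion), re_sd = unlist(j$re_sd)),
      class = "sim_truth")
  }
  validate_bundle(structure(list(index_admissions = adm, diagnoses = dx,
                                 enrollment = enr, truth = truth),
                            class = "claims_bundle"))
}

#' @exportS3Method base::print
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  cat("  index admissions:", nrow(x$index_admissions), "\n")
  cat("  diagnoses:       ", nrow(x$diagnoses), "\n")
  cat("  patients:        ", nrow(x$enrollment), "\n")
  cat("  conditions:      ",
      paste(sort(unique(x$index_admissions$condition)), collapse = ", "), "\n")
  cat("  ground truth:    ", if (is.null(x$truth)) "absent" else "recorded", "\n")
  invisible(x)
}
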