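#' Winsorize payments at an upper quantile
#'
#' Caps values above the empirical `upper_q` quantile at that quantile
#' (one-sided: payments are bounded below by zero, and the cap exists to
#' limit the influence of high-cost outliers on model fitting). The quantile
#' uses linear interpolation between order statistics
#' (`stats::quantile(type = 7)`); the rule is fixed because the cap is
#' sensitive to it.
#'
#' @param payments positive numeric vector.
#' @param upper_q quantile in (0, 1]; the default 0.995 caps the top 0.5%.
#' @return vector of the same length with values above the cap replaced by
#'   the cap. Idempotent; `upper_q = 1` is the identity.
#' @export
winsorize <- function(payments, upper_q = 0.995) {
  if (!length(payments)) stop2("payments must be nonempty")
  if (any(!is.finite(payments)) || any(payments <= 0))
    stop2("payments must be positive and finite")
  if (!is.numeric(upper_q) || length(upper_q) != 1 ||
      upper_q <= 0 || upper_q > 1)
    stop2("upper_q must lie in (0, 1]")
  if (upper_q == 1) return(payments)
  cap <- stats::quantile(payments, upper_q, names = FALSE, type = 7)
  pmin(payments, cap)
}

# Age bands used as categorical risk variables; reference band is <=74.
age_band <- function(age) {
  cut(age, breaks = c(-Inf, 74, 84, Inf), labels = c("<=74", "75-84", ">=85"))
}

#' Build a condition cohort with inclusion rules and winsorized outcome
#'
#' Applies the study inclusion criteria to a claims bundle for one condition:
#' age at the index admission must be at least 65, the patient must have a
#' full 12 months of prior continuous fee-for-service enrollment, and
#' patients who died within the 30-day window are retained (payments are not
#' prorated). The 30-day standardized payment is winsorized at `winsor_q`
#' within the condition cohort, after the inclusion filters.
#'
#' @param bundle a validated `claims_bundle`.
#' @param condition cohort condition label (e.g. `"AMI"`).
#' @param winsor_q upper winsorization quantile (default 0.995).
#' @return object of class `cohort_table`: data.frame with columns
#'   `admission_id`, `patient_id`, `hospital_id`, `condition`, `age_band`
#'   (levels `<=74`, `75-84`, `>=85`), `payment_w`, `died_30d`, with the
#'   winsorization cap in attribute `"winsor_cap"`.
#' @export
build_cohort <- function(bundle, condition, winsor_q = 0.995) {
  validate_bundle(bundle)
  adm <- bundle$index_admissions
  months <- stats::setNames(bundle$enrollment$prior_ff_months,
                            bundle$enrollment$patient_id)
  keep <- adm$condition == condition &
    adm$age_years >= 65 &
    months[adm$patient_id] >= 12
  out <- adm[keep, , drop = FALSE]
  if (!nrow(out)) {
    warning("empty cohort for condition '", condition, "'", call. = FALSE)
    res <- data.frame(admission_id = character(), patient_id = character(),
                      hospital_id = character(), condition = character(),
                      age_band = age_band(integer()), payment_w = numeric(),
                      died_30d = integer(), stringsAsFactors = FALSE)
    return(structure(res, winsor_cap = NA_real_, winsor_q = winsor_q,
                     class = c("cohort_table", "data.frame")))
  }
  pw <- winsorize(out$payment_30d, winsor_q)
  res <- data.frame(
    admission_id = out$admission_id, patient_id = out$patient_id,
    hospital_id = out$hospital_id, condition = out$condition,
    age_band = age_band(out$age_years), payment_w = pw,
    died_30d = out$died_30d, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res,
            winsor_cap = if (winsor_q < 1)
              stats::quantile(out$payment_30d, winsor_q, names = FALSE, type = 7)
            else max(out$payment_30d),
            winsor_q = winsor_q,
            class = c("cohort_table", "data.frame"))
}

#' @exportS3Method base::print
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x), " admissions",
      if (nrow(x)) paste0(" (", x$condition[1], ")"), "\n", sep = "")
  if (nrow(x)) {
    cat("  winsorization cap: ", format(round(attr(x, "winsor_cap"), 2)),
        " (q = ", attr(x, "winsor_q"), ")\n", sep = "")
    print(utils::head(as.data.frame(x), 5))
  }
  invisible(x)
}
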