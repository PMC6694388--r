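# Rank-based near-equal binning: stable sort by (value, input order); the
# first (n %% bins) bins receive the extra admission when n is not a
# multiple of bins.
rank_bins <- function(x, bins) {
  n <- length(x)
  if (bins > n) stop2("more bins than observations")
  sizes <- rep(n %/% bins, bins) + (seq_len(bins) <= n %% bins)
  ord <- order(x)  # stable: ties keep input order
  bin <- integer(n)
  bin[ord] <- rep(seq_len(bins), sizes)
  bin
}

#' Decile predictive ratios
#'
#' Calibration diagnostic: admissions are ranked by predicted payment and
#' split into `bins` near-equal groups (ties broken by stable input order);
#' within each bin the ratio of mean predicted to mean actual payment is
#' reported. Ratios near 1 across bins indicate a well-calibrated model.
#'
#' @param pred predicted payments.
#' @param actual observed payments (same length, at least `bins`).
#' @param bins number of groups (default 10, i.e. deciles).
#' @return data.frame `bin`, `n`, `mean_pred`, `mean_actual`, `ratio`
#'   (class `predictive_ratio_table`), bin 1 = lowest predicted payment.
#' @export
predictive_ratios <- function(pred, actual, bins = 10) {
  if (length(pred) != length(actual)) stop2("length mismatch")
  bin <- rank_bins(pred, bins)
  mp <- as.numeric(tapply(pred, bin, mean))
  ma <- as.numeric(tapply(actual, bin, mean))
  structure(data.frame(bin = seq_len(bins), n = as.integer(table(bin)),
                       mean_pred = mp, mean_actual = ma, ratio = mp / ma),
            class = c("predictive_ratio_table", "data.frame"))
}

#' Quintile reclassification table between two models' predictions
#'
#' Cross-classifies admissions by their quintile of predicted payment under
#' model A vs model B; the off-diagonal share summarizes how much the two
#' models disagree about where patients sit in the payment distribution.
#'
#' @param pred_a,pred_b predicted payments for the same admissions.
#' @return object of class `quintile_shift_table`: list with the 5x5
#'   `table` and `pct_off_diagonal`.
#' @export
quintile_shift <- function(pred_a, pred_b) {
  if (length(pred_a) != length(pred_b)) stop2("length mismatch")
  qa <- rank_bins(pred_a, 5)
  qb <- rank_bins(pred_b, 5)
  tab <- table(model_a = qa, model_b = qb)
  structure(list(table = tab,
                 pct_off_diagonal = 100 * (sum(tab) - sum(diag(tab))) / sum(tab)),
            class = "quintile_shift_table")
}

#' @exportS3Method base::print
print.quintile_shift_table <- function(x, ...) {
  cat("<quintile_shift_table> ", round(x$pct_off_diagonal, 1),
      "% of admissions change quintile\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Median and range of predicted payments
#'
#' @param pred nonempty numeric vector.
#' @return named vector `median`, `min`, `max` (exact order statistics).
#' @export
payment_distribution_summary <- function(pred) {
  if (!length(pred)) stop2("empty input")
  c(median = stats::median(pred), min = min(pred), max = max(pred))
}
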