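#' Present-on-admission eligibility rule for index diagnoses
#'
#' Restricts index-admission diagnosis rows to those usable as comorbidity
#' risk variables under the POA rule: principal diagnoses are always
#' eligible; secondary diagnoses are kept iff their POA flag is `Y`, or the
#' flag is `missing` and the code is on the POA-exempt list (exempt codes are
#' not required to carry a flag, so a missing flag is uninformative there).
#' Secondary diagnoses flagged `N` arose during the stay and are dropped.
#'
#' @param dx_rows data.frame of index-window diagnosis rows (columns
#'   `admission_id`, `code`, `role`, `poa`, `window`).
#' @param maps a [code_maps()] object (supplies the exempt list).
#' @return the eligible subset of `dx_rows`. Idempotent.
#' @export
poa_eligible <- function(dx_rows, maps) {
  if (nrow(dx_rows) && any(dx_rows$window != "index"))
    stop2("poa_eligible expects index-window rows only")
  bad <- setdiff(unique(dx_rows$poa), c("Y", "N", "missing"))
  if (length(bad) || any(is.na(dx_rows$poa)))
    stop2("unknown poa token(s): ",
          paste(c(bad, if (any(is.na(dx_rows$poa))) "NA"), collapse = ", "))
  keep <- dx_rows$role == "principal" |
    dx_rows$poa == "Y" |
    (dx_rows$poa == "missing" & dx_rows$code %in% maps$poa_exempt)
  dx_rows[keep, , drop = FALSE]
}

# Apply the CC hierarchy to a (admission_id, cc) membership table: within
# each group, an admission's presence of a higher-ranked CC (presence judged
# before any suppression) removes the listed lower-ranked CCs.
apply_hierarchy <- function(memb, maps) {
  if (!nrow(memb)) return(memb)
  drop <- rep(FALSE, nrow(memb))
  for (g in unique(maps$hierarchy$group)) {
    ccs <- maps$hierarchy$cc[maps$hierarchy$group == g]
    for (j in seq_len(length(ccs) - 1L)) {
      adm_hi <- memb$admission_id[memb$cc == ccs[j]]
      if (!length(adm_hi)) next
      drop <- drop | (memb$cc %in% ccs[(j + 1L):length(ccs)] &
                        memb$admission_id %in% adm_hi)
    }
  }
  memb[!drop, , drop = FALSE]
}

# Map a (admission_id, code) table to a deduplicated (admission_id, cc)
# table with the hierarchy applied per admission; unmapped codes are ignored
# and counted in attr "n_unmapped".
admission_ccs <- function(code_rows, maps) {
  cc <- maps$code_to_cc$cc[match(code_rows$code, maps$code_to_cc$code)]
  n_unmapped <- sum(is.na(cc) & !duplicated(code_rows$code))
  memb <- unique(data.frame(admission_id = code_rows$admission_id[!is.na(cc)],
                            cc = cc[!is.na(cc)], stringsAsFactors = FALSE))
  structure(apply_hierarchy(memb, maps), n_unmapped = n_unmapped)
}

#' Map a set of diagnosis codes to condition categories
#'
#' Maps codes through the crosswalk and applies the CC hierarchy: within each
#' hierarchy group, a present higher-ranked category suppresses the listed
#' lower-ranked ones. Unmapped codes are ignored (counted in attribute
#' `"n_unmapped"`), not an error.
#'
#' @param codes character vector of diagnosis codes (one patient/admission).
#' @param maps a [code_maps()] object.
#' @return sorted character vector of surviving CCs.
#' @export
map_to_ccs <- function(codes, maps) {
  memb <- admission_ccs(data.frame(admission_id = rep("x", length(codes)),
                                   code = codes, stringsAsFactors = FALSE),
                        maps)
  structure(sort(unique(memb$cc)), n_unmapped = attr(memb, "n_unmapped"))
}

#' Complication-exclusion algorithm of the base (pre-POA) model
#'
#' Before POA flags were reliable, the grouped-category payment models
#' excluded index-only diagnoses that could be complications of care: an
#' index secondary diagnosis whose CC is on the excludable list is dropped
#' unless the same CC also arises from the patient's 12-month history.
#' Principal diagnoses and diagnoses in non-excludable CCs are kept.
#'
#' @param index_dx index-window diagnosis rows.
#' @param history_dx history-window diagnosis rows (or a data.frame with
#'   `admission_id`, `code`).
#' @param maps a [code_maps()] object.
#' @return the retained subset of `index_dx`.
#' @export
base_model_exclusion <- function(index_dx, history_dx, maps) {
  if (!nrow(index_dx)) return(index_dx)
  cc <- maps$code_to_cc$cc[match(index_dx$code, maps$code_to_cc$code)]
  his_cc <- unique(data.frame(
    admission_id = history_dx$admission_id,
    cc = maps$code_to_cc$cc[match(history_dx$code, maps$code_to_cc$code)],
    stringsAsFactors = FALSE))
  his_cc <- his_cc[!is.na(his_cc$cc), , drop = FALSE]
  in_history <- paste(index_dx$admission_id, cc) %in%
    paste(his_cc$admission_id, his_cc$cc)
  drop <- index_dx$role == "secondary" & !is.na(cc) &
    cc %in% maps$excludable_ccs & !in_history
  index_dx[!drop, , drop = FALSE]
}

#' Candidate-code frequency filter
#'
#' A diagnosis code is a candidate risk variable iff the number of cohort
#' admissions carrying it (counted once per admission) exceeds
#' `threshold` of the cohort size — a strict inequality, so a code at exactly
#' the threshold frequency is excluded.
#'
#' @param dx data.frame with `admission_id`, `code` (one channel).
#' @param n_cohort cohort size (number of admissions).
#' @param threshold frequency threshold in `[0, 1)`; default 0.005 (0.5%).
#' @return character vector of candidate codes.
#' @export
frequency_filter <- function(dx, n_cohort, threshold = 0.005) {
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1)
    stop2("threshold must lie in [0, 1)")
  if (n_cohort < 1) stop2("cohort is empty")
  u <- unique(dx[c("admission_id", "code")])
  counts <- table(u$code)
  names(counts)[counts / n_cohort > threshold]
}

scheme_names <- c("cms_base", "cms_poa", "hcc_index", "hcc_pooled",
                  "hcc_separate", "codes_index", "codes_index_history")

#' Covariate scheme descriptor
#'
#' Names one of the seven candidate-variable constructions compared by the
#' package, from the CMS-style grouped-category models to the individual-code
#' models:
#' \describe{
#'   \item{cms_base}{pooled CC indicators, complication-exclusion algorithm
#'     in place of POA logic (the pre-POA grouped model).}
#'   \item{cms_poa}{same grouping, POA rule replaces the exclusion algorithm.}
#'   \item{hcc_index}{CC indicators from index diagnoses only.}
#'   \item{hcc_pooled}{one indicator per CC, set if the CC arises from the
#'     index admission, the 12-month history, or both.}
#'   \item{hcc_separate}{distinct indicator per (CC, channel).}
#'   \item{codes_index}{one indicator per frequency-passing individual code
#'     from the index admission.}
#'   \item{codes_index_history}{individual-code indicators per channel.}
#' }
#'
#' @param name one of the scheme names above.
#' @param threshold candidate-code frequency threshold for the
#'   individual-code schemes.
#' @return object of class `rv_scheme`.
#' @export
rv_scheme <- function(name, threshold = 0.005) {
  if (!is.character(name) || length(name) != 1 || !(name %in% scheme_names))
    stop2("unknown scheme '", paste(name, collapse = ","), "'; must be one of: ",
          paste(scheme_names, collapse = ", "))
  structure(list(name = name, threshold = threshold), class = "rv_scheme")
}

#' Build the design matrix for one cohort under a covariate scheme
#'
#' Produces the binary risk-variable matrix plus the two age-band indicators
#' (reference band is 74 and younger) for every admission in the cohort.
#' Index-window diagnoses pass through the scheme's eligibility logic first:
#' the complication-exclusion algorithm for `cms_base`, the POA rule for all
#' other schemes. Comorbidity columns that are constant across the cohort
#' (all zero or all one, e.g. the principal-diagnosis CC) are dropped and
#' recorded in attribute `"dropped_constant"`.
#'
#' @param cohort a [build_cohort()] result.
#' @param bundle the `claims_bundle` the cohort came from.
#' @param scheme an [rv_scheme()] or scheme name.
#' @param maps a [code_maps()] object (required by all schemes for POA /
#'   exclusion logic; CC schemes also use the crosswalk).
#' @param columns optional column-info data.frame from a previously built
#'   design (its `info`); when given, exactly those columns are built — used
#'   to score held-out admissions with a training design's variables.
#' @return object of class `design_matrix`: list with `x` (sparse 0/1 matrix,
#'   rows keyed by admission_id), `info` (column, key, channel, unit), and
#'   `scheme`.
#' @export
build_design <- function(cohort, bundle, scheme, maps = toy_code_maps(),
                         columns = NULL) {
  if (is.character(scheme)) scheme <- rv_scheme(scheme)
  stopifnot(inherits(scheme, "rv_scheme"))
  ids <- cohort$admission_id
  n <- length(ids)
  dx <- bundle$diagnoses[bundle$diagnoses$admission_id %in% ids, , drop = FALSE]
  index <- dx[dx$window == "index", , drop = FALSE]
  history <- unique(dx[dx$window == "history", c("admission_id", "code")])

  eligible <- if (scheme$name == "cms_base")
    base_model_exclusion(index, history, maps)
  else poa_eligible(index, maps)
  idx_codes <- unique(eligible[c("admission_id", "code")])

  n_unmapped <- 0L
  hits <- NULL  # data.frame(admission_id, key, channel)
  ch <- function(df, channel) {
    if (!nrow(df)) return(NULL)
    names(df)[2] <- "key"
    df$channel <- channel
    df
  }
  if (scheme$name %in% c("cms_base", "cms_poa")) {
    pooled <- unique(rbind(idx_codes, history))
    memb <- admission_ccs(pooled, maps)
    n_unmapped <- attr(memb, "n_unmapped")
    if (!is.null(maps$cms_ccs))
      memb <- memb[memb$cc %in% maps$cms_ccs, , drop = FALSE]
    hits <- ch(memb, "pooled")
    unit <- "cc"
  } else if (scheme$name %in% c("hcc_index", "hcc_pooled", "hcc_separate")) {
    mi <- admission_ccs(idx_codes, maps)
    mh <- admission_ccs(history, maps)
    n_unmapped <- attr(mi, "n_unmapped") + attr(mh, "n_unmapped")
    hits <- switch(scheme$name,
      hcc_index = ch(mi, "index"),
      hcc_pooled = ch(unique(rbind(mi, mh)), "pooled"),
      hcc_separate = rbind(ch(mi, "index"), ch(mh, "history")))
    unit <- "cc"
  } else {  # individual-code schemes bypass CC mapping entirely
    if (scheme$name == "codes_index") {
      if (is.null(columns)) {
        cand <- frequency_filter(idx_codes, n, scheme$threshold)
        idx_codes <- idx_codes[idx_codes$code %in% cand, , drop = FALSE]
      }
      hits <- ch(idx_codes, "index")
    } else {
      if (is.null(columns)) {
        ci <- frequency_filter(idx_codes, n, scheme$threshold)
        chh <- frequency_filter(history, n, scheme$threshold)
        idx_codes <- idx_codes[idx_codes$code %in% ci, , drop = FALSE]
        history <- history[history$code %in% chh, , drop = FALSE]
      }
      hits <- rbind(ch(idx_codes, "index"), ch(history, "history"))
    }
    unit <- "code"
  }
  if (is.null(hits))
    hits <- data.frame(admission_id = character(), key = character(),
                       channel = character(), stringsAsFactors = FALSE)

  single_channel <- scheme$name %in%
    c("cms_base", "cms_poa", "hcc_index", "hcc_pooled", "codes_index")
  if (is.null(columns)) {
    defs <- unique(hits[c("key", "channel")])
    defs <- defs[order(defs$key, defs$channel), , drop = FALSE]
    defs$column <- if (single_channel) defs$key
      else paste(defs$key, defs$channel, sep = ".")
    defs$unit <- unit
  } else {
    defs <- columns[columns$unit != "age", c("column", "key", "channel", "unit"),
                    drop = FALSE]
  }

  age1 <- as.integer(cohort$age_band == "75-84")
  age2 <- as.integer(cohort$age_band == ">=85")
  if (nrow(defs)) {
    j <- match(paste(hits$key, hits$channel),
               paste(defs$key, defs$channel))
    ok <- !is.na(j)
    xm <- Matrix::sparseMatrix(
      i = match(hits$admission_id[ok], ids), j = j[ok], x = 1,
      dims = c(n, nrow(defs)), dimnames = list(ids, defs$column))
    xm@x[] <- 1  # duplicated (admission, column) hits collapse to 1
  } else {
    xm <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                               dims = c(n, 0), dimnames = list(ids, NULL))
  }
  dropped <- character()
  if (is.null(columns) && ncol(xm)) {
    cs <- Matrix::colSums(xm)
    const <- cs == 0 | cs == n
    dropped <- colnames(xm)[const]
    xm <- xm[, !const, drop = FALSE]
    defs <- defs[!const, , drop = FALSE]
  }
  x <- cbind(Matrix::Matrix(cbind(age_75_84 = age1, age_85p = age2),
                            sparse = TRUE), xm)
  rownames(x) <- ids
  info <- rbind(
    data.frame(column = c("age_75_84", "age_85p"), key = NA_character_,
               channel = "demographic", unit = "age",
               stringsAsFactors = FALSE),
    defs[c("column", "key", "channel", "unit")])
  rownames(info) <- NULL
  structure(list(x = methods::as(x, "CsparseMatrix"), info = info,
                 scheme = scheme$name),
            dropped_constant = dropped, n_unmapped = n_unmapped,
            class = "design_matrix")
}

#' @exportS3Method base::print
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> scheme=", x$scheme, ": ", nrow(x$x), " admissions x ",
      ncol(x$x), " columns (", sum(x$info$unit != "age"),
      " risk variables + 2 age bands)\n", sep = "")
  invisible(x)
}
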