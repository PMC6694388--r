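#' Diagnosis-code maps: CC crosswalk, hierarchy, POA-exempt and exclusion lists
#'
#' Bundles the configuration tables that drive covariate construction: the
#' code-to-condition-category (CC) crosswalk, the CC hierarchy (within a
#' group, a present higher-ranked category suppresses the listed lower-ranked
#' ones), the POA-exempt code list, the set of CCs treated as potential
#' complications of care by the base model's exclusion algorithm, and
#' optionally the restricted CC list used by the CMS-style grouped schemes.
#'
#' The licensed v22 crosswalk and the real POA-exempt list are not
#' redistributed; a small synthetic stand-in ships with the package (see
#' [toy_code_maps()]) and users supply full tables in the same format.
#'
#' @param code_to_cc data.frame with columns `code`, `cc`.
#' @param hierarchy data.frame with columns `group`, `rank`, `cc`; rank 1 is
#'   the top of the group.
#' @param poa_exempt character vector of exempt codes (or data.frame with a
#'   `code` column).
#' @param excludable_ccs character vector of CCs excludable as complications
#'   (or data.frame with a `cc` column).
#' @param cms_ccs optional character vector restricting which CCs the
#'   `cms_base` / `cms_poa` schemes use; `NULL` means all mapped CCs.
#' @return object of class `code_maps`.
#' @export
code_maps <- function(code_to_cc, hierarchy, poa_exempt = character(),
                      excludable_ccs = character(), cms_ccs = NULL) {
  if (!all(c("code", "cc") %in% names(code_to_cc)))
    stop2("code_to_cc needs columns code, cc")
  if (!all(c("group", "rank", "cc") %in% names(hierarchy)))
    stop2("hierarchy needs columns group, rank, cc")
  if (is.data.frame(poa_exempt)) poa_exempt <- poa_exempt$code
  if (is.data.frame(excludable_ccs)) excludable_ccs <- excludable_ccs$cc
  known <- unique(code_to_cc$cc)
  if (length(setdiff(hierarchy$cc, known)))
    stop2("hierarchy references unknown CC(s): ",
          paste(setdiff(hierarchy$cc, known), collapse = ", "))
  if (anyDuplicated(code_to_cc$code))
    stop2("code_to_cc maps a code twice")
  hierarchy <- hierarchy[order(hierarchy$group, hierarchy$rank), , drop = FALSE]
  structure(list(code_to_cc = code_to_cc[c("code", "cc")],
                 hierarchy = hierarchy[c("group", "rank", "cc")],
                 poa_exempt = as.character(poa_exempt),
                 excludable_ccs = as.character(excludable_ccs),
                 cms_ccs = if (is.null(cms_ccs)) NULL else as.character(cms_ccs)),
            class = "code_maps")
}

#' Read code maps from a directory of CSV tables
#'
#' Expects `code_to_cc.csv` (code,cc), `hierarchy.csv` (group,rank,cc),
#' and optionally `poa_exempt.csv` (code), `excludable_ccs.csv` (cc),
#' `cms_ccs.csv` (cc).
#'
#' @param dir directory containing the tables.
#' @return a [code_maps()] object.
#' @export
read_code_maps <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  c2c <- rd("code_to_cc.csv")
  hier <- rd("hierarchy.csv")
  if (is.null(c2c) || is.null(hier))
    stop2("dir must contain code_to_cc.csv and hierarchy.csv")
  code_maps(c2c, hier,
            poa_exempt = rd("poa_exempt.csv") %||% character(),
            excludable_ccs = rd("excludable_ccs.csv") %||% character(),
            cms_ccs = (rd("cms_ccs.csv") %||% list(cc = NULL))$cc)
}

#' Packaged toy code maps
#'
#' A small synthetic crosswalk (57 codes onto 9 comorbidity CCs plus 3
#' principal-diagnosis CCs, 3 hierarchy groups) matching the codes emitted by
#' [default_code_catalog()]. Intended for tests and examples; real analyses
#' supply full tables via [read_code_maps()].
#'
#' @return a [code_maps()] object.
#' @export
toy_code_maps <- function() {
  read_code_maps(system.file("extdata", "toy_maps", package = "payrisk"))
}

#' @exportS3Method base::print
print.code_maps <- function(x, ...) {
  cat("<code_maps> ", nrow(x$code_to_cc), " codes -> ",
      length(unique(x$code_to_cc$cc)), " CCs; ",
      length(unique(x$hierarchy$group)), " hierarchy groups; ",
      length(x$poa_exempt), " POA-exempt codes; ",
      length(x$excludable_ccs), " excludable CCs\n", sep = "")
  invisible(x)
}
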