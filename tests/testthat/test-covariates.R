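maps <- tiny_maps()

test_that("POA eligibility follows the full rule truth table", {
  # enumerate role x poa x exempt; expected kept iff principal, poa Y, or
  # (poa missing and exempt)
  grid <- expand.grid(role = c("principal", "secondary"),
                      poa = c("Y", "N", "missing"),
                      exempt = c(TRUE, FALSE), stringsAsFactors = FALSE)
  grid$code <- ifelse(grid$exempt, "cE", "cA")
  dx <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    dx_row(paste0("a", i), grid$code[i], role = grid$role[i],
           poa = grid$poa[i])))
  kept <- poa_eligible(dx, maps)
  expected <- grid$role == "principal" | grid$poa == "Y" |
    (grid$poa == "missing" & grid$exempt)
  expect_setequal(kept$admission_id, paste0("a", which(expected)))
  expect_true(all(kept$poa[kept$role == "secondary"] != "N"))
})

test_that("POA eligibility is idempotent and rejects unknown tokens", {
  dx <- rbind(dx_row("a1", "cA", poa = "Y"),
              dx_row("a2", "cE", poa = "missing"),
              dx_row("a3", "cA", role = "principal", poa = "N"))
  once <- poa_eligible(dx, maps)
  expect_identical(poa_eligible(once, maps), once)
  bad <- dx_row("a1", "cA", poa = "U")
  expect_error(poa_eligible(bad, maps), "poa token")
  expect_error(poa_eligible(dx_row("a1", "cA", window = "history"), maps),
               "index-window")
})

test_that("CC mapping applies the hierarchy and counts unmapped codes", {
  expect_identical(as.character(map_to_ccs(c("cA", "cB"), maps)), "CC1")
  expect_identical(as.character(map_to_ccs("cB", maps)), "CC2")
  expect_identical(length(map_to_ccs(character(), maps)), 0L)
  # presence of CC2 suppresses CC3 even when CC1 also suppresses CC2
  expect_identical(as.character(map_to_ccs(c("cA", "cB", "cC2"), maps)), "CC1")
  got <- map_to_ccs(c("cA", "cU", "cZ"), maps)
  expect_identical(as.character(got), "CC1")
  expect_identical(attr(got, "n_unmapped"), 2L)
})

test_that("base-model exclusion drops index-only complications", {
  idx <- rbind(dx_row("a1", "cX"),            # CC4 excludable, index only
               dx_row("a2", "cX"),            # CC4 but also in history
               dx_row("a3", "cA"),            # CC1 not excludable
               dx_row("a4", "cX", role = "principal"))
  his <- dx_row("a2", "cX", window = "history")
  kept <- base_model_exclusion(idx, his, maps)
  expect_setequal(kept$admission_id, c("a2", "a3", "a4"))
})

test_that("frequency filter uses a strict per-admission threshold", {
  dx5 <- data.frame(admission_id = paste0("a", 1:5), code = "c1")
  dx6 <- data.frame(admission_id = paste0("a", 1:6), code = "c2")
  both <- rbind(dx5, dx6)
  expect_identical(frequency_filter(both, 1000, 0.005), "c2")
  # duplicate rows within one admission count once
  dup <- rbind(dx5, data.frame(admission_id = "a1", code = "c1"))
  expect_identical(length(frequency_filter(dup, 1000, 0.005)), 0L)
  expect_error(frequency_filter(both, 1000, 1), "threshold")
  expect_error(frequency_filter(both, 1000, -0.1), "threshold")
})

test_that("scheme channel semantics: index-only vs pooled vs separate", {
  adm <- rbind(adm_row("a1", age = 70), adm_row("a2", age = 80),
               adm_row("a3", age = 88), adm_row("a4", age = 70),
               adm_row("a5", age = 70))
  dx <- rbind(
    dx_row("a1", "cH", window = "history"),          # CC7 history only
    dx_row("a2", "cH", poa = "Y"),                   # CC7 index only
    dx_row("a3", "cA", poa = "Y"),                   # CC1 index
    dx_row("a3", "cB", window = "history"),          # CC2 history
    dx_row("a5", "cH", poa = "Y"),                   # same code both windows
    dx_row("a5", "cH", window = "history"))
  b <- hand_bundle(adm, dx)
  coh <- build_cohort(b, "HF", winsor_q = 1)

  d_idx <- build_design(coh, b, "hcc_index", maps)
  d_pool <- build_design(coh, b, "hcc_pooled", maps)
  d_sep <- build_design(coh, b, "hcc_separate", maps)
  g <- function(d, col) as.numeric(d$x[, col])

  expect_equal(g(d_idx, "CC7"), c(0, 1, 0, 0, 1))
  expect_equal(g(d_pool, "CC7"), c(1, 1, 0, 0, 1))
  expect_equal(g(d_sep, "CC7.history"), c(1, 0, 0, 0, 1))
  expect_equal(g(d_sep, "CC7.index"), c(0, 1, 0, 0, 1))
  # per-channel hierarchy: index CC1 does not suppress history CC2
  expect_equal(g(d_pool, "CC1"), c(0, 0, 1, 0, 0))
  expect_equal(g(d_pool, "CC2"), c(0, 0, 1, 0, 0))
  # admission with no diagnoses: all comorbidity columns 0, age columns set
  expect_true(all(d_sep$x["a4", d_sep$info$unit != "age"] == 0))
  expect_equal(g(d_sep, "age_75_84"), c(0, 1, 0, 0, 0))
  expect_equal(g(d_sep, "age_85p"), c(0, 0, 1, 0, 0))
})

test_that("individual-code schemes keep channels distinct and bypass CC mapping", {
  adm <- rbind(adm_row("a1"), adm_row("a2"), adm_row("a3"))
  dx <- rbind(dx_row("a1", "cH", poa = "Y"),
              dx_row("a1", "cH", window = "history"),
              dx_row("a2", "cA", poa = "Y"))
  b <- hand_bundle(adm, dx)
  coh <- build_cohort(b, "HF", winsor_q = 1)
  d <- build_design(coh, b, rv_scheme("codes_index_history", threshold = 0),
                    maps)
  expect_true(all(c("cH.index", "cH.history") %in% colnames(d$x)))
  expect_equal(as.numeric(d$x["a1", c("cH.index", "cH.history")]), c(1, 1))
  expect_equal(as.numeric(d$x["a2", "cH.index"]), 0)
  expect_false(any(grepl("^CC", colnames(d$x))))
})

test_that("pooled CC indicator equals the OR of the separate pair on any bundle", {
  b <- shared_bundle()
  coh <- build_cohort(b, "PN")
  tm <- toy_code_maps()
  d_pool <- build_design(coh, b, "hcc_pooled", tm)
  d_sep <- build_design(coh, b, "hcc_separate", tm)
  ccs <- unique(d_pool$info$key[d_pool$info$unit == "cc"])
  for (cc in ccs) {
    pool <- as.numeric(d_pool$x[, cc])
    ci <- paste0(cc, ".index"); ch <- paste0(cc, ".history")
    sep_or <- pmax(
      if (ci %in% colnames(d_sep$x)) as.numeric(d_sep$x[, ci]) else 0,
      if (ch %in% colnames(d_sep$x)) as.numeric(d_sep$x[, ch]) else 0)
    expect_identical(pool, sep_or)
  }
})

test_that("designs are invariant to diagnosis row order", {
  b <- shared_bundle()
  coh <- build_cohort(b, "HF")
  b2 <- b
  set.seed(1)
  b2$diagnoses <- b2$diagnoses[sample(nrow(b2$diagnoses)), ]
  tm <- toy_code_maps()
  for (sc in c("cms_base", "hcc_separate", "codes_index_history")) {
    d1 <- build_design(coh, b, sc, tm)
    d2 <- build_design(coh, b2, sc, tm)
    expect_identical(as.matrix(d1$x), as.matrix(d2$x))
  }
})

test_that("cms schemes differ: exclusion algorithm vs POA rule", {
  adm <- rbind(adm_row("a1"), adm_row("a2"))
  dx <- rbind(dx_row("a1", "cX", poa = "Y"),   # excludable CC4, index only
              dx_row("a2", "cA", poa = "N"))   # in-hospital complication
  b <- hand_bundle(adm, dx)
  coh <- build_cohort(b, "HF", winsor_q = 1)
  d_base <- build_design(coh, b, "cms_base", maps)
  d_poa <- build_design(coh, b, "cms_poa", maps)
  # base model: CC4 excluded (index-only complication), poa N irrelevant
  expect_false("CC4" %in% colnames(d_base$x))
  expect_true("CC1" %in% colnames(d_base$x))
  # POA model: CC4 kept (flagged present on admission), poa N dropped
  expect_true("CC4" %in% colnames(d_poa$x))
  expect_false("CC1" %in% colnames(d_poa$x))
})

test_that("unknown schemes are rejected; constant columns are dropped and recorded", {
  b <- shared_bundle()
  coh <- build_cohort(b, "HF")
  expect_error(build_design(coh, b, "hcc_fancy"), "unknown scheme")
  d <- build_design(coh, b, "hcc_pooled", toy_code_maps())
  # every HF admission carries the principal CC -> constant, dropped
  expect_true("CC11" %in% attr(d, "dropped_constant"))
  cs <- Matrix::colSums(d$x[, d$info$unit != "age", drop = FALSE])
  expect_true(all(cs > 0 & cs < nrow(coh)))
})
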