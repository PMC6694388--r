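test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_patients = 500, n_hospitals = 20, seed = 11)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  expect_identical(b1$index_admissions, b2$index_admissions)
  expect_identical(b1$diagnoses, b2$diagnoses)
  expect_identical(b1$enrollment, b2$enrollment)
  expect_identical(b1$truth$hospital_effects, b2$truth$hospital_effects)
})

test_that("intercept-only generators reproduce the marginal mean for all three family/link pairs", {
  n <- 20000
  cases <- list(
    list(spec = glm_spec("gamma", "log"), b0 = log(15000), phi = 0.5,
         mean = 15000),
    list(spec = glm_spec("inverse_gaussian", "log"), b0 = log(20000),
         phi = 2.7e-5, mean = 20000),
    list(spec = glm_spec("gamma", "identity"), b0 = 17000, phi = 0.4,
         mean = 17000))
  for (cs in cases) {
    cfg <- sim_config(
      n_patients = n, n_hospitals = 20,
      condition_mix = c(HF = 1),
      code_catalog = default_code_catalog(4, p_range = c(0.01, 0.02)),
      poa_exempt_codes = character(),
      true_beta = list(HF = c("(Intercept)" = cs$b0)),
      family_link = list(HF = cs$spec),
      dispersion = c(HF = cs$phi), re_sd = 0,
      frac_short_enrollment = 0, frac_under65 = 0, seed = 4)
    y <- generate_bundle(cfg)$index_admissions$payment_30d
    sd_y <- if (cs$spec$family == "gamma") sqrt(cs$phi) * cs$mean
            else sqrt(cs$phi * cs$mean^3)
    expect_lt(abs(mean(y) - cs$mean), 3 * sd_y / sqrt(n))
  }
})

test_that("code prevalence and POA flag frequencies follow the catalog", {
  cat4 <- default_code_catalog(4, p_range = c(0.004, 0.05))
  expect_equal(min(cat4$p_index), 0.004)
  cfg <- sim_config(n_patients = 10000, n_hospitals = 20,
                    code_catalog = cat4, poa_exempt_codes = character(),
                    true_beta = list(
                      AMI = c("(Intercept)" = log(20000)),
                      HF = c("(Intercept)" = log(15000)),
                      PN = c("(Intercept)" = 16000)),
                    seed = 9)
  b <- generate_bundle(cfg)
  rare <- cat4$code[which.min(cat4$p_index)]
  dx <- b$diagnoses
  count <- length(unique(dx$admission_id[dx$code == rare & dx$window == "index"]))
  # binomial 99% interval oracle at p = 0.004, n = 10000
  expect_gte(count, qbinom(0.005, 10000, 0.004))
  expect_lte(count, qbinom(0.995, 10000, 0.004))

  sec <- dx[dx$window == "index" & dx$role == "secondary", ]
  n_sec <- nrow(sec)
  for (tok in c("Y", "N", "missing")) {
    p <- c(Y = 0.75, N = 0.15, missing = 0.10)[[tok]]
    k <- sum(sec$poa == tok)
    expect_gte(k, qbinom(0.0005, n_sec, p))
    expect_lte(k, qbinom(0.9995, n_sec, p))
  }
})

test_that("short-enrollment fraction is exact by construction", {
  cfg <- sim_config(n_patients = 1000, n_hospitals = 10,
                    frac_short_enrollment = 0.13, seed = 2)
  b <- generate_bundle(cfg)
  expect_identical(sum(b$enrollment$prior_ff_months < 12), 130L)
})

test_that("bundles round-trip through CSV field-for-field", {
  b <- generate_bundle(sim_config(n_patients = 300, n_hospitals = 10, seed = 5))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_equal(b2$index_admissions, b$index_admissions)
  expect_equal(b2$diagnoses, b$diagnoses)
  expect_equal(b2$enrollment, b$enrollment)
  expect_equal(b2$truth$true_beta, b$truth$true_beta)
  expect_equal(b2$truth$hospital_effects, b$truth$hospital_effects)
  expect_equal(b2$truth$dispersion, b$truth$dispersion)
})

test_that("schema violations are reported by name", {
  b <- generate_bundle(sim_config(n_patients = 100, n_hospitals = 5, seed = 6))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  dxf <- file.path(dir, "diagnoses.csv")
  dx <- utils::read.csv(dxf)
  utils::write.csv(dx[setdiff(names(dx), "poa")], dxf, row.names = FALSE)
  expect_error(read_bundle(dir), "poa")

  write_bundle(b, dir)
  dx <- utils::read.csv(dxf, stringsAsFactors = FALSE)
  dx$admission_id[1] <- "A9999999"
  utils::write.csv(dx, dxf, row.names = FALSE)
  expect_error(read_bundle(dir), "orphan")
})

test_that("an empty diagnosis table with nonempty admissions is a valid bundle", {
  b <- hand_bundle(adm_row("a1"))
  expect_s3_class(b, "claims_bundle")
  expect_identical(nrow(b$diagnoses), 0L)
})

test_that("identity-link configurations that admit non-positive means are rejected", {
  expect_error(
    sim_config(n_patients = 100, n_hospitals = 5,
               condition_mix = c(PN = 1),
               true_beta = list(PN = c("(Intercept)" = 5000,
                                       "index:C01" = -6000)),
               family_link = list(PN = glm_spec("gamma", "identity")),
               dispersion = c(PN = 0.4), re_sd = c(PN = 100)),
    "non-positive")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(condition_mix = c(AMI = 0.6, HF = 0.6)), "sum to 1")
  expect_error(sim_config(dispersion = c(AMI = -1, HF = 0.5, PN = 0.5)),
               "dispersion")
  expect_error(sim_config(re_sd = -0.1), "re_sd")
})
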