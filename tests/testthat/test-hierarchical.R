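hand_hier <- function(beta, alpha, spec) {
  structure(list(beta = beta, alpha = alpha, tau = sd(alpha),
                 dispersion = 1, spec = spec, hospitals = names(alpha),
                 iterations = 0L, converged = TRUE), class = "hier_glm")
}

test_that("RSP closed-form identities: zero intercepts and log-link multiplicativity", {
  x <- cbind(age_75_84 = c(1, 0, 0, 1), age_85p = c(0, 1, 0, 0))
  h <- c("h1", "h1", "h2", "h2")
  spec <- glm_spec("gamma", "log")
  beta <- c(`(Intercept)` = log(10000), age_75_84 = 0.2, age_85p = 0.4)

  f0 <- hand_hier(beta, c(h1 = 0, h2 = 0), spec)
  prof <- rsp(f0, x, h, national_mean = 12345)
  expect_equal(prof$rsp, c(12345, 12345))

  f1 <- hand_hier(beta, c(h1 = log(1.1), h2 = -0.3), spec)
  prof <- rsp(f1, x, h, national_mean = 10000)
  expect_equal(prof$rsp[prof$hospital_id == "h1"], 1.1 * 10000,
               tolerance = 1e-12)
  expect_equal(prof$rsp[prof$hospital_id == "h2"], exp(-0.3) * 10000,
               tolerance = 1e-12)
})

test_that("identity-link RSP matches a hand-summed oracle", {
  x <- cbind(age_75_84 = c(1, 0, 1), age_85p = c(0, 1, 0))
  h <- c("h1", "h1", "h2")
  beta <- c(`(Intercept)` = 9000, age_75_84 = 1500, age_85p = 3000)
  alpha <- c(h1 = 800, h2 = -400)
  f <- hand_hier(beta, alpha, glm_spec("gamma", "identity"))
  prof <- rsp(f, x, h, national_mean = 11000)
  # hand sums: h1 cases mu_e = 10500, 12000; h2 case mu_e = 10500
  expect_equal(prof$predicted_total, c(10500 + 800 + 12000 + 800, 10500 - 400))
  expect_equal(prof$expected_total, c(22500, 10500))
  expect_equal(prof$rsp, c(24100 / 22500, 10100 / 10500) * 11000)
})

test_that("hierarchical fit recovers no-heterogeneity and shrinks intercepts", {
  set.seed(21)
  nh <- 30; m <- 40; n <- nh * m
  h <- rep(sprintf("h%02d", 1:nh), each = m)
  x <- cbind(age_75_84 = rbinom(n, 1, 0.3))
  y <- rgamma(n, shape = 2, scale = exp(log(9000) + 0.2 * x[, 1]) / 2)
  f <- fit_hierarchical(x, y, h, glm_spec("gamma", "log"))
  expect_lt(f$tau, 0.06)
  expect_lt(max(abs(f$alpha)), 0.05)
  expect_lt(abs(f$beta["age_75_84"] - 0.2), 0.1)
})

test_that("hierarchical estimates agree with an integrated-likelihood cross-check", {
  set.seed(22)
  nh <- 40; m <- 60; n <- nh * m
  hosp <- rep(sprintf("h%02d", 1:nh), each = m)
  alpha <- rnorm(nh, 0, 0.25); names(alpha) <- sprintf("h%02d", 1:nh)
  x <- cbind(age_75_84 = rbinom(n, 1, 0.3))
  mu <- exp(log(9000) + 0.25 * x[, 1] + alpha[hosp])
  y <- rgamma(n, shape = 2, scale = mu / 2)
  f <- fit_hierarchical(x, y, hosp, glm_spec("gamma", "log"))
  df <- data.frame(y = y, age = x[, 1], hosp = hosp)
  gm <- lme4::glmer(y ~ age + (1 | hosp), data = df,
                    family = Gamma(link = "log"),
                    control = lme4::glmerControl(check.conv.singular = "ignore"))
  expect_equal(unname(f$beta["age_75_84"]), lme4::fixef(gm)[["age"]],
               tolerance = 0.05)
  expect_lt(abs(f$tau - attr(lme4::VarCorr(gm)$hosp, "stddev")[[1]]), 0.08)
  re <- lme4::ranef(gm)$hosp[, 1]
  names(re) <- rownames(lme4::ranef(gm)$hosp)
  expect_gt(cor(f$alpha[names(re)], re, method = "spearman"), 0.95)
})

test_that("single-hospital input is rejected", {
  x <- cbind(a = rbinom(50, 1, 0.5))
  y <- rgamma(50, 2, 1e-3)
  expect_error(fit_hierarchical(x, y, rep("h1", 50), glm_spec("gamma", "log")),
               "2 hospitals")
})

test_that("bootstrap CIs are deterministic and reduce to min/max at two replicates", {
  set.seed(30)
  nh <- 8; m <- 30; n <- nh * m
  h <- rep(sprintf("h%d", 1:nh), each = m)
  x <- cbind(age_75_84 = rbinom(n, 1, 0.3))
  y <- rgamma(n, shape = 2, scale = 9000 / 2)
  spec <- glm_spec("gamma", "log")
  ci1 <- bootstrap_rsp(x, y, h, spec, national_mean = 9000, n_boot = 25,
                       seed = 5)
  ci2 <- bootstrap_rsp(x, y, h, spec, national_mean = 9000, n_boot = 25,
                       seed = 5)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_rsp(x, y, h, spec, national_mean = 9000, n_boot = 2,
                       seed = 6)
  sampled <- ci3[ci3$n_sampled > 0, ]
  expect_true(all(sampled$ci_lower <= sampled$ci_upper))
  # with so few replicate values the percentile CI spans the observed range
  one <- sampled[sampled$n_sampled == 1, ]
  expect_equal(one$ci_lower, one$ci_upper)
  expect_error(bootstrap_rsp(x, y, h, spec, 9000, n_boot = 1), "at least 2")
})

test_that("categorization applies CI rules and the 25-case threshold", {
  m <- 20000
  prof <- data.frame(
    hospital_id = c("h1", "h2", "h3", "h4"),
    n_cases = c(100, 100, 24, 100),
    predicted_total = 1, expected_total = 1,
    rsp = c(1.06, 1.00, 1.30, 0.90) * m,
    ci_lower = c(1.02, 0.95, 1.20, 0.85) * m,
    ci_upper = c(1.10, 1.05, 1.40, 0.95) * m)
  cat <- categorize_hospitals(prof, m, min_cases = 25)
  expect_identical(cat$category, c("higher", "no_different", NA, "lower"))
  expect_identical(cat$eligible, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("shift tables count reclassification and respect hospital alignment", {
  a <- c(h1 = "lower", h2 = "no_different", h3 = "higher", h4 = "no_different")
  st0 <- shift_table(a, a)
  expect_equal(st0$pct_reclassified, 0)
  expect_equal(sum(diag(st0$table)), 4)

  b <- c(h1 = "no_different", h2 = "no_different", h3 = "higher", h4 = "lower")
  st <- shift_table(a, b)
  expect_equal(st$pct_reclassified, 100 * mean(a != b[names(a)]))
  # accounting identity: model-B column sums equal B's category counts
  expect_equal(as.numeric(colSums(st$table)),
               as.numeric(table(factor(b, c("lower", "no_different", "higher")))))
  expect_error(shift_table(a, b[1:3]), "mismatched")
  expect_error(shift_table(a, setNames(b, c("h1", "h2", "h3", "hX"))),
               "mismatched")
})

test_that("fitted hierarchical models are calibrated in aggregate", {
  set.seed(23)
  nh <- 25; m <- 50; n <- nh * m
  hosp <- rep(sprintf("h%02d", 1:nh), each = m)
  alpha <- rnorm(nh, 0, 0.15); names(alpha) <- sprintf("h%02d", 1:nh)
  x <- cbind(age_75_84 = rbinom(n, 1, 0.3))
  y <- rgamma(n, shape = 2, scale = exp(log(9000) + alpha[hosp]) / 2)
  f <- fit_hierarchical(x, y, hosp, glm_spec("gamma", "log"))
  prof <- rsp(f, x, hosp, national_mean = mean(y))
  # E-weighted mean RSP equals the national mean within 1%
  expect_equal(sum(prof$rsp * prof$expected_total) / sum(prof$expected_total),
               mean(y), tolerance = 0.01)
})
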