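test_that("eCRF is the declared linear combination", {
  row <- data.frame(gender = "M", age_years = 40, bmi = 25,
                    resting_hr_bpm = 60, activity_score = 4)
  # all-zero weights leave the constant
  w0 <- list(constant = 10, gender_male = 0, age = 0, bmi = 0,
             resting_hr = 0, activity = 0)
  expect_equal(compute_ecrf(row, w0), 10)
  # hand-computed dot product with a fixture weight set
  w <- list(constant = 18.07, gender_male = 2.77, age = -0.10, bmi = -0.17,
            resting_hr = -0.03, activity = 0.61)
  expect_equal(compute_ecrf(row, w),
               18.07 + 2.77 - 0.10 * 40 - 0.17 * 25 - 0.03 * 60 + 0.61 * 4,
               tolerance = 1e-12)
  # negative age weight: older otherwise-identical subject scores lower
  rows <- data.frame(gender = c("F", "F"), age_years = c(30, 60),
                     bmi = 25, resting_hr_bpm = 60, activity_score = 4)
  e <- compute_ecrf(rows)
  expect_lt(e[2], e[1])
  expect_error(compute_ecrf(data.frame(gender = "F")), "missing covariate")
})

test_that("outlier exclusion is single-pass, scale- and shift-invariant", {
  v <- c(rep(0, 46), 10)
  ex <- exclude_outliers(v)
  expect_equal(ex$excluded, 47L)
  # all-equal values: zero SD handled as no outliers
  expect_equal(length(exclude_outliers(rep(3, 10))$excluded), 0)
  # a point constructed (by mean/SD arithmetic) to sit just beyond |Z| = 2.5
  set.seed(81)
  base <- rnorm(40)
  base <- (base - mean(base)) / sd(base)      # exact mean 0, sd 1
  v2 <- c(base, 0)
  # choose the appended value so its single-pass Z score is exactly 2.6
  f <- function(a) { z <- (a - mean(c(base, a))) / sd(c(base, a)); z - 2.6 }
  a_star <- uniroot(f, c(0.1, 50))$root
  v2[41] <- a_star
  ex2 <- exclude_outliers(v2)
  expect_equal(ex2$excluded, 41L)
  expect_equal(max(abs(ex2$z)), 2.6, tolerance = 1e-6)
  # invariance
  v3 <- c(rnorm(30), 8)
  e_raw <- exclude_outliers(v3)$excluded
  expect_equal(exclude_outliers(v3 * 7 + 100)$excluded, e_raw)
})

test_that("split-half reliability matches the covariance-formula oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(split_half_reliability(x, x)$estimate, 1)
  expect_equal(split_half_reliability(x, -x)$estimate, -1)
  set.seed(83)
  b1 <- rnorm(47)
  b2 <- b1 + rnorm(47, sd = 0.5)
  res <- split_half_reliability(b1, b2)
  oracle <- sum((b1 - mean(b1)) * (b2 - mean(b2))) /
    sqrt(sum((b1 - mean(b1))^2) * sum((b2 - mean(b2))^2))
  expect_equal(res$estimate, oracle, tolerance = 1e-12)
  expect_equal(res$df, 45)
})

test_that("partial correlation reduces to Pearson and matches the oracle", {
  set.seed(85)
  x <- rnorm(60); y <- rnorm(60)
  expect_equal(partial_correlation(x, y)$estimate, cor(x, y),
               tolerance = 1e-12)
  # brute-force two-stage regression oracle with one covariate
  z <- rnorm(60)
  rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
  res <- partial_correlation(x, y, covariates = z)
  expect_equal(res$estimate, cor(rx, ry), tolerance = 1e-10)
  expect_equal(res$df, 60 - 3)
  # y an exact linear function of the covariate: partial r ~ 0 residual
  y2 <- 3 * z - 1
  res2 <- partial_correlation(x, y2, covariates = z)
  expect_true(isTRUE(res2$degenerate) || abs(res2$estimate) < 1e-6)
  # two covariates, mixed types (gender-like factor)
  g <- rep(c("F", "M"), 30)
  res3 <- partial_correlation(x, y, covariates = data.frame(z = z, g = g))
  X <- cbind(1, z, as.numeric(factor(g)) - 1)
  ora <- cor(resid(lm.fit(X, x)), resid(lm.fit(X, y)))
  expect_equal(res3$estimate, ora, tolerance = 1e-10)
})

test_that("one-tailed p is half the two-tailed p in the declared direction", {
  set.seed(87)
  x <- rnorm(40)
  y <- 0.5 * x + rnorm(40)
  res <- partial_correlation(x, y, tail = "positive")
  expect_gt(res$estimate, 0)
  expect_equal(res$p_one_tailed, res$p_two_tailed / 2, tolerance = 1e-12)
  res_neg <- partial_correlation(x, -y, tail = "negative")
  expect_equal(res_neg$p_one_tailed, res_neg$p_two_tailed / 2,
               tolerance = 1e-12)
  # against the declared direction the one-tailed p exceeds 1/2
  res_wrong <- partial_correlation(x, y, tail = "negative")
  expect_gt(res_wrong$p_one_tailed, 0.5)
})

test_that("residual-variance analysis is null-calibrated and flags exact fits", {
  set.seed(89)
  x <- runif(500, 18, 77)
  y_hom <- 2 + 0.1 * x + rnorm(500, sd = 1)
  res <- residual_variance_vs_covariate(y_hom, x)
  expect_lt(abs(res$estimate), 0.1)
  # exact linear relation: degenerate
  res_d <- residual_variance_vs_covariate(2 + 0.1 * x, x)
  expect_true(isTRUE(res_d$degenerate))
  # variance growing with x is detected
  y_het <- 2 + 0.1 * x + rnorm(500, sd = 0.2 + 0.05 * (x - 18))
  res_h <- residual_variance_vs_covariate(y_het, x)
  expect_gt(res_h$estimate, 0)
  expect_lt(res_h$p_one_tailed, 0.05)
})

test_that("mediation recovers strong effects and refuses tiny bootstraps", {
  expect_error(mediation_simple(rnorm(50), rnorm(50), rnorm(50),
                                n_boot = 50), "n_boot")
  set.seed(91)
  n <- 200
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n, sd = 0.5)
  y <- 0.5 * m + rnorm(n, sd = 0.5)
  res <- mediation_simple(x, m, y, n_boot = 1000, seed = 4)
  expect_equal(res$a, 0.5, tolerance = 0.2)
  expect_equal(res$b, 0.5, tolerance = 0.2)
  expect_true(res$significant)
  expect_true(res$ci[1] > 0)
  # same seed reproduces the CI exactly
  res2 <- mediation_simple(x, m, y, n_boot = 1000, seed = 4)
  expect_identical(res$ci, res2$ci)
  # permuted outcome: indirect estimates center on zero
  perm <- replicate(40, {
    yp <- sample(y)
    mediation_simple(x, m, yp, n_boot = 100, seed = 1)$indirect
  })
  expect_lt(abs(mean(perm)), 0.03)
})

test_that("mediation residualizes covariates before fitting paths", {
  set.seed(93)
  n <- 150
  g <- rnorm(n)                      # confounder
  x <- g + rnorm(n)
  m <- g + rnorm(n)                  # m related to x only through g
  y <- m + rnorm(n)
  res_adj <- mediation_simple(x, m, y, covariates = g, n_boot = 500,
                              seed = 5)
  res_raw <- mediation_simple(x, m, y, n_boot = 500, seed = 5)
  expect_lt(abs(res_adj$a), abs(res_raw$a))
  expect_false(res_adj$significant)
})

test_that("the analysis runner validates, excludes and reproduces", {
  cfg <- sim_config(n_subjects = 120, seed = 95)
  co <- simulate_cohort(cfg, recordings = FALSE)$cohort
  co$ecrf_mets <- compute_ecrf(co)
  plan <- data.frame(x = "age_years", y = "true_compliance",
                     tail = "negative", outlier_on = "y",
                     stringsAsFactors = FALSE)
  res <- run_study_analyses(co, plan)
  # the built-in age -> stiffness effect makes compliance fall with age
  expect_lt(res$estimate, 0)
  expect_lt(res$p_one_tailed, 0.05)
  # identical rerun
  expect_identical(res, run_study_analyses(co, plan))
  # unknown column names the offender
  bad <- data.frame(x = "age_years", y = "nonexistent_col",
                    stringsAsFactors = FALSE)
  expect_error(run_study_analyses(co, bad), "nonexistent_col")
  # covariate partialing runs end to end on the default plan shape
  co$est_compliance <- co$true_compliance
  co$est_amplitude <- co$true_pulse_pressure_au
  co$est_compliance_frontoparietal <- co$true_compliance
  co$est_compliance_visual <- co$true_compliance
  full <- run_study_analyses(co, default_analysis_plan())
  expect_equal(nrow(full), 7)
  expect_true(all(full$n + full$n_excluded == nrow(co)))
})
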