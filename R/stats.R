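# Cohort statistics: estimated cardiorespiratory fitness, outlier
# exclusion, split-half reliability, partial correlation,
# residual-variance (heteroscedasticity) analysis, percentile-bootstrap
# mediation, and a declarative analysis runner.

#' Container for a correlation-style statistical result
#'
#' @param estimate Effect estimate (usually a correlation).
#' @param n Sample size after exclusions.
#' @param df Degrees of freedom of the test.
#' @param statistic Test statistic (t).
#' @param tail `"positive"`, `"negative"` or `"two"`; the declared
#'   directional hypothesis.
#' @param covariates Names of covariates partialed out.
#' @param exclusions Identifiers (or indices) of excluded observations.
#' @param extra Optional named list of additional fields.
#' @return A list of class `stat_result` with `p_two_tailed` and
#'   `p_one_tailed`.  When the estimate lies in the hypothesized
#'   direction, `p_one_tailed = p_two_tailed / 2`.
#' @keywords internal
stat_result <- function(estimate, n, df, statistic, tail = "two",
                        covariates = character(0), exclusions = integer(0),
                        extra = list()) {
  p2 <- if (is.finite(statistic) && df > 0) {
    2 * pt(-abs(statistic), df)
  } else NA_real_
  p1 <- if (!is.finite(statistic) || df <= 0) NA_real_
  else switch(tail,
              positive = pt(statistic, df, lower.tail = FALSE),
              negative = pt(statistic, df, lower.tail = TRUE),
              two = p2 / 2)
  structure(c(list(estimate = estimate, n = n, df = df,
                   statistic = statistic, p_two_tailed = p2,
                   p_one_tailed = p1, tail = tail,
                   covariates = covariates, exclusions = exclusions),
              extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("r = %.3f, df = %d, t = %.2f, p(two) = %.4g, p(one, %s) = %.4g\n",
              x$estimate, x$df, x$statistic, x$p_two_tailed, x$tail,
              x$p_one_tailed))
  if (length(x$covariates)) {
    cat("  partialed:", paste(x$covariates, collapse = ", "), "\n")
  }
  if (length(x$exclusions)) {
    cat("  excluded:", paste(x$exclusions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default eCRF weights
#'
#' Coefficients of the non-exercise estimation equation for
#' cardiorespiratory fitness (in METs) from gender, age, BMI, resting
#' heart rate and a 0--7 self-reported physical-activity score, of the
#' form popularized by Jurca et al. (2005, Am J Prev Med).  The weights
#' are configuration data, not code: supply your own list to
#' [compute_ecrf()] to use a different published equation.
#'
#' @return Named list: `constant`, `gender_male`, `age`, `bmi`,
#'   `resting_hr`, `activity`.
#' @export
ecrf_weights <- function() {
  list(constant = 18.07, gender_male = 2.77, age = -0.10, bmi = -0.17,
       resting_hr = -0.03, activity = 0.61)
}

#' Estimated cardiorespiratory fitness (eCRF)
#'
#' Linear combination of gender, age, BMI, resting heart rate and the
#' physical-activity score plus a constant, in metabolic equivalents
#' (METs).  Rows with any missing covariate get `NA` with a warning.
#'
#' @param data data.frame with columns `gender` (`"M"`/`"F"` or 0/1
#'   male), `age_years`, `bmi`, `resting_hr_bpm`, `activity_score`.
#' @param weights Coefficient list as from [ecrf_weights()].
#' @return Numeric eCRF per row (METs).
#' @export
compute_ecrf <- function(data, weights = ecrf_weights()) {
  req <- c("gender", "age_years", "bmi", "resting_hr_bpm", "activity_score")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  male <- if (is.numeric(data$gender)) data$gender == 1 else
    toupper(as.character(data$gender)) %in% c("M", "MALE", "1")
  out <- weights$constant + weights$gender_male * as.numeric(male) +
    weights$age * data$age_years + weights$bmi * data$bmi +
    weights$resting_hr * data$resting_hr_bpm +
    weights$activity * data$activity_score
  if (anyNA(out)) warning(sum(is.na(out)), " row(s) with missing covariates")
  out
}

#' Exclude statistical outliers by standardized score
#'
#' Single-pass exclusion: values are standardized against the sample
#' mean and SD once, and those with `|Z| > z_cut` (default 2.5) are
#' marked excluded.  No re-standardization after removal.  A zero-SD
#' sample has no outliers.  Scale- and shift-invariant.
#'
#' @param values Numeric vector, `length >= 3` (NAs are kept, never
#'   counted as outliers).
#' @param z_cut Threshold (default 2.5).
#' @return List: `keep` (logical), `excluded` (indices), `z` (scores).
#' @export
exclude_outliers <- function(values, z_cut = 2.5) {
  if (sum(is.finite(values)) < 3) stop("need at least 3 finite values")
  m <- mean(values, na.rm = TRUE)
  s <- sd(values, na.rm = TRUE)
  z <- if (s == 0) rep(0, length(values)) else (values - m) / s
  out <- is.finite(z) & abs(z) > z_cut
  list(keep = !out, excluded = which(out), z = z)
}

#' Split-half reliability across recording blocks
#'
#' Pearson correlation between an index computed from block 1 and the
#' same index from block 2, over the same subjects.
#'
#' @param block1,block2 Paired numeric vectors.
#' @param tail Directional hypothesis (default `"positive"`).
#' @return A `stat_result` with `df = n - 2`.
#' @export
split_half_reliability <- function(block1, block2, tail = "positive") {
  if (length(block1) != length(block2)) stop("blocks must be paired")
  cc <- complete.cases(block1, block2)
  x <- block1[cc]; y <- block2[cc]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  r <- cor(x, y)
  df <- n - 2
  t <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  stat_result(r, n, df, t, tail = tail,
              exclusions = which(!cc))
}

# Residuals of y on a covariate matrix plus intercept.
residualize <- function(y, covariates) {
  if (is.null(covariates) || NCOL(covariates) == 0) return(y - mean(y))
  X <- cbind(1, as.matrix(covariates))
  as.numeric(lm.fit(X, y)$residuals)
}

#' Partial correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after
#' least-squares projection on the covariates (plus intercept), with
#' `df = n - 2 - n_covariates`.  With no covariates this reduces exactly
#' to the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional vector/matrix/data.frame of covariates.
#'   Factor-like covariates (e.g. gender) may be passed as character and
#'   are coded 0/1 per level beyond the first.
#' @param tail Directional hypothesis (default `"two"`).
#' @return A `stat_result`.
#' @export
partial_correlation <- function(x, y, covariates = NULL, tail = "two") {
  cov_m <- prepare_covariates(covariates, length(x))
  cc <- complete.cases(x, y, if (is.null(cov_m)) rep(1, length(x)) else cov_m)
  x <- x[cc]; y <- y[cc]
  if (!is.null(cov_m)) cov_m <- cov_m[cc, , drop = FALSE]
  n <- length(x)
  k <- if (is.null(cov_m)) 0 else ncol(cov_m)
  if (n <= k + 2) stop("need n > n_covariates + 2")
  rx <- residualize(x, cov_m)
  ry <- residualize(y, cov_m)
  if (sd(rx) <= 1e-10 * max(sd(x), 1e-300) ||
      sd(ry) <= 1e-10 * max(sd(y), 1e-300)) {
    return(stat_result(NA_real_, n, n - 2 - k, NA_real_, tail = tail,
                       covariates = colnames(cov_m) %||% character(0),
                       extra = list(degenerate = TRUE)))
  }
  r <- cor(rx, ry)
  df <- n - 2 - k
  t <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  stat_result(r, n, df, t, tail = tail,
              covariates = colnames(cov_m) %||% character(0),
              exclusions = which(!cc))
}

prepare_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.data.frame(covariates)) {
    cols <- lapply(seq_along(covariates), function(i) {
      v <- covariates[[i]]
      if (is.numeric(v)) v else as.numeric(factor(v)) - 1
    })
    m <- do.call(cbind, cols)
    colnames(m) <- names(covariates)
  } else if (is.matrix(covariates)) {
    m <- covariates
  } else {
    v <- covariates
    m <- matrix(if (is.numeric(v)) v else as.numeric(factor(v)) - 1, ncol = 1)
    colnames(m) <- "cov1"
  }
  if (nrow(m) != n) stop("covariates must match the length of x")
  m
}

#' Heteroscedasticity: residual variance against a covariate
#'
#' Regresses `y` on `x`, squares the standardized residuals (each
#' subject's squared deviation from its predicted mean, in SD units),
#' and correlates those squared residuals with `x`.  A positive
#' correlation indicates variance in `y` growing with `x`.
#'
#' @param y Outcome.
#' @param x Covariate (e.g. age).
#' @param tail Directional hypothesis (default `"positive"`).
#' @return A `stat_result`; `degenerate = TRUE` in the result when the
#'   regression fits exactly (all residuals zero).
#' @export
residual_variance_vs_covariate <- function(y, x, tail = "positive") {
  cc <- complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  if (n < 10) stop("need at least 10 complete observations")
  fit <- lm(y ~ x)
  r <- resid(fit)
  if (sd(r) < 1e-12 * max(sd(y), 1e-300)) {
    return(stat_result(NA_real_, n, n - 2, NA_real_, tail = tail,
                       extra = list(degenerate = TRUE)))
  }
  z2 <- (r / sd(r))^2
  est <- cor(z2, x)
  df <- n - 2
  t <- if (abs(est) >= 1) sign(est) * Inf else est * sqrt(df / (1 - est^2))
  stat_result(est, n, df, t, tail = tail, exclusions = which(!cc))
}

#' Simple mediation with a percentile bootstrap
#'
#' Ordinary-least-squares mediation (single mediator): the a-path
#' regresses `m` on `x`, the b-path regresses `y` on `m` controlling
#' `x`; the indirect effect is `a * b`.  Its confidence interval is the
#' percentile interval of the indirect effect over `n_boot` resamples of
#' subjects.  Covariates, when given, are residualized out of `x`, `m`
#' and `y` before the paths are fit.
#'
#' @param x Predictor.
#' @param m Mediator.
#' @param y Outcome.
#' @param covariates Optional covariates (vector/matrix/data.frame).
#' @param n_boot Bootstrap samples (default 5000; refuses < 100).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Optional integer; when given, the bootstrap is
#'   reproducible and the caller's RNG state is restored afterwards.
#' @return A list of class `mediation_result`: `a`, `b`, `direct`,
#'   `indirect`, `ci` (percentile), `significant` (CI excludes 0), `n`,
#'   `n_boot`, `conf_level`.
#' @export
mediation_simple <- function(x, m, y, covariates = NULL, n_boot = 5000,
                             conf_level = 0.95, seed = NULL) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  cov_m <- prepare_covariates(covariates, length(x))
  cc <- complete.cases(x, m, y, if (is.null(cov_m)) rep(1, length(x)) else cov_m)
  x <- x[cc]; m <- m[cc]; y <- y[cc]
  if (!is.null(cov_m)) {
    cov_m <- cov_m[cc, , drop = FALSE]
    x <- residualize(x, cov_m)
    m <- residualize(m, cov_m)
    y <- residualize(y, cov_m)
  }
  n <- length(x)
  if (n < 10) stop("need at least 10 complete observations")
  paths <- ols_paths(x, m, y)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  Xb <- matrix(x[idx], n_boot, n)
  Mb <- matrix(m[idx], n_boot, n)
  Yb <- matrix(y[idx], n_boot, n)
  mx <- rowMeans(Xb); mm <- rowMeans(Mb); my <- rowMeans(Yb)
  Sxx <- rowMeans(Xb * Xb) - mx^2
  Smm <- rowMeans(Mb * Mb) - mm^2
  Sxm <- rowMeans(Xb * Mb) - mx * mm
  Sxy <- rowMeans(Xb * Yb) - mx * my
  Smy <- rowMeans(Mb * Yb) - mm * my
  ab <- (Sxm / Sxx) * (Sxx * Smy - Sxm * Sxy) / (Sxx * Smm - Sxm^2)
  alpha <- (1 - conf_level) / 2
  ci <- quantile(ab, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(a = paths$a, b = paths$b, direct = paths$direct,
                 indirect = paths$a * paths$b, ci = ci,
                 significant = ci[1] > 0 || ci[2] < 0,
                 n = n, n_boot = n_boot, conf_level = conf_level),
            class = "mediation_result")
}

ols_paths <- function(x, m, y) {
  sxx <- stats::var(x); sxm <- stats::cov(x, m); smm <- stats::var(m)
  sxy <- stats::cov(x, y); smy <- stats::cov(m, y)
  a <- sxm / sxx
  den <- sxx * smm - sxm^2
  b <- (sxx * smy - sxm * sxy) / den
  direct <- (smm * sxy - sxm * smy) / den
  list(a = a, b = b, direct = direct)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(paste0("indirect a*b = %.4f (a = %.4f, b = %.4f, ",
                     "direct = %.4f)\n%d%% percentile CI [%.4f, %.4f] ",
                     "over %d bootstrap samples: %s\n"),
              x$indirect, x$a, x$b, x$direct, round(100 * x$conf_level),
              x$ci[1], x$ci[2], x$n_boot,
              if (x$significant) "CI excludes 0 (significant mediation)"
              else "CI contains 0"))
  invisible(x)
}

#' Run a declared list of cohort analyses
#'
#' Executes a plan of correlation analyses over a cohort table.  Each
#' plan entry names the `x` and `y` columns, optional covariate columns
#' (comma-separated), the declared tail, and which variables the
#' single-pass |Z| > 2.5 outlier exclusion applies to (`""`, `"x"`,
#' `"y"`, or `"xy"`).  Exclusions and covariates are recorded in the
#' output so every analysis is auditable.
#'
#' @param cohort Cohort data.frame.
#' @param plan data.frame with columns `x`, `y` and optionally
#'   `covariates`, `tail`, `outlier_on`, `z_cut`.
#' @return A tidy data.frame, one row per analysis: `x`, `y`,
#'   `covariates`, `tail`, `n`, `n_excluded`, `excluded_ids`, `estimate`,
#'   `df`, `statistic`, `p_one_tailed`, `p_two_tailed`.
#' @export
run_study_analyses <- function(cohort, plan) {
  stopifnot(is.data.frame(cohort), is.data.frame(plan))
  if (is.null(plan$covariates)) plan$covariates <- ""
  if (is.null(plan$tail)) plan$tail <- "two"
  if (is.null(plan$outlier_on)) plan$outlier_on <- ""
  if (is.null(plan$z_cut)) plan$z_cut <- 2.5
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    p <- plan[i, ]
    covs <- if (nzchar(p$covariates)) {
      trimws(strsplit(p$covariates, ",")[[1]])
    } else character(0)
    need <- c(p$x, p$y, covs)
    miss <- setdiff(need, names(cohort))
    if (length(miss)) stop("plan refers to unknown column(s): ",
                           paste(miss, collapse = ", "))
    keep <- rep(TRUE, nrow(cohort))
    for (side in c("x", "y")) {
      if (grepl(side, p$outlier_on, fixed = TRUE)) {
        v <- cohort[[if (side == "x") p$x else p$y]]
        keep <- keep & exclude_outliers(v, p$z_cut)$keep
      }
    }
    ids <- if (!is.null(cohort$subject_id)) cohort$subject_id else
      as.character(seq_len(nrow(cohort)))
    sub <- cohort[keep, , drop = FALSE]
    res <- partial_correlation(sub[[p$x]], sub[[p$y]],
                               covariates = if (length(covs))
                                 sub[covs] else NULL,
                               tail = p$tail)
    data.frame(x = p$x, y = p$y, covariates = p$covariates, tail = p$tail,
               n = res$n, n_excluded = sum(!keep),
               excluded_ids = paste(ids[!keep], collapse = ";"),
               estimate = res$estimate, df = res$df,
               statistic = res$statistic,
               p_one_tailed = res$p_one_tailed,
               p_two_tailed = res$p_two_tailed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an analysis plan from YAML
#'
#' The file holds a list of entries with fields `x`, `y` and optionally
#' `covariates` (list or comma-separated string), `tail`, `outlier_on`,
#' `z_cut`.
#'
#' @param path YAML file path.
#' @return A plan data.frame for [run_study_analyses()].
#' @export
read_analysis_plan <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- lapply(raw, function(r) {
    # YAML 1.1 reads a bare `y` as TRUE; map it back to the column name
    nm <- names(r)
    nm[nm %in% c("TRUE", "yes")] <- "y"
    names(r) <- nm
    oo <- r$outlier_on %||% ""
    if (is.logical(oo)) oo <- if (isTRUE(oo)) "y" else ""
    data.frame(x = r$x, y = r$y,
               covariates = paste(unlist(r$covariates), collapse = ","),
               tail = r$tail %||% "two",
               outlier_on = oo,
               z_cut = r$z_cut %||% 2.5,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' The package's standard cohort analysis plan
#'
#' The directional analyses run over a processed cohort: age and eCRF
#' against the global compliance and amplitude estimates (with gender
#' partialed out of eCRF analyses and the |Z| > 2.5 exclusion on the
#' optical measure), plus the regional compliance contrasts.
#'
#' @return A plan data.frame for [run_study_analyses()].
#' @export
default_analysis_plan <- function() {
  data.frame(
    x = c("age_years", "age_years", "ecrf_mets", "age_years",
          "age_years", "ospan_score", "ospan_score"),
    y = c("est_compliance", "est_amplitude", "est_compliance",
          "est_compliance_frontoparietal", "est_compliance_visual",
          "est_compliance_frontoparietal", "est_compliance"),
    covariates = c("", "", "gender", "", "", "", ""),
    tail = c("negative", "positive", "positive", "negative", "negative",
             "positive", "positive"),
    outlier_on = c("y", "y", "y", "y", "y", "y", "y"),
    z_cut = 2.5,
    stringsAsFactors = FALSE)
}
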