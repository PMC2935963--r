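#' Sympercent group difference on the natural-log scale
#'
#' Fits ordinary least squares of `ln(outcome)` on the 0/1 group
#' indicator plus optional covariates; 100 times the group coefficient is
#' the sympercent (symmetric percentage) difference between groups, with
#' its standard error and two-sided t-test p-value. For two groups whose
#' outcomes differ by an exact factor `c`, the unadjusted estimate is
#' exactly `100 * ln(c)`.
#'
#' @param data A data frame, one row per subject.
#' @param outcome Name of the strictly positive outcome column.
#' @param group Name of the 0/1 group indicator column (both labels must
#'   be present).
#' @param covariates Character vector of covariate column names (default
#'   none).
#' @return A one-row tibble of class `sympercent_result`: `outcome`,
#'   `estimate` (sympercent), `std_error`, `statistic`, `p_value`, `n`,
#'   `covariates`. The underlying `lm` fit is attached as attribute
#'   `"fit"`.
#' @examples
#' d <- data.frame(group = rep(0:1, each = 10),
#'                 y = rep(c(10, 10 * exp(0.15)), each = 10))
#' sympercent_difference(d, "y", "group")   # estimate = 15
#' @export
sympercent_difference <- function(data, outcome, group = "group",
                                  covariates = character()) {
  stopifnot(is.data.frame(data))
  for (col in c(outcome, group, covariates)) {
    if (!col %in% names(data)) stop("column not found: ", col)
  }
  y <- data[[outcome]]
  if (anyNA(y) || anyNA(data[[group]])) stop("missing values in fitted columns")
  bad <- which(y <= 0)
  if (length(bad)) {
    stop("outcome '", outcome, "' must be strictly positive for the log ",
         "transform; offending row(s): ",
         paste(head(bad, 10L), collapse = ", "))
  }
  g <- data[[group]]
  if (length(unique(g)) < 2L) {
    stop("group column '", group, "' must contain both labels")
  }
  df <- data.frame(.logy = log(y), .group = as.numeric(g),
                   data[, covariates, drop = FALSE])
  fml <- stats::as.formula(paste(".logy ~ .group",
                                 if (length(covariates))
                                   paste("+", paste(covariates, collapse = " + "))
                                 else ""))
  fit <- stats::lm(fml, data = df)
  if (anyNA(coef(fit))) {
    stop("rank-deficient model: collinear covariates (",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "), ")")
  }
  sm <- summary(fit)$coefficients
  est <- 100 * sm[".group", "Estimate"]
  se <- 100 * sm[".group", "Std. Error"]
  out <- tibble::tibble(
    outcome = outcome,
    estimate = est,
    std_error = se,
    statistic = sm[".group", "t value"],
    p_value = sm[".group", "Pr(>|t|)"],
    n = nrow(df),
    covariates = paste(covariates, collapse = ", ")
  )
  class(out) <- c("sympercent_result", class(out))
  attr(out, "fit") <- fit
  out
}

#' @rdname tidiers
#' @export
tidy.sympercent_result <- function(x, ...) {
  fit <- attr(x, "fit")
  sm <- summary(fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p_value = sm[, "Pr(>|t|)"]
  )
}

#' @rdname tidiers
#' @export
glance.sympercent_result <- function(x, ...) {
  fit <- attr(x, "fit")
  sm <- summary(fit)
  tibble::tibble(r_squared = sm$r.squared, sigma = sm$sigma,
                 df_residual = fit$df.residual, n = x$n)
}

#' Agreement regression between two measurement methods
#'
#' Pearson correlation and the ordinary least-squares fit of `y` on `x`
#' with standard errors, as used to compare shape-sensitive against
#' ring-model outputs of the same scans.
#'
#' @param x,y Equal-length numeric vectors (`>= 3` points, `x` must
#'   vary).
#' @return A one-row tibble: `r`, `intercept`, `intercept_se`, `slope`,
#'   `slope_se`, `p_value` (slope t-test), `n`.
#' @examples
#' agreement_regression(1:10, 2 * (1:10) + 3)
#' @export
agreement_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0) stop("x is constant: agreement slope is undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    r = stats::cor(x, y),
    intercept = sm["(Intercept)", "Estimate"],
    intercept_se = sm["(Intercept)", "Std. Error"],
    slope = sm["x", "Estimate"],
    slope_se = sm["x", "Std. Error"],
    p_value = sm["x", "Pr(>|t|)"],
    n = length(x)
  )
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Compare cohorts across a set of outcomes
#'
#' For each outcome: group medians and interquartile ranges, the
#' unadjusted sympercent difference and (optionally) the difference
#' adjusted for age, height and weight, with significance stars at the
#' 0.05 / 0.01 / 0.001 thresholds. No multiple-testing correction is
#' applied. Medians use the lower-interpolation convention
#' (`quantile type = 1`).
#'
#' @param data A data frame with the `group` indicator, the outcomes and
#'   any adjustment covariates.
#' @param outcomes Character vector of outcome column names.
#' @param group Name of the 0/1 group column.
#' @param adjust If `TRUE` (default) also report the covariate-adjusted
#'   sympercent.
#' @param covariates Adjustment covariates (default `age`, `height`,
#'   `weight`; must be columns of `data` when `adjust = TRUE`).
#' @return A tibble, one row per outcome: medians and IQRs per group,
#'   `pct_diff`, `pct_diff_stars`, and when adjusted `pct_diff_adj`,
#'   `pct_diff_adj_stars`.
#' @export
compare_cohorts <- function(data, outcomes, group = "group", adjust = TRUE,
                            covariates = c("age", "height", "weight")) {
  stopifnot(is.data.frame(data), length(outcomes) >= 1L)
  g <- data[[group]]
  if (is.null(g) || length(unique(g)) < 2L) {
    stop("group column '", group, "' must contain both labels")
  }
  q1 <- function(z, p) unname(quantile(z, p, type = 1))
  rows <- lapply(outcomes, function(oc) {
    y <- data[[oc]]
    if (is.null(y)) stop("outcome column not found: ", oc)
    un <- sympercent_difference(data, oc, group)
    row <- tibble::tibble(
      outcome = oc,
      median_1 = q1(y[g == 1], 0.5),
      iqr_lo_1 = q1(y[g == 1], 0.25), iqr_hi_1 = q1(y[g == 1], 0.75),
      median_0 = q1(y[g == 0], 0.5),
      iqr_lo_0 = q1(y[g == 0], 0.25), iqr_hi_0 = q1(y[g == 0], 0.75),
      pct_diff = un$estimate,
      pct_diff_se = un$std_error,
      pct_diff_p = un$p_value,
      pct_diff_stars = significance_stars(un$p_value)
    )
    if (adjust) {
      ad <- sympercent_difference(data, oc, group, covariates)
      row$pct_diff_adj <- ad$estimate
      row$pct_diff_adj_se <- ad$std_error
      row$pct_diff_adj_p <- ad$p_value
      row$pct_diff_adj_stars <- significance_stars(ad$p_value)
    }
    row
  })
  dplyr::bind_rows(rows)
}

#' Simulate a two-group cohort with known sympercent effects
#'
#' Generates a subjects-by-variables table in the layout of a pQCT cohort
#' study: a 0/1 group indicator, age / height / weight covariates, and
#' log-normal outcomes whose true group effects are specified directly in
#' sympercent. Used by the test-suite to check parameter recovery.
#'
#' @param n_per_group Subjects per group (default 38, giving n = 76).
#' @param effects Named numeric vector: true sympercent difference per
#'   outcome (e.g. `c(peri_circ = -5.6)`).
#' @param baseline Named numeric vector of group-0 geometric means (same
#'   names as `effects`; defaults to 100 for each).
#' @param sigma Residual SD on the log scale (default 0.05).
#' @param height_effect Per-cm effect of height on the log outcome
#'   (default 0; set nonzero to make covariate adjustment matter).
#' @param seed Integer seed for reproducibility.
#' @return A tibble with columns `group`, `age`, `height`, `weight` and
#'   one column per outcome.
#' @export
simulate_cohort <- function(n_per_group = 38L,
                            effects = c(outcome = -10),
                            baseline = NULL, sigma = 0.05,
                            height_effect = 0, seed = 1L) {
  stopifnot(!is.null(names(effects)), all(nzchar(names(effects))))
  if (is.null(baseline)) {
    baseline <- setNames(rep(100, length(effects)), names(effects))
  }
  set.seed(seed)
  n <- 2L * n_per_group
  group <- rep(c(0L, 1L), each = n_per_group)
  # covariate distributions sized like the study populations
  age <- runif(n, 24, 36)
  height <- rnorm(n, 164, 5)
  weight <- rnorm(n, 59, 7)
  out <- tibble::tibble(group = group, age = age, height = height,
                        weight = weight)
  for (oc in names(effects)) {
    mu <- log(baseline[[oc]]) + (effects[[oc]] / 100) * group +
      height_effect * (height - mean(height))
    out[[oc]] <- exp(mu + rnorm(n, 0, sigma))
  }
  out
}
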