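#' @include AllClasses.R
NULL

# Validate a cohort table: per-patient MDS, overall survival in days (all
# events observed), age.
checkCohort <- function(cohort) {
  need <- c("mds", "os_days")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyNA(cohort$mds) || anyNA(cohort$os_days))
    stop("cohort table has missing mds or os_days")
  if (any(cohort$os_days <= 0)) stop("os_days must be positive")
  if (!is.null(cohort$event) && any(cohort$event != 1))
    stop("all events must be observed (event = 1); censoring is not modelled")
  invisible(TRUE)
}

#' Pearson correlation of MDS with overall survival
#'
#' @param cohort data.frame with columns `mds` and `os_days` (days, all
#'   deaths observed).
#' @return list with `r` and two-sided `p`.
#' @export
pearsonMdsOs <- function(cohort) {
  checkCohort(cohort)
  if (nrow(cohort) < 3) stop("need n >= 3")
  if (stats::sd(cohort$mds) == 0 || stats::sd(cohort$os_days) == 0)
    stop("zero variance")
  ct <- stats::cor.test(cohort$mds, cohort$os_days)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Cox proportional-hazards model with standardized MDS
#'
#' Fits a Cox model of overall survival on MDS (standardized to zero mean
#' and unit SD before fitting, so the exponentiated coefficient is the
#' hazard ratio per 1 SD of MDS), optionally adjusting for age. Uses the
#' Efron partial likelihood for ties (likely with day-resolution survival)
#' and reports Wald CI/p per covariate, the likelihood-ratio model p, and
#' the global Schoenfeld proportional-hazards test p.
#'
#' @param cohort data.frame with `mds`, `os_days`, optionally `age_years`;
#'   all events observed.
#' @param covariates character subset of `c("age")`.
#' @return list (`CoxResult`): `hr_per_sd`, `ci95` (length 2), `p_mds`,
#'   `p_age` (NA when age not included), `model_p` (LRT), `ph_test_p`.
#' @export
fitCox <- function(cohort, covariates = character()) {
  checkCohort(cohort)
  if (nrow(cohort) < 10)
    warning("n < 10: hazard-ratio estimates will be unstable")
  z <- as.vector(scale(cohort$mds))
  dat <- data.frame(os = cohort$os_days, z = z)
  form <- survival::Surv(os, rep(1, nrow(dat))) ~ z
  if ("age" %in% covariates) {
    dat$age <- cohort$age_years
    form <- survival::Surv(os, rep(1, nrow(dat))) ~ z + age
  }
  fit <- survival::coxph(form, data = dat, ties = "efron")
  if (any(abs(stats::coef(fit)) > 20))
    warning("monotone likelihood suspected (coefficient diverging)")
  sm <- summary(fit)
  ci <- exp(stats::confint(fit)["z", ])
  zph <- tryCatch(survival::cox.zph(fit)$table["GLOBAL", "p"],
                  error = function(e) NA_real_)
  list(hr_per_sd = unname(exp(stats::coef(fit)["z"])),
       ci95 = unname(ci),
       p_mds = unname(sm$coefficients["z", "Pr(>|z|)"]),
       p_age = if ("age" %in% covariates)
         unname(sm$coefficients["age", "Pr(>|z|)"]) else NA_real_,
       model_p = unname(sm$logtest["pvalue"]),
       ph_test_p = unname(zph))
}

#' Survival summary (no censoring)
#'
#' Kaplan-Meier median with a log-log confidence interval — which, with all
#' events observed, coincides with the plain sample median — plus the
#' arithmetic mean and range.
#'
#' @param cohort data.frame with `os_days`, all deaths observed.
#' @return list with `median_days`, `ci95_median` (length 2, NA when
#'   degenerate), `mean_days`, `range` (length 2).
#' @export
survivalSummary <- function(cohort) {
  checkCohort(cohort)
  os <- cohort$os_days
  fit <- survival::survfit(survival::Surv(os, rep(1, length(os))) ~ 1,
                           conf.type = "log-log")
  q <- stats::quantile(fit, probs = 0.5)  # survfit method: KM median + CI
  list(median_days = unname(q$quantile),
       ci95_median = c(unname(q$lower), unname(q$upper)),
       mean_days = mean(os), range = range(os))
}

#' Repeated-measures coefficient of variation
#'
#' RMCoV = sd of the within-subject differences divided by the mean of the
#' within-subject means, for paired same-scale measurements (e.g. two ADC
#' acquisitions per volunteer). The sd uses the sample (n-1) denominator;
#' set `sd_denominator = "n"` for the population form.
#'
#' @param x1,x2 paired numeric vectors, one entry per subject.
#' @param sd_denominator `"n-1"` (default) or `"n"`.
#' @return RMCoV (dimensionless).
#' @examples
#' rmcov(c(2, 4), c(4, 2))   # sd(c(-2, 2)) / 3
#' @export
rmcov <- function(x1, x2, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  if (length(x1) != length(x2)) stop("x1 and x2 must be paired")
  n <- length(x1)
  if (n < 2) stop("need n >= 2 pairs")
  s <- stats::sd(x1 - x2)
  if (sd_denominator == "n") s <- s * sqrt((n - 1) / n)
  denom <- mean((x1 + x2) / 2)
  if (denom == 0) stop("zero denominator: mean of within-subject means is 0")
  s / denom
}

#' ICC(2,1) and Bland-Altman limits for paired measurements
#'
#' Two-way random-effects, single-measure, absolute-agreement intraclass
#' correlation from the standard mean-squares decomposition, plus
#' Bland-Altman bias (mean difference) and 95% limits of agreement
#' (bias +/- 1.96 sd of the differences).
#'
#' @param x1,x2 paired numeric vectors (n >= 3 subjects).
#' @return list with `icc_2_1`, `bias`, `loa_low`, `loa_high`.
#' @export
iccBlandAltman <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("x1 and x2 must be paired")
  n <- length(x1)
  if (n < 3) stop("need n >= 3 subjects")
  Y <- cbind(x1, x2)
  k <- 2
  if (stats::var(as.vector(Y)) == 0) stop("degenerate variance")
  rowM <- rowMeans(Y); colM <- colMeans(Y); gm <- mean(Y)
  MSR <- k * sum((rowM - gm)^2) / (n - 1)
  MSC <- n * sum((colM - gm)^2) / (k - 1)
  SSE <- sum((Y - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + gm)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) /
    (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  d <- x1 - x2
  bias <- mean(d)
  s <- stats::sd(d)
  list(icc_2_1 = icc, bias = bias,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' One-way ANOVA across labelled groups
#'
#' @param values numeric vector.
#' @param groups factor or character vector of group labels (>= 2 groups,
#'   each with n >= 2).
#' @return list with `F` and `p`.
#' @export
groupAnova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("each group needs n >= 2")
  if (stats::var(values) == 0) stop("zero variance across all groups")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  list(F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1])
}
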