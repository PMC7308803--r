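#' Area under the ROC curve by Mann-Whitney concordance
#'
#' AUC computed exactly as the Mann-Whitney U statistic normalized by
#' `n_case * n_control` (midranks for ties): the probability that a random
#' case outranks a random control on the score.
#'
#' @param score numeric score (e.g. a model's linear predictor).
#' @param outcome binary outcome (0/1); counts are binarized as `>= 1`.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(score, outcome) {
  y <- as.integer(outcome >= 1)
  if (length(unique(y)) < 2L) stop("AUC needs both outcome classes")
  r <- rank(score)
  n1 <- as.numeric(sum(y == 1L))   # numeric: n1 * (n1 + 1) overflows integer
  n0 <- as.numeric(sum(y == 0L))
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit an association model (logistic or Poisson)
#'
#' Maximum-likelihood GLM fit (IRLS, relative-convergence tolerance 1e-8,
#' at most 100 iterations) of a binary or 0/1/2-count outcome on the given
#' predictors. Reports per-predictor coefficients with
#' observed-information standard errors and two-sided Wald p-values, the
#' model log-likelihood, and the AUC of the linear predictor against the
#' binarized outcome (for counts: at least one affected vs none). Rows with
#' missing values in any modelled column are dropped and counted.
#' Quasi-separation (any |coefficient| > 30) and non-convergence raise
#' errors with diagnostics.
#'
#' @param data data frame holding outcome and predictors.
#' @param outcome name of the outcome column.
#' @param predictors character vector of predictor column names.
#' @param family `"binomial"` (logit) or `"poisson"` (log).
#' @return An object of class `prs_assoc`.
#' @export
fit_assoc <- function(data, outcome, predictors,
                      family = c("binomial", "poisson")) {
  family <- match.arg(family)
  cols <- c(outcome, predictors)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("column(s) absent from data: ",
                         paste(miss, collapse = ", "))
  d <- data[, cols, drop = FALSE]
  cc <- stats::complete.cases(d)
  n_dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  y <- d[[outcome]]
  if (family == "binomial" && !all(y %in% 0:1))
    stop("binomial outcome must be 0/1")
  if (family == "poisson" && (any(y < 0) || any(y != round(y))))
    stop("poisson outcome must be a non-negative count")
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: single observed value")
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- stats::glm(fml, data = d,
                    family = if (family == "binomial") stats::binomial()
                             else stats::poisson(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged)
    stop("GLM did not converge in 100 IRLS iterations (deviance ",
         format(fit$deviance), ")")
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient model; aliased column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  if (any(abs(cf[-1L]) > 30))
    stop("separation suspected: |coefficient| > 30 for ",
         paste(names(cf)[-1L][abs(cf[-1L]) > 30], collapse = ", "))
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), beta = sm[, 1L], se = sm[, 2L],
                      p = sm[, 4L], row.names = NULL,
                      stringsAsFactors = FALSE)
  ybin <- as.integer(y >= 1)
  structure(list(coefficients = coefs,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 df = attr(stats::logLik(fit), "df"),
                 auc = auc_mw(fit$linear.predictors, y),
                 n = nrow(d), n_dropped = n_dropped,
                 n_by_outcome = table(factor(y)),
                 family = family, outcome = outcome,
                 predictors = predictors,
                 auc_binarization = if (family == "poisson")
                   "any affected (count >= 1) vs none" else "as observed",
                 glm = fit),
            class = "prs_assoc")
}

#' @export
print.prs_assoc <- function(x, digits = 3, ...) {
  cat("prs_assoc: ", x$family, " fit of ", x$outcome, " on ",
      paste(x$predictors, collapse = " + "), "\n", sep = "")
  cat("  n = ", x$n, " (", x$n_dropped, " dropped); outcome counts: ",
      paste(names(x$n_by_outcome), unclass(x$n_by_outcome),
            sep = "=", collapse = ", "), "\n", sep = "")
  tab <- x$coefficients
  tab$beta <- signif(tab$beta, digits)
  tab$se <- signif(tab$se, digits)
  tab$p <- signif(tab$p, digits)
  print(tab, row.names = FALSE)
  cat("  logLik = ", format(x$log_likelihood), ", AUC = ",
      signif(x$auc, digits), "\n", sep = "")
  invisible(x)
}

#' @export
coef.prs_assoc <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' @export
summary.prs_assoc <- function(object, ...) object$coefficients

#' Likelihood-ratio test between nested association fits
#'
#' Twice the log-likelihood difference, referred to the chi-squared upper
#' tail with degrees of freedom equal to the difference in parameter counts.
#' Requires the reduced model's predictors to be a subset of the full
#' model's and both fits to use the same rows.
#'
#' @param full,reduced `prs_assoc` fits.
#' @return A list of class `prs_lrt`: `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "prs_assoc"), inherits(reduced, "prs_assoc"))
  if (!all(reduced$predictors %in% full$predictors))
    stop("models are not nested: reduced predictors are not a subset")
  if (full$n != reduced$n)
    stop("models were fitted on different numbers of rows (",
         full$n, " vs ", reduced$n, ")")
  stat <- 2 * (full$log_likelihood - reduced$log_likelihood)
  if (stat < -1e-8)
    stop("full model log-likelihood below reduced model's: fit failure")
  stat <- max(stat, 0)
  df <- full$df - reduced$df
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p = p), class = "prs_lrt")
}

#' @export
print.prs_lrt <- function(x, ...) {
  cat("LRT: chi-squared = ", format(x$statistic), ", df = ", x$df,
      ", p = ", format(x$p), "\n", sep = "")
  invisible(x)
}

stratum_labels <- function(cutoff) c("all", paste0("<", cutoff),
                                     paste0(">=", cutoff))

# assemble the modelling frame: samples + standardized score + APOE doses
assoc_frame <- function(samples, scores, apoe) {
  d <- merge(as.data.frame(samples), scores[, c("sample_id", "standardized")],
             by = "sample_id", sort = FALSE)
  names(d)[names(d) == "standardized"] <- "prs"
  d <- merge(d, apoe[, c("sample_id", "e2_dose", "e4_dose")],
             by = "sample_id", sort = FALSE)
  d
}

#' Age-stratified association of APOE and PRS with disease
#'
#' Fits, for the whole cohort and for the two age strata (`< cutoff`,
#' `>= cutoff`; age exactly at the cutoff goes to the upper stratum), three
#' models each: (a) APOE allele doses only, (b) PRS (excluding APOE) only,
#' (c) APOE + PRS jointly — plus the likelihood-ratio test of (c) against
#' (a), i.e. whether the polygenic score explains variation over and above
#' APOE. The PRS enters as the standardized, covariate-adjusted score; the
#' \eqn{\epsilon 4} and \eqn{\epsilon 2} doses enter as two separate count
#' covariates.
#'
#' @param samples a sample table with the outcome, the age variable and any
#'   requested covariate columns.
#' @param scores a `score_result` from [adjust_standardize()].
#' @param apoe APOE calls from [call_apoe_panel()].
#' @param outcome outcome column name (binary `status` or the 0/1/2
#'   `parental_count`).
#' @param family `"binomial"` or `"poisson"` (must match the outcome type).
#' @param age_var name of the age column used for stratification.
#' @param cutoff stratum boundary in years (default 80).
#' @param covariates optional extra predictor columns (e.g. `age`, `sex`)
#'   added to every model.
#' @param min_events strata with fewer outcome events are skipped with a
#'   warning (default 10).
#' @return An object of class `prs_assoc_table`; `as.data.frame()` renders
#'   the per-stratum, per-block coefficient/AUC/LRT table.
#' @export
stratified_assoc <- function(samples, scores, apoe, outcome = "status",
                             family = c("binomial", "poisson"),
                             age_var = "age", cutoff = 80,
                             covariates = NULL, min_events = 10L) {
  family <- match.arg(family)
  if (cutoff <= 0) stop("cutoff must be positive")
  d <- assoc_frame(samples, scores, apoe)
  if (!age_var %in% names(d)) stop("age variable '", age_var, "' not found")
  strata <- list(rep(TRUE, nrow(d)),
                 d[[age_var]] < cutoff,
                 d[[age_var]] >= cutoff)
  names(strata) <- stratum_labels(cutoff)
  preds_apoe <- c("e4_dose", "e2_dose", covariates)
  preds_prs <- c("prs", covariates)
  preds_joint <- c("e4_dose", "e2_dose", "prs", covariates)
  out <- list()
  for (s in names(strata)) {
    ds <- d[strata[[s]], , drop = FALSE]
    events <- sum(ds[[outcome]] >= 1, na.rm = TRUE)
    if (nrow(ds) == 0L || events < min_events) {
      warning("stratum '", s, "' skipped: ", events, " outcome events")
      next
    }
    fits <- list(apoe = fit_assoc(ds, outcome, preds_apoe, family),
                 prs = fit_assoc(ds, outcome, preds_prs, family),
                 joint = fit_assoc(ds, outcome, preds_joint, family))
    out[[s]] <- list(fits = fits,
                     lrt = likelihood_ratio_test(fits$joint, fits$apoe),
                     n = nrow(ds), n_by_outcome = fits$joint$n_by_outcome)
  }
  structure(list(strata = out, outcome = outcome, family = family,
                 age_var = age_var, cutoff = cutoff,
                 covariates = covariates),
            class = "prs_assoc_table")
}

#' @export
as.data.frame.prs_assoc_table <- function(x, ...) {
  rows <- list()
  for (s in names(x$strata)) {
    st <- x$strata[[s]]
    for (b in names(st$fits)) {
      f <- st$fits[[b]]
      cf <- f$coefficients[f$coefficients$term != "(Intercept)", ,
                           drop = FALSE]
      rows[[length(rows) + 1L]] <-
        data.frame(stratum = s, block = b, n = st$n, term = cf$term,
                   beta = cf$beta, se = cf$se, p = cf$p, auc = f$auc,
                   lrt_p = st$lrt$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.prs_assoc_table <- function(x, digits = 3, ...) {
  cat("prs_assoc_table: ", x$family, " models of ", x$outcome,
      ", stratified on ", x$age_var, " at ", x$cutoff, " years\n", sep = "")
  tab <- as.data.frame(x)
  for (col in c("beta", "se", "p", "auc", "lrt_p"))
    tab[[col]] <- signif(tab[[col]], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Parental-proxy association models
#'
#' The three proxy fits: Poisson regression of the 0/1/2 affected-parent
#' count, and separate logistic regressions of maternal and paternal status,
#' each on APOE doses + PRS + covariates, with the relevant parental age
#' (mean of the two parents' ages for the count model) as the age covariate.
#'
#' @inheritParams stratified_assoc
#' @param samples a proxy sample table from [simulate_parents()] (or the same
#'   columns from real data).
#' @return A list of class `prs_parental`: `count` (Poisson), `maternal`,
#'   `paternal` (logistic) `prs_assoc` fits.
#' @export
parental_assoc <- function(samples, scores, apoe, covariates = NULL) {
  d <- assoc_frame(samples, scores, apoe)
  need <- c("parental_count", "maternal_status", "paternal_status",
            "maternal_age", "paternal_age")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("proxy column(s) absent: ",
                         paste(miss, collapse = ", "))
  d$parental_age <- (d$maternal_age + d$paternal_age) / 2
  base <- c("e4_dose", "e2_dose", "prs")
  structure(list(
    count = fit_assoc(d, "parental_count",
                      c(base, "parental_age", covariates), "poisson"),
    maternal = fit_assoc(d, "maternal_status",
                         c(base, "maternal_age", covariates), "binomial"),
    paternal = fit_assoc(d, "paternal_status",
                         c(base, "paternal_age", covariates), "binomial")),
    class = "prs_parental")
}

#' @export
print.prs_parental <- function(x, ...) {
  for (nm in names(x)) {
    cat("--", nm, "--\n")
    print(x[[nm]])
  }
  invisible(x)
}

#' Parental age tables by child APOE homozygote stratum
#'
#' Restricts to participants homozygous for an APOE allele (\eqn{\epsilon 4
#' \epsilon 4}, \eqn{\epsilon 3 \epsilon 3}, \eqn{\epsilon 2 \epsilon 2}) —
#' so each parent carries at least one copy of that allele — and tabulates
#' (i) per stratum, the mean (SD) of the mothers' and fathers' last recorded
#' age (age at death when dead) and of their age at death (dead parents
#' only), and (ii) after splitting parents into age groups below / at or
#' above the cutoff, the proportion of each homozygote stratum within each
#' (parent, age-group) column (columns sum to 1).
#'
#' @param samples a proxy sample table with `maternal_age`, `paternal_age`
#'   and the `*_is_death` flags.
#' @param apoe APOE calls from [call_apoe_panel()].
#' @param cutoff parental age-group boundary (default 80).
#' @return A list of class `apoe_survival`: `ages` (per-stratum means/SDs)
#'   and `proportions`.
#' @export
apoe_survival_tables <- function(samples, apoe, cutoff = 80) {
  d <- merge(as.data.frame(samples),
             apoe[, c("sample_id", "diplotype")], by = "sample_id",
             sort = FALSE)
  strata <- c("e4e4", "e3e3", "e2e2")
  d <- d[!is.na(d$diplotype) & d$diplotype %in% strata, , drop = FALSE]
  if (!nrow(d)) stop("no APOE-homozygous participants")
  msd <- function(x) if (length(x)) c(mean = mean(x), sd = stats::sd(x))
                     else c(mean = NA_real_, sd = NA_real_)
  ages <- do.call(rbind, lapply(strata, function(s) {
    ds <- d[d$diplotype == s, ]
    m_last <- msd(ds$maternal_age)
    f_last <- msd(ds$paternal_age)
    m_death <- msd(ds$maternal_age[ds$maternal_is_death])
    f_death <- msd(ds$paternal_age[ds$paternal_is_death])
    data.frame(apoe = s, n = nrow(ds),
               mother_last_mean = m_last[1], mother_last_sd = m_last[2],
               father_last_mean = f_last[1], father_last_sd = f_last[2],
               mother_death_mean = m_death[1], mother_death_sd = m_death[2],
               father_death_mean = f_death[1], father_death_sd = f_death[2],
               stringsAsFactors = FALSE)
  }))
  rownames(ages) <- NULL

  prop_col <- function(age) {
    lo <- age < cutoff
    hi <- age >= cutoff
    cbind(lo = as.vector(table(factor(d$diplotype[lo], levels = strata))) /
            max(sum(lo), 1L),
          hi = as.vector(table(factor(d$diplotype[hi], levels = strata))) /
            max(sum(hi), 1L))
  }
  fp <- prop_col(d$paternal_age)
  mp <- prop_col(d$maternal_age)
  proportions <- data.frame(apoe = strata,
                            father_lt = fp[, "lo"], father_ge = fp[, "hi"],
                            mother_lt = mp[, "lo"], mother_ge = mp[, "hi"],
                            stringsAsFactors = FALSE)
  names(proportions) <- c("apoe", paste0("father_<", cutoff),
                          paste0("father_>=", cutoff),
                          paste0("mother_<", cutoff),
                          paste0("mother_>=", cutoff))
  structure(list(ages = ages, proportions = proportions, cutoff = cutoff),
            class = "apoe_survival")
}

#' @export
print.apoe_survival <- function(x, digits = 4, ...) {
  cat("Parental ages by participant APOE homozygote stratum\n")
  tab <- x$ages
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits)
  print(tab, row.names = FALSE)
  cat("\nProportions by parental age group (columns sum to 1)\n")
  tab2 <- x$proportions
  num <- vapply(tab2, is.numeric, logical(1))
  tab2[num] <- lapply(tab2[num], signif, digits)
  print(tab2, row.names = FALSE)
  invisible(x)
}
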