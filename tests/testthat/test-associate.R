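test_that("logistic fit on a 2x2 table recovers the closed-form log odds ratio", {
  d <- data.frame(y = c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30)),
                  x = c(rep(1, 40), rep(0, 40)))
  fit <- fit_assoc(d, "y", "x", "binomial")
  expect_equal(unname(coef(fit)["x"]), log(9), tolerance = 1e-6)
  expect_equal(fit$n, 80)
  expect_equal(as.integer(fit$n_by_outcome), c(40L, 40L))
})

test_that("AUC equals the O(n^2) Mann-Whitney oracle, ties included", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(50:500, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(seq_len(20), n, replace = TRUE)  # heavy ties
    expect_equal(auc_mw(s, y), auc_oracle(s, y), tolerance = 1e-12)
  }
  # cross-check against an established implementation on continuous scores
  skip_if_not_installed("pROC")
  y <- rbinom(400, 1, 0.5)
  s <- rnorm(400) + y
  expect_equal(auc_mw(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("fit_assoc validates outcomes, missingness and pathologies", {
  d <- data.frame(y = rbinom(100, 1, 0.5), x = rnorm(100))
  d$y[1] <- NA
  fit <- fit_assoc(d, "y", "x", "binomial")
  expect_equal(fit$n_dropped, 1)
  expect_error(fit_assoc(data.frame(y = rep(0, 50), x = rnorm(50)),
                         "y", "x", "binomial"), "degenerate")
  expect_error(fit_assoc(data.frame(y = c(0, 1, 2, 1), x = rnorm(4)),
                         "y", "x", "binomial"), "0/1")
  expect_error(fit_assoc(data.frame(y = c(0.5, 1, 0), x = rnorm(3)),
                         "y", "x", "poisson"), "count")
  # aliased columns are reported, not silently dropped
  d2 <- data.frame(y = rbinom(200, 1, 0.5), a = rnorm(200))
  d2$b <- d2$a
  expect_error(fit_assoc(d2, "y", c("a", "b"), "binomial"), "aliased|rank")
  # complete separation is refused with diagnostics
  x3 <- c(rnorm(50, -2), rnorm(50, 2))
  d3 <- data.frame(y = as.integer(x3 > 0), x = x3)
  expect_error(suppressWarnings(fit_assoc(d3, "y", "x", "binomial")),
               "separation|converge")
})

test_that("likelihood-ratio test follows the chi-squared contract", {
  set.seed(10)
  d <- data.frame(y = rbinom(500, 1, 0.4), x = rnorm(500), z = rnorm(500))
  full <- fit_assoc(d, "y", c("x", "z"), "binomial")
  red <- fit_assoc(d, "y", "x", "binomial")
  lr <- likelihood_ratio_test(full, red)
  expect_equal(lr$df, 1)
  expect_gte(lr$statistic, 0)
  # identity: full against itself
  self <- likelihood_ratio_test(full, full)
  expect_equal(self$statistic, 0)
  expect_equal(self$p, 1)
  # non-nested and row-mismatched comparisons are refused
  other <- fit_assoc(d, "y", "z", "binomial")
  expect_error(likelihood_ratio_test(other, red), "nested")
  d2 <- d[1:400, ]
  red2 <- fit_assoc(d2, "y", "x", "binomial")
  expect_error(likelihood_ratio_test(full, red2), "rows")
})

test_that("a strongly informative predictor yields decisive LRT p-values", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 20000
    x <- rnorm(n)
    y <- rbinom(n, 1, stats::plogis(-1 + 0.3 * x))
    z <- rnorm(n)
    d <- data.frame(y = y, x = x, z = z)
    lr <- likelihood_ratio_test(fit_assoc(d, "y", c("z", "x"), "binomial"),
                                fit_assoc(d, "y", "z", "binomial"))
    expect_lt(lr$p, 1e-6)
  }
})

test_that("stratified tables partition the cohort and honour the boundary", {
  fx <- sim_cohort_fixture(seed = 17, n_target = 3000)
  sc <- adjust_standardize(
    compute_prs(fx$panel, simulate_discovery_sumstats(fx$cfg),
                exclude_regions = apoe_region()),
    fx$pheno[, c("age", "sex")])
  tab <- stratified_assoc(fx$pheno, sc, fx$apoe)
  df <- as.data.frame(tab)
  n_all <- unique(df$n[df$stratum == "all"])
  expect_equal(unique(df$n[df$stratum == "<80"]) +
                 unique(df$n[df$stratum == ">=80"]), n_all)
  # age exactly at the cutoff is assigned to the upper stratum
  ph <- fx$pheno
  ph$age[1] <- 80
  tab2 <- stratified_assoc(ph, sc, fx$apoe)
  expect_equal(tab2$strata[[">=80"]]$n, sum(ph$age >= 80))
  # a cutoff above the oldest sample leaves an empty stratum, skipped cleanly
  expect_warning(tab3 <- stratified_assoc(fx$pheno, sc, fx$apoe,
                                          cutoff = max(fx$pheno$age) + 1),
                 "skipped")
  expect_false(any(grepl(">=", names(tab3$strata))))
  expect_true("all" %in% names(tab3$strata))
})

test_that("parental models are exchangeable under a symmetric simulation", {
  cfg <- sim_config(seed = 18, n_variants = 30, n_blocks = 5, n_causal = 10,
                    n_target = 8000, proxy = TRUE)
  panel <- attach_apoe(simulate_genotypes(cfg), cfg)
  fam <- simulate_parents(panel, cfg)
  ss <- simulate_discovery_sumstats(cfg)
  ph <- simulate_phenotype(panel, cfg)
  sc <- adjust_standardize(compute_prs(panel, ss,
                                       exclude_regions = apoe_region()),
                           ph[, c("age", "sex")])
  ap <- call_apoe_panel(panel)
  par <- parental_assoc(fam$samples, sc, ap)
  bm <- par$maternal$coefficients
  bp <- par$paternal$coefficients
  i <- bm$term == "prs"
  j <- bp$term == "prs"
  joint_se <- sqrt(bm$se[i]^2 + bp$se[j]^2)
  expect_lt(abs(bm$beta[i] - bp$beta[j]), 3 * joint_se)
  # the Poisson count fit exists with the same predictors plus parental age
  expect_true("parental_age" %in% par$count$coefficients$term)

  # all-unaffected parents make the count model degenerate, a clean error
  s0 <- fam$samples
  s0$parental_count <- 0L
  s0$maternal_status <- 0L
  s0$paternal_status <- 0L
  expect_error(parental_assoc(s0, sc, ap), "degenerate")
})

test_that("survival tables order strata and normalize proportions", {
  cfg <- sim_config(seed = 19, n_variants = 10, n_blocks = 2, n_causal = 3,
                    n_target = 20000, proxy = TRUE)
  panel <- attach_apoe(simulate_genotypes(cfg), cfg)
  fam <- simulate_parents(panel, cfg)
  ap <- call_apoe_panel(panel)
  sv <- apoe_survival_tables(fam$samples, ap)
  expect_identical(sv$ages$apoe, c("e4e4", "e3e3", "e2e2"))
  # proportions sum to 1 within each (parent, age-group) column
  for (col in names(sv$proportions)[-1])
    expect_equal(sum(sv$proportions[[col]]), 1)
  # no homozygote children is an error
  ap_het <- ap
  ap_het$diplotype <- "e2e3"
  expect_error(apoe_survival_tables(fam$samples, ap_het), "homozygous")
})
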