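test_that("uncorrelated configuration yields independent variants", {
  cfg <- sim_config(seed = 1, n_variants = 10, n_blocks = 2,
                    within_block_r = 0, n_target = 2000, n_causal = 3)
  panel <- simulate_genotypes(cfg)
  cors <- stats::cor(panel$dosages)
  off <- abs(cors[upper.tri(cors)])
  expect_lt(max(off), 0.08)
})

test_that("within-block correlation is calibrated to the target", {
  # frozen from the pre-build Monte Carlo oracle: tetrachoric calibration at
  # target r = 0.9 with MAF in (0.1, 0.5) gives mean adjacent r^2 ~ 0.52
  cfg <- sim_config(seed = 1, n_variants = 30, n_blocks = 1,
                    within_block_r = 0.9, n_target = 5000, n_causal = 5)
  panel <- simulate_genotypes(cfg)
  r2 <- vapply(1:29, function(j)
    stats::cor(panel$dosages[, j], panel$dosages[, j + 1])^2, numeric(1))
  expect_gt(mean(r2), 0.5)
  # a moderate target is matched closely in correlation (not r^2) terms
  cfg2 <- sim_config(seed = 2, n_variants = 30, n_blocks = 1,
                     within_block_r = 0.5, n_target = 5000, n_causal = 5)
  p2 <- simulate_genotypes(cfg2)
  r <- vapply(1:29, function(j)
    stats::cor(p2$dosages[, j], p2$dosages[, j + 1]), numeric(1))
  expect_equal(mean(r), 0.5, tolerance = 0.1)
})

test_that("generator operations are bit-reproducible under the seed", {
  cfg <- sim_config(seed = 42, n_variants = 24, n_blocks = 3, n_target = 300,
                    n_discovery = 250, n_causal = 8, proxy = TRUE)
  run <- function() {
    panel <- attach_apoe(simulate_genotypes(cfg), cfg)
    list(panel = panel, ss = simulate_discovery_sumstats(cfg),
         ph = simulate_phenotype(panel, cfg),
         fam = simulate_parents(panel, cfg))
  }
  a <- run()
  b <- run()
  expect_identical(a$panel$dosages, b$panel$dosages)
  expect_identical(a$ss, b$ss)
  expect_identical(a$ph, b$ph)
  expect_identical(a$fam$samples, b$fam$samples)
  expect_identical(a$fam$mother$dosages, b$fam$mother$dosages)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_variants = 3, n_blocks = 5), "n_blocks")
  expect_error(sim_config(prevalence = 0), "prevalence")
  expect_error(sim_config(maf_range = c(0.5, 0.1)), "maf_range")
  expect_error(sim_config(n_causal = 300, n_variants = 200), "n_causal")
  expect_error(sim_config(h2_poly = 1), "h2_poly")
})

test_that("APOE attachment is phase-consistent and frequency-faithful", {
  cfg <- sim_config(seed = 3, n_variants = 2, n_blocks = 1, n_causal = 1,
                    n_target = 100000)
  panel <- attach_apoe(simulate_genotypes(cfg), cfg)
  expect_error(attach_apoe(panel, cfg), "duplicate")
  v <- panel$variants
  expect_true(all(c("rs429358", "rs7412") %in% v$id))
  expect_equal(v$chrom[v$id == "rs429358"], "19")
  # haplotype-level sampling: only genotype pairs possible under e2/e3/e4
  c4 <- panel$dosages[, "rs429358"]
  c2 <- panel$dosages[, "rs7412"]
  expect_true(all(paste(c4, c2) %in%
                    c("0 0", "0 1", "0 2", "1 0", "1 1", "2 0")))
  # e4 allele fraction recovered within 3 SE of 0.137 at n = 100,000
  f4 <- mean(c4) / 2
  se <- sqrt(0.137 * (1 - 0.137) / (2 * 100000))
  expect_lt(abs(f4 - 0.137), 3 * se)
  # degenerate frequencies: an all-e3 population is TT / CC throughout
  cfg3 <- sim_config(seed = 4, n_variants = 2, n_blocks = 1, n_causal = 1,
                     n_target = 500, apoe_freqs = c(0, 1, 0))
  p3 <- attach_apoe(simulate_genotypes(cfg3), cfg3)
  expect_true(all(p3$dosages[, "rs429358"] == 0))
  expect_true(all(p3$dosages[, "rs7412"] == 0))
})

test_that("liability-threshold phenotype honours prevalence and null models", {
  cfg <- sim_config(seed = 5, n_variants = 10, n_blocks = 2, n_causal = 3,
                    n_target = 20000, prevalence = 0.2)
  panel <- attach_apoe(simulate_genotypes(cfg), cfg)
  ph <- simulate_phenotype(panel, cfg)
  se <- sqrt(0.2 * 0.8 / 20000)
  expect_lt(abs(mean(ph$status) - 0.2), 3 * se)

  # null model: no APOE or polygenic effect -> e4 logistic beta ~ 0
  cfg0 <- sim_config(seed = 6, n_variants = 10, n_blocks = 2, n_causal = 3,
                     n_target = 20000, beta_e4_young = 0, beta_e4_old = 0,
                     beta_e2 = 0, h2_poly = 0)
  p0 <- attach_apoe(simulate_genotypes(cfg0), cfg0)
  ph0 <- simulate_phenotype(p0, cfg0)
  ap0 <- call_apoe_panel(p0)
  fit <- stats::glm(ph0$status ~ ap0$e4_dose, family = stats::binomial())
  z <- summary(fit)$coefficients[2, 3]
  expect_lt(abs(z), 4)
})

test_that("age-dependent APOE effect is recovered in the fitted strata", {
  cfg <- sim_config(seed = 8, n_variants = 20, n_blocks = 4, n_causal = 8,
                    n_target = 20000, beta_e4_young = 0.5, beta_e4_old = 0.2)
  panel <- attach_apoe(simulate_genotypes(cfg), cfg)
  ph <- simulate_phenotype(panel, cfg)
  ap <- call_apoe_panel(panel)
  d <- data.frame(status = ph$status, age = ph$age, e4 = ap$e4_dose)
  by <- stats::coef(stats::glm(status ~ e4, stats::binomial(),
                               data = d[d$age < 80, ]))["e4"]
  bo <- stats::coef(stats::glm(status ~ e4, stats::binomial(),
                               data = d[d$age >= 80, ]))["e4"]
  expect_gt(by, bo)
})

test_that("discovery summary statistics are powered, calibrated bookkeeping", {
  cfg <- sim_config(seed = 9, n_variants = 20, n_blocks = 4, n_causal = 5,
                    h2_poly = 0.3, n_discovery = 20000)
  ss <- simulate_discovery_sumstats(cfg)
  map <- prsage:::sim_variant_map(cfg)
  # the strongest causal variant is detected decisively at n = 20,000
  strongest <- map$variants$id[map$causal[which.max(abs(map$beta_raw))]]
  expect_lt(ss$p[ss$id == strongest], 1e-4)
  # rs429358 carries the APOE signal
  expect_lt(ss$p[ss$id == "rs429358"], 1e-4)
  # effect-allele labels match the panel's
  panel <- attach_apoe(simulate_genotypes(cfg), cfg)
  m <- match(panel$variants$id, ss$id)
  expect_identical(ss$effect_allele[m], panel$variants$effect_allele)
  expect_true(all(ss$p > 0 & ss$p <= 1))
  expect_true(all(ss$se > 0))
  expect_error(simulate_discovery_sumstats(sim_config(n_discovery = 50)),
               "n_discovery")
})

test_that("null discovery p-values are uniform across replicates", {
  ps <- vapply(1:200, function(i) {
    cfg <- sim_config(seed = 1000 + i, n_variants = 12, n_blocks = 3,
                      n_causal = 2, h2_poly = 0, beta_e4_young = 0,
                      beta_e4_old = 0, beta_e2 = 0, n_discovery = 400)
    simulate_discovery_sumstats(cfg)$p[1]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("parental genotypes are Mendelian and survival shift is planted", {
  cfg <- sim_config(seed = 10, n_variants = 12, n_blocks = 3, n_causal = 4,
                    n_target = 20000, proxy = TRUE)
  panel <- attach_apoe(simulate_genotypes(cfg), cfg)
  fam <- simulate_parents(panel, cfg)
  # parent-child dosage correlation ~ 0.5 at a common variant
  j <- which.max(prsage:::sim_variant_map(cfg)$maf)
  r <- stats::cor(fam$mother$dosages[, j], panel$dosages[, j])
  expect_lt(abs(r - 0.5), 3 / sqrt(20000) + 0.02)
  # proxy coding is the affected-parent count
  expect_identical(fam$samples$parental_count,
                   fam$samples$maternal_status + fam$samples$paternal_status)

  # null survival shift: no death-age difference by parental e4 carriage
  cfg0 <- sim_config(seed = 12, n_variants = 12, n_blocks = 3, n_causal = 4,
                     n_target = 8000, proxy = TRUE, survival_shift_e4 = 0)
  p0 <- attach_apoe(simulate_genotypes(cfg0), cfg0)
  f0 <- simulate_parents(p0, cfg0)
  s <- f0$samples
  mom_e4 <- call_apoe_panel(f0$mother)$e4_dose > 0
  dad_e4 <- call_apoe_panel(f0$father)$e4_dose > 0
  death <- c(s$maternal_age[s$maternal_is_death],
             s$paternal_age[s$paternal_is_death])
  carrier <- c(mom_e4[s$maternal_is_death], dad_e4[s$paternal_is_death])
  expect_lt(abs(mean(death[carrier]) - mean(death[!carrier])), 0.6)

  expect_error(simulate_parents(panel, sim_config(proxy = FALSE)), "proxy")
})

test_that("fitted e4 effects recover the liability model's implied log-odds", {
  # the implied observed-scale effect is computed by brute force: one large
  # cohort (n = 10^6) under the same configuration, marginal logistic fit
  mkcfg <- function(seed, n) sim_config(seed = seed, n_variants = 10,
                                        n_blocks = 2, n_causal = 3,
                                        h2_poly = 0.1, n_target = n)
  big <- mkcfg(901, 1000000)
  pb <- attach_apoe(simulate_genotypes(big), big)
  phb <- simulate_phenotype(pb, big)
  apb <- call_apoe_panel(pb)
  db <- data.frame(status = phb$status, e4_dose = apb$e4_dose,
                   e2_dose = apb$e2_dose)
  implied <- unname(coef(fit_assoc(db, "status", c("e4_dose", "e2_dose"),
                                   "binomial"))["e4_dose"])
  rm(pb, phb, apb, db); gc(verbose = FALSE)

  covered <- vapply(1:50, function(i) {
    cfg <- mkcfg(910 + i, 20000)
    p <- attach_apoe(simulate_genotypes(cfg), cfg)
    ph <- simulate_phenotype(p, cfg)
    ap <- call_apoe_panel(p)
    fit <- fit_assoc(data.frame(status = ph$status, e4_dose = ap$e4_dose,
                                e2_dose = ap$e2_dose),
                     "status", c("e4_dose", "e2_dose"), "binomial")
    cf <- fit$coefficients[fit$coefficients$term == "e4_dose", ]
    abs(cf$beta - implied) <= 1.96 * cf$se
  }, logical(1))
  # 95% Wald CIs should cover the implied effect in at least 90% of runs
  expect_gte(mean(covered), 0.9)
})
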