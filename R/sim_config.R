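#' Simulation configuration
#'
#' Collects and validates every parameter of the synthetic cohort generator.
#' The generator emulates the data structure an age-stratified APOE/PRS
#' analysis of Alzheimer's disease assumes: LD-blocked biallelic genotypes, a
#' discovery cohort yielding per-variant marginal effects, a
#' liability-threshold disease model whose APOE effect differs below/above an
#' age cutoff, Mendelian-consistent parental genotypes with parental case
#' status coded 0/1/2, and parental ages of death shifted by APOE
#' \eqn{\epsilon 4} dose.
#'
#' @param seed integer seed; all five generator operations are bit-reproducible
#'   under it.
#' @param n_variants number of background (non-APOE) variants.
#' @param n_blocks number of LD blocks; variants are split into contiguous
#'   blocks, independent across blocks.
#' @param within_block_r target genotype correlation between adjacent variants
#'   within a block, in `[0, 1)`. Achieved by a latent-Gaussian (copula)
#'   AR(1) whose latent correlations are tetrachorically calibrated so the
#'   *genotype* correlation, not the latent one, matches this value (up to the
#'   ceiling imposed by unequal allele frequencies).
#' @param maf_range range the per-variant minor-allele frequency is drawn
#'   uniformly from; both ends in `(0, 0.5]`.
#' @param n_discovery,n_target discovery / target cohort sizes.
#' @param prevalence disease probability in `(0, 1)`; cases are liabilities
#'   above the empirical `1 - prevalence` quantile.
#' @param beta_e4_young,beta_e4_old liability-scale per-allele effect of
#'   \eqn{\epsilon 4} below / at-or-above `age_cutoff`.
#' @param beta_e2 liability-scale per-allele effect of \eqn{\epsilon 2}
#'   (protective, so negative by default).
#' @param n_causal number of causal background variants.
#' @param h2_poly fraction of the non-APOE liability variance explained by the
#'   polygenic term, in `[0, 1)`.
#' @param age_distribution `c(mean, sd)` of participant age in years.
#' @param age_cutoff years; age strata are `< cutoff` and `>= cutoff`.
#' @param survival_shift_e4 years added to a parent's mean age at death per
#'   \eqn{\epsilon 4} allele (default -1: one year earlier per allele).
#' @param proxy logical; generate parental genotypes/phenotypes.
#' @param apoe_freqs haplotype frequencies `c(e2, e3, e4)`; defaults to the
#'   worldwide estimates 8.4/77.9/13.7 percent.
#' @param apoe_pos GRCh38 positions of rs429358 and rs7412 on chromosome 19.
#' @param sex_effect liability-scale main effect of sex (default 0).
#' @param n_pcs number of simulated stand-in principal-component covariates
#'   (independent standard normals; the generator has no population
#'   structure, so these are pure noise covariates).
#' @param parent_age_death `c(mean, sd)` of parental age at death before the
#'   APOE shift.
#' @param parent_age_alive `c(mean, sd)` of last recorded age for parents
#'   still alive.
#' @param parent_alive_prob probability a parent is alive (their age is then a
#'   last-recorded age, not an age at death).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_variants = 200L,
                       n_blocks = 20L,
                       within_block_r = 0.8,
                       maf_range = c(0.1, 0.5),
                       n_discovery = 2000L,
                       n_target = 2000L,
                       prevalence = 0.2,
                       beta_e4_young = 0.5,
                       beta_e4_old = 0.2,
                       beta_e2 = -0.15,
                       n_causal = 50L,
                       h2_poly = 0.15,
                       age_distribution = c(mean = 75, sd = 8),
                       age_cutoff = 80,
                       survival_shift_e4 = -1.0,
                       proxy = FALSE,
                       apoe_freqs = c(e2 = 0.084, e3 = 0.779, e4 = 0.137),
                       apoe_pos = c(rs429358 = 44908684, rs7412 = 44908822),
                       sex_effect = 0,
                       n_pcs = 4L,
                       parent_age_death = c(mean = 75, sd = 9),
                       parent_age_alive = c(mean = 79, sd = 7),
                       parent_alive_prob = 0.35) {
  cfg <- list(seed = as.integer(seed), n_variants = as.integer(n_variants),
              n_blocks = as.integer(n_blocks), within_block_r = within_block_r,
              maf_range = as.numeric(maf_range),
              n_discovery = as.integer(n_discovery),
              n_target = as.integer(n_target), prevalence = prevalence,
              beta_e4_young = beta_e4_young, beta_e4_old = beta_e4_old,
              beta_e2 = beta_e2, n_causal = as.integer(n_causal),
              h2_poly = h2_poly, age_distribution = as.numeric(age_distribution),
              age_cutoff = age_cutoff, survival_shift_e4 = survival_shift_e4,
              proxy = isTRUE(proxy), apoe_freqs = as.numeric(apoe_freqs),
              apoe_pos = apoe_pos, sex_effect = sex_effect,
              n_pcs = as.integer(n_pcs),
              parent_age_death = as.numeric(parent_age_death),
              parent_age_alive = as.numeric(parent_age_alive),
              parent_alive_prob = parent_alive_prob)
  names(cfg$apoe_freqs) <- c("e2", "e3", "e4")
  names(cfg$age_distribution) <- names(cfg$parent_age_death) <-
    names(cfg$parent_age_alive) <- c("mean", "sd")
  with(cfg, {
    if (n_variants < 1L) stop("n_variants must be positive")
    if (n_blocks < 1L) stop("n_blocks must be positive")
    if (n_variants < n_blocks)
      stop("configuration error: n_variants (", n_variants,
           ") < n_blocks (", n_blocks, ")")
    if (within_block_r < 0 || within_block_r >= 1)
      stop("within_block_r must be in [0, 1)")
    if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
        maf_range[1] <= 0 || maf_range[2] > 0.5)
      stop("maf_range must be an increasing pair in (0, 0.5]")
    if (prevalence <= 0 || prevalence >= 1)
      stop("prevalence must be in (0, 1)")
    if (h2_poly < 0 || h2_poly >= 1) stop("h2_poly must be in [0, 1)")
    if (n_causal > n_variants) stop("n_causal must be <= n_variants")
    if (abs(sum(apoe_freqs) - 1) > 1e-8)
      stop("apoe_freqs must sum to 1")
    # APOE liability variance on top of the unit-variance non-APOE part must
    # leave the model proper (informal bound; doses have variance 2f(1-f))
    b4 <- max(abs(beta_e4_young), abs(beta_e4_old))
    v_apoe <- b4^2 * 2 * apoe_freqs[3] * (1 - apoe_freqs[3]) +
      beta_e2^2 * 2 * apoe_freqs[1] * (1 - apoe_freqs[1])
    if (h2_poly + v_apoe / (1 + v_apoe) >= 1)
      stop("polygenic plus APOE variance leaves no room for noise")
    if (age_distribution[2] <= 0) stop("age sd must be positive")
    if (age_cutoff <= 0) stop("age_cutoff must be positive")
  })
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_variants, " variants in ", x$n_blocks,
      " blocks (adjacent r ~ ", x$within_block_r, ")\n",
      "  cohorts: discovery n=", x$n_discovery, ", target n=", x$n_target,
      ", prevalence ", x$prevalence, "\n",
      "  APOE e4 effect: ", x$beta_e4_young, " (<", x$age_cutoff, "y) / ",
      x$beta_e4_old, " (>=", x$age_cutoff, "y); e2 effect ", x$beta_e2, "\n",
      "  polygenic: ", x$n_causal, " causal variants, h2 = ", x$h2_poly,
      "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}
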