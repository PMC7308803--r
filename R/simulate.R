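# Seed offsets: each generator operation re-seeds from config$seed plus a
# fixed offset, so every operation is independently bit-reproducible and the
# cohorts (target, discovery, parents) draw from disjoint streams.
.OFF_MAP <- 11L
.OFF_GENO <- 23L
.OFF_APOE <- 37L
.OFF_PHENO <- 53L
.OFF_DISC <- 71L
.OFF_PARENT <- 89L

# ---- latent-Gaussian copula with tetrachoric calibration ----------------

# P(Z1 < t1, Z2 < t2) for standard bivariate normal with correlation rho
biv_lower <- function(t1, t2, rho) {
  rho <- min(rho, 0.9999)
  f <- function(z) stats::pnorm((t2 - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z)
  stats::integrate(f, -Inf, t1, rel.tol = 1e-10)$value
}

# correlation of the allele indicators 1{Z1 < qnorm(p1)}, 1{Z2 < qnorm(p2)}
indicator_corr <- function(p1, p2, rho) {
  p11 <- biv_lower(stats::qnorm(p1), stats::qnorm(p2), rho)
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# latent correlation giving a target genotype correlation between two
# variants with allele frequencies p1, p2; capped at the ceiling unequal
# frequencies impose (rho -> 1)
calibrate_rho <- function(p1, p2, target) {
  if (target <= 0) return(0)
  if (indicator_corr(p1, p2, 0.9999) <= target) return(0.9999)
  stats::uniroot(function(r) indicator_corr(p1, p2, r) - target,
                 c(0, 0.9999), tol = 1e-7)$root
}

# ---- variant map (deterministic given config) ---------------------------

map_cache <- new.env(parent = emptyenv())

map_key <- function(config)
  paste(config$seed, config$n_variants, config$n_blocks,
        config$within_block_r, config$maf_range[1], config$maf_range[2],
        config$n_causal, sep = "|")

# Variant map shared by every cohort of one configuration: ids, positions,
# block structure, allele frequencies, calibrated latent AR coefficients,
# causal set and raw causal weights.
sim_variant_map <- function(config) {
  key <- map_key(config)
  if (!is.null(map_cache[[key]])) return(map_cache[[key]])
  set.seed(config$seed + .OFF_MAP)
  m <- config$n_variants
  nb <- config$n_blocks
  sizes <- diff(floor(seq(0, m, length.out = nb + 1)))
  block <- rep(seq_len(nb), sizes)
  chrom <- ((block - 1L) %% 22L) + 1L
  block_on_chrom <- (block - 1L) %/% 22L
  gap_bp <- 2e6 + 1e4 * max(sizes)
  idx_in_block <- sequence(sizes)
  pos <- 1e6 + block_on_chrom * gap_bp + (idx_in_block - 1L) * 1e4
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  # latent AR coefficient linking variant j to j-1 (0 at block starts)
  rho <- numeric(m)
  if (config$within_block_r > 0 && m > 1) {
    for (j in 2:m) {
      if (block[j] == block[j - 1L])
        rho[j] <- calibrate_rho(maf[j - 1L], maf[j], config$within_block_r)
    }
  }
  causal <- sort(sample.int(m, config$n_causal))
  beta_raw <- stats::rnorm(config$n_causal)
  out <- list(
    variants = data.frame(id = sprintf("snp%05d", seq_len(m)),
                          chrom = as.character(chrom), pos = pos,
                          effect_allele = "A", other_allele = "G",
                          info = 1, stringsAsFactors = FALSE),
    block = block, maf = maf, rho = rho,
    causal = causal, beta_raw = beta_raw)
  map_cache[[key]] <- out
  out
}

# one n x m haplotype matrix (0/1 allele indicators) under the block AR copula
sim_haplotypes <- function(map, n) {
  m <- length(map$maf)
  z <- matrix(stats::rnorm(n * m), n, m)
  for (j in seq_len(m)) {
    r <- map$rho[j]
    if (r > 0) z[, j] <- r * z[, j - 1L] + sqrt(1 - r^2) * z[, j]
  }
  h <- matrix(0L, n, m)
  thr <- stats::qnorm(map$maf)
  for (j in seq_len(m)) h[, j] <- as.integer(z[, j] < thr[j])
  colnames(h) <- map$variants$id
  h
}

# ---- public generator operations ----------------------------------------

#' Simulate an LD-blocked genotype panel
#'
#' Draws `n_target` diploid samples at `n_variants` biallelic variants.
#' Variants fall into `n_blocks` contiguous blocks; within a block adjacent
#' genotypes correlate at approximately `within_block_r` (latent-Gaussian
#' threshold construction, tetrachorically calibrated), across blocks they
#' are independent. Dosages count copies of the effect allele (the minor
#' allele, labelled `A`). Haplotypes are retained as attributes so parental
#' genotypes can be generated by Mendelian transmission.
#'
#' @param config a [sim_config()].
#' @param n number of samples; defaults to `config$n_target`.
#' @return A [genotype_panel()].
#' @seealso [attach_apoe()], [simulate_phenotype()], [simulate_parents()]
#' @export
simulate_genotypes <- function(config, n = config$n_target) {
  stopifnot(inherits(config, "sim_config"))
  map <- sim_variant_map(config)
  set.seed(config$seed + .OFF_GENO)
  hapA <- sim_haplotypes(map, n)
  hapB <- sim_haplotypes(map, n)
  panel <- genotype_panel(hapA + hapB, map$variants,
                          sample_ids = sprintf("S%05d", seq_len(n)))
  attr(panel, "haplotypes") <- list(A = hapA, B = hapB)
  panel
}

# diplotype draws: haplotype labels -> SNP allele counts
# e2 = (rs429358 T, rs7412 T); e3 = (T, C); e4 = (C, C)
apoe_variant_map <- function(config) {
  data.frame(id = c("rs429358", "rs7412"), chrom = "19",
             pos = as.numeric(config$apoe_pos),
             effect_allele = c("C", "T"), other_allele = c("T", "C"),
             info = 1, stringsAsFactors = FALSE)
}

draw_apoe_haplotypes <- function(n, freqs) {
  matrix(sample(c("e2", "e3", "e4"), 2L * n, replace = TRUE, prob = freqs),
         n, 2L)
}

apoe_dosages <- function(haps) {
  cbind(rs429358 = rowSums(haps == "e4"),   # C allele occurs only on e4
        rs7412 = rowSums(haps == "e2"))     # T allele occurs only on e2
}

#' Append the two APOE SNPs to a panel
#'
#' Adds rs429358 and rs7412 on chromosome 19, sampling each sample's two
#' APOE haplotypes from \eqn{\epsilon 2 / \epsilon 3 / \epsilon 4} at the
#' configured frequencies. Sampling at the haplotype level guarantees the
#' two-SNP genotypes are phase-consistent (no genotype pair impossible under
#' the three haplotypes is ever produced). rs429358 dosage counts the C
#' allele, rs7412 dosage the T allele.
#'
#' @inheritParams simulate_genotypes
#' @param panel a [genotype_panel()] not already carrying the APOE SNPs.
#' @return The panel with the two variants inserted in genomic order and the
#'   haplotype draw stored in the `apoe_haplotypes` attribute.
#' @export
attach_apoe <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  if (any(c("rs429358", "rs7412") %in% panel$variants$id))
    stop("duplicate variant ids: panel already contains APOE SNPs")
  set.seed(config$seed + .OFF_APOE)
  n <- nrow(panel$dosages)
  haps <- draw_apoe_haplotypes(n, config$apoe_freqs)
  dos <- apoe_dosages(haps)
  variants <- rbind(panel$variants, apoe_variant_map(config))
  dosages <- cbind(panel$dosages, dos)
  ord <- order(chrom_rank(variants$chrom), variants$pos)
  out <- genotype_panel(dosages[, ord, drop = FALSE],
                        variants[ord, , drop = FALSE],
                        sample_ids = panel$sample_ids)
  attr(out, "haplotypes") <- attr(panel, "haplotypes")
  attr(out, "apoe_haplotypes") <- haps
  out
}

chrom_rank <- function(chrom) {
  chrom <- norm_chrom(chrom)
  n <- suppressWarnings(as.numeric(chrom))
  extra <- match(chrom, c("X", "Y", "MT", "M"))
  r <- ifelse(!is.na(n), n, 100 + extra)
  ifelse(is.na(r), 200 + as.numeric(factor(chrom)), r)
}

# e4/e2 allele doses for a simulated panel: from the haplotype attribute when
# present (ground truth), else called from the two SNP genotypes
panel_apoe_doses <- function(panel) {
  haps <- attr(panel, "apoe_haplotypes")
  if (!is.null(haps))
    return(data.frame(e4 = rowSums(haps == "e4"), e2 = rowSums(haps == "e2")))
  ids <- c("rs429358", "rs7412")
  if (!all(ids %in% panel$variants$id))
    stop("panel lacks APOE SNPs rs429358/rs7412; run attach_apoe() first")
  calls <- call_apoe_panel(panel)
  data.frame(e4 = calls$e4_dose, e2 = calls$e2_dose)
}

#' Simulate disease status under an age-dependent liability-threshold model
#'
#' Liability is the sum of (i) a polygenic term over the configured causal
#' variants (standardized dosages weighted by the causal effects, rescaled so
#' it explains `h2_poly` of the non-APOE liability variance), (ii) an APOE
#' term whose per-\eqn{\epsilon 4}-allele effect is `beta_e4_young` below the
#' age cutoff and `beta_e4_old` at or above it, plus `beta_e2` per
#' \eqn{\epsilon 2} allele, and (iii) standard-normal noise scaled to the
#' residual variance. A sample is a case iff its liability exceeds the
#' empirical `1 - prevalence` quantile of the cohort's liabilities.
#'
#' @inheritParams attach_apoe
#' @param panel a panel carrying the APOE SNPs (see [attach_apoe()]).
#' @param ages optional vector of ages; drawn from `config$age_distribution`
#'   when `NULL`.
#' @param stream integer offset separating independent phenotype draws (the
#'   discovery cohort and each parent use distinct streams).
#' @return A `sample_table` data frame: `sample_id`, `status`, `age`, `sex`,
#'   and `n_pcs` noise covariates `PC1..`; the latent liability is attached
#'   as attribute `liability`.
#' @export
simulate_phenotype <- function(panel, config, ages = NULL, stream = 0L) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  map <- sim_variant_map(config)
  set.seed(config$seed + .OFF_PHENO + 101L * as.integer(stream))
  n <- nrow(panel$dosages)
  if (is.null(ages))
    ages <- stats::rnorm(n, config$age_distribution[1], config$age_distribution[2])
  ages <- pmax(ages, 1)
  sex <- stats::rbinom(n, 1L, 0.5)
  pcs <- matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs,
                dimnames = list(NULL, paste0("PC", seq_len(max(config$n_pcs, 1)))[seq_len(config$n_pcs)]))

  poly <- numeric(n)
  if (config$h2_poly > 0 && config$n_causal > 0) {
    causal_ids <- map$variants$id[map$causal]
    idx <- match(causal_ids, panel$variants$id)
    if (anyNA(idx))
      stop("panel lacks causal variants of this configuration; ",
           "simulate_phenotype expects the unfiltered simulated panel")
    G <- panel$dosages[, idx, drop = FALSE]
    Z <- scale(G)
    Z[, attr(Z, "scaled:scale") == 0 | is.na(attr(Z, "scaled:scale"))] <- 0
    p <- as.vector(Z %*% map$beta_raw)
    s <- stats::sd(p)
    if (s > 0) poly <- p * sqrt(config$h2_poly) / s
  }
  doses <- panel_apoe_doses(panel)
  b4 <- ifelse(ages < config$age_cutoff, config$beta_e4_young, config$beta_e4_old)
  eps <- stats::rnorm(n, 0, sqrt(1 - config$h2_poly))
  liab <- poly + b4 * doses$e4 + config$beta_e2 * doses$e2 +
    config$sex_effect * sex + eps
  thr <- stats::quantile(liab, 1 - config$prevalence, names = FALSE)
  out <- data.frame(sample_id = panel$sample_ids,
                    status = as.integer(liab > thr),
                    age = ages, sex = sex, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pcs))
  class(out) <- c("sample_table", "data.frame")
  attr(out, "liability") <- liab
  out
}

# per-variant marginal logistic fits (intercept + one dosage column)
marginal_logistic <- function(G, y) {
  m <- ncol(G)
  beta <- se <- p <- numeric(m)
  for (j in seq_len(m)) {
    g <- G[, j]
    if (stats::var(g) == 0) { beta[j] <- 0; se[j] <- Inf; p[j] <- 1; next }
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, g), y, family = stats::binomial()))
    cf <- fit$coefficients[2L]
    # observed-information SE from the weighted cross-product
    X <- cbind(1, g)
    W <- fit$weights
    XtWX <- crossprod(X * sqrt(W))
    v <- tryCatch(solve(XtWX)[2L, 2L], error = function(e) NA_real_)
    beta[j] <- cf
    se[j] <- sqrt(v)
    z <- cf / se[j]
    p[j] <- max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  }
  data.frame(beta = beta, se = se, p = p)
}

#' Simulate a discovery GWAS and its summary statistics
#'
#' Draws an independent discovery cohort of `n_discovery` samples on the same
#' variant map (no sample overlap with the target cohort), simulates disease
#' status under the same liability model, and fits a marginal logistic
#' regression per variant (including the two APOE SNPs), yielding the
#' per-variant weights (`beta`), standard errors and Wald p-values a
#' polygenic score is built from.
#'
#' @inheritParams simulate_genotypes
#' @return A `sumstats` data frame: `id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `p`.
#' @export
simulate_discovery_sumstats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_discovery < 100L)
    stop("n_discovery < 100: marginal fits would be unstable")
  map <- sim_variant_map(config)
  set.seed(config$seed + .OFF_DISC)
  n <- config$n_discovery
  hapA <- sim_haplotypes(map, n)
  hapB <- sim_haplotypes(map, n)
  haps <- draw_apoe_haplotypes(n, config$apoe_freqs)
  variants <- rbind(map$variants, apoe_variant_map(config))
  dosages <- cbind(hapA + hapB, apoe_dosages(haps))
  ord <- order(chrom_rank(variants$chrom), variants$pos)
  panel <- genotype_panel(dosages[, ord, drop = FALSE],
                          variants[ord, , drop = FALSE],
                          sample_ids = sprintf("D%05d", seq_len(n)))
  attr(panel, "apoe_haplotypes") <- haps
  pheno <- simulate_phenotype(panel, config, stream = 7L)
  fits <- marginal_logistic(panel$dosages, pheno$status)
  out <- cbind(panel$variants[, c("id", "chrom", "pos",
                                  "effect_allele", "other_allele")], fits)
  rownames(out) <- NULL
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Simulate parental genotypes and proxy phenotypes
#'
#' For each target sample one haplotype is assigned as transmitted by the
#' mother and the other by the father; each parent's second haplotype is a
#' fresh population draw (block-wise, from the same copula), so parent-child
#' dosage correlation is about 0.5 per variant. Parental disease status is
#' simulated under the same liability model at parental ages; parental age at
#' death is shifted by `survival_shift_e4` years per parental
#' \eqn{\epsilon 4} allele. Parental Alzheimer's status is recorded per
#' parent and as the 0/1/2 affected-parent count.
#'
#' @inheritParams simulate_phenotype
#' @param panel the simulated target panel including APOE (with haplotype
#'   attributes, i.e. as produced by `attach_apoe(simulate_genotypes(cfg), cfg)`).
#' @return A list with elements `mother` and `father` (each a
#'   [genotype_panel()]) and `samples`, a `sample_table` with per-parent
#'   status, ages (`*_is_death` flags whether the age is an age at death),
#'   the affected-parent count, and the child's sex and noise covariates.
#' @export
simulate_parents <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  if (!isTRUE(config$proxy))
    stop("configuration error: proxy flag not set")
  haps <- attr(panel, "haplotypes")
  apoe_h <- attr(panel, "apoe_haplotypes")
  if (is.null(haps) || is.null(apoe_h))
    stop("panel missing APOE/haplotype attributes; ",
         "use attach_apoe(simulate_genotypes(config), config)")
  map <- sim_variant_map(config)
  set.seed(config$seed + .OFF_PARENT)
  n <- nrow(panel$dosages)

  build_parent <- function(transmitted_bg, transmitted_apoe, prefix) {
    new_bg <- sim_haplotypes(map, n)
    new_apoe <- sample(c("e2", "e3", "e4"), n, replace = TRUE,
                       prob = config$apoe_freqs)
    phaps <- cbind(transmitted_apoe, new_apoe)
    variants <- rbind(map$variants, apoe_variant_map(config))
    dosages <- cbind(transmitted_bg + new_bg, apoe_dosages(phaps))
    ord <- order(chrom_rank(variants$chrom), variants$pos)
    p <- genotype_panel(dosages[, ord, drop = FALSE],
                        variants[ord, , drop = FALSE],
                        sample_ids = paste0(prefix, panel$sample_ids))
    attr(p, "apoe_haplotypes") <- phaps
    p
  }
  mother <- build_parent(haps$A, apoe_h[, 1L], "M_")
  father <- build_parent(haps$B, apoe_h[, 2L], "F_")

  parent_age <- function(p) {
    e4 <- rowSums(attr(p, "apoe_haplotypes") == "e4")
    alive <- stats::rbinom(n, 1L, config$parent_alive_prob) == 1L
    age <- ifelse(alive,
                  stats::rnorm(n, config$parent_age_alive[1],
                               config$parent_age_alive[2]),
                  stats::rnorm(n, config$parent_age_death[1],
                               config$parent_age_death[2]) +
                    config$survival_shift_e4 * e4)
    list(age = pmax(age, 40), is_death = !alive)
  }
  ma <- parent_age(mother)
  fa <- parent_age(father)
  m_pheno <- simulate_phenotype(mother, config, ages = ma$age, stream = 11L)
  f_pheno <- simulate_phenotype(father, config, ages = fa$age, stream = 13L)

  sex <- stats::rbinom(n, 1L, 0.5)
  pcs <- matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs,
                dimnames = list(NULL, paste0("PC", seq_len(config$n_pcs))))
  samples <- data.frame(sample_id = panel$sample_ids,
                        maternal_status = m_pheno$status,
                        paternal_status = f_pheno$status,
                        parental_count = m_pheno$status + f_pheno$status,
                        maternal_age = ma$age, maternal_is_death = ma$is_death,
                        paternal_age = fa$age, paternal_is_death = fa$is_death,
                        sex = sex, stringsAsFactors = FALSE)
  samples <- cbind(samples, as.data.frame(pcs))
  class(samples) <- c("sample_table", "data.frame")
  list(mother = mother, father = father, samples = samples)
}
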