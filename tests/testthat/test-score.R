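mk_score_fixture <- function() {
  dos <- cbind(v1 = c(2, 0, 1), v2 = c(1, 1, 0), v3 = c(0, 2, 2))
  v <- data.frame(id = c("v1", "v2", "v3"), chrom = c("1", "1", "2"),
                  pos = c(1e3, 2e6, 5e3),
                  effect_allele = "A", other_allele = "G")
  ss <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos,
                   effect_allele = "A", other_allele = "G",
                   beta = c(0.1, -0.2, 0.3), se = 0.1, p = c(0.01, 0.2, 0.4))
  list(panel = genotype_panel(dos, v, sample_ids = c("s1", "s2", "s3")),
       ss = ss)
}

test_that("raw scores equal the hand-computed weighted allele sum", {
  fx <- mk_score_fixture()
  res <- compute_prs(fx$panel, fx$ss)
  # s1: 0.1*2 - 0.2*1 + 0.3*0 = 0; s2: 0 - 0.2 + 0.6 = 0.4; s3: 0.1 + 0.6
  expect_equal(res$scores$raw, c(0, 0.4, 0.7))
  expect_equal(res$n_variants_used, 3L)

  # orientation: v2 counted on the other allele, dose reflected, score equal
  fl <- fx
  fl$panel$variants$effect_allele[2] <- "G"
  fl$panel$variants$other_allele[2] <- "A"
  fl$panel$dosages[, 2] <- 2 - fl$panel$dosages[, 2]
  expect_equal(compute_prs(fl$panel, fl$ss)$scores$raw, c(0, 0.4, 0.7))

  # unresolvable mismatch: dropped with a warning and reported
  bad <- fx
  bad$ss$effect_allele[3] <- "C"
  bad$ss$other_allele[3] <- "T"
  expect_warning(r2 <- compute_prs(bad$panel, bad$ss), "dropped")
  expect_identical(r2$dropped, "v3")
  expect_equal(r2$scores$raw, c(0, -0.2, 0.1))
})

test_that("p-threshold, exclusion and inclusion select the scored set", {
  fx <- mk_score_fixture()
  r <- compute_prs(fx$panel, fx$ss, p_threshold = 0.1)
  expect_equal(r$n_variants_used, 1L)
  expect_equal(r$scores$raw, c(0.2, 0, 0.1))

  # excluding everything gives the empty sum
  all_of_it <- list(region_spec("1", 1, 1e9), region_spec("2", 1, 1e9))
  r0 <- compute_prs(fx$panel, fx$ss, exclude_regions = all_of_it)
  expect_equal(r0$scores$raw, c(0, 0, 0))
  expect_equal(r0$n_variants_used, 0L)

  # excluding a region with no scored variant changes nothing
  r1 <- compute_prs(fx$panel, fx$ss,
                    exclude_regions = region_spec("7", 1, 1e9))
  expect_equal(r1$scores$raw, c(0, 0.4, 0.7))

  # linearity over disjoint sets
  ra <- compute_prs(fx$panel, fx$ss, keep = c("v1", "v2"))
  rb <- compute_prs(fx$panel, fx$ss, keep = "v3")
  rall <- compute_prs(fx$panel, fx$ss)
  expect_equal(ra$scores$raw + rb$scores$raw, rall$scores$raw)
})

test_that("missing dosages follow the declared policy", {
  fx <- mk_score_fixture()
  fx$panel$dosages[1, 3] <- NA
  r_mean <- compute_prs(fx$panel, fx$ss, missing_policy = "mean")
  expect_equal(r_mean$scores$raw[1], 0.1 * 2 - 0.2 * 1 + 0.3 * 2)  # mean dose 2
  r_omit <- compute_prs(fx$panel, fx$ss, missing_policy = "omit")
  expect_equal(r_omit$scores$raw[1], (0.1 * 2 - 0.2 * 1) * 3 / 2)
})

test_that("adjustment and standardization follow the regression contract", {
  set.seed(8)
  raw <- rnorm(200, 5, 2)
  # intercept-only adjustment is plain z-scoring
  z <- adjust_standardize(raw)
  expect_equal(z$standardized, as.vector(scale(raw)), tolerance = 1e-12)

  covar <- data.frame(age = rnorm(200, 70, 8), sex = rbinom(200, 1, 0.5))
  res <- adjust_standardize(raw, covar)
  expect_lt(abs(mean(res$standardized)), 1e-10)
  expect_lt(abs(stats::sd(res$standardized) - 1), 1e-10)
  # residuals orthogonal to covariates
  expect_lt(abs(stats::cor(res$adjusted, covar$age)), 1e-10)

  # rank deficiency is an error naming the collinear column
  covar$age2 <- covar$age * 2
  expect_error(adjust_standardize(raw, covar), "age2")

  # a score that is an exact function of a covariate is flagged
  expect_warning(
    flat <- adjust_standardize(3 * covar$age[1:200],
                               data.frame(age = covar$age[1:200])),
    "tolerance")
  expect_true(all(is.na(flat$standardized)))
  expect_lt(max(abs(flat$adjusted)), 1e-8)
})

test_that("gene sets resolve to intervals with unions and unresolved reports", {
  bed <- data.frame(chrom = c("1", "1", "2", "chr2"),
                    start = c(100, 500, 300, 900), end = c(200, 600, 400, 950),
                    gene = c("G1", "G1", "G2", "G3"))
  gs <- resolve_gene_set(c("G1", "G3", "GX"), bed, name = "demo")
  expect_equal(nrow(gs$intervals), 3)   # union of the two G1 rows + G3
  expect_identical(gs$unresolved, "GX")
  expect_true(all(gs$intervals$chrom %in% c("1", "2")))  # chr prefix stripped
  expect_error(resolve_gene_set("GX", bed), "no gene")
})

test_that("pathway membership uses 1-based inclusive gene bounds", {
  dos <- matrix(rbinom(40 * 5, 2, 0.4), 40, 5)
  v <- data.frame(id = paste0("v", 1:5), chrom = "1",
                  pos = c(99, 100, 150, 200, 201),
                  effect_allele = "A", other_allele = "G")
  panel <- genotype_panel(dos, v)
  gs <- resolve_gene_set("G1", data.frame(chrom = "1", start = 100, end = 200,
                                          gene = "G1"))
  expect_identical(pathway_variants(gs, panel), c("v2", "v3", "v4"))
})

test_that("pathway scores respect APOE handling and reduce to the global PRS", {
  cfg <- sim_config(seed = 16, n_variants = 20, n_blocks = 4, n_causal = 6,
                    n_target = 300)
  panel <- attach_apoe(simulate_genotypes(cfg), cfg)
  ss <- simulate_discovery_sumstats(cfg)
  # a pathway spanning the APOE region but not APOE itself: with region
  # exclusion off, its APOE-region member variants are scored
  gs_apoe <- resolve_gene_set("RELBlike",
                              data.frame(chrom = "19", start = 44.0e6,
                                         end = 46.6e6, gene = "RELBlike"))
  r_in <- pathway_prs(panel, ss, gs_apoe, exclude_apoe = FALSE, p_threshold = 1)
  expect_gte(r_in$n_variants_used, 2L)   # at least the two APOE SNPs
  r_out <- pathway_prs(panel, ss, gs_apoe, exclude_apoe = TRUE, p_threshold = 1)
  expect_equal(r_out$n_variants_used,
               r_in$n_variants_used - sum(in_region <- with(panel$variants,
                 chrom == "19" & pos >= 44.4e6 & pos <= 46.5e6)))

  # include_regions spanning the whole genome equals the global PRS
  whole <- lapply(unique(panel$variants$chrom), function(ch)
    region_spec(ch, 1, 1e9))
  gs_all <- structure(list(name = "all", genes = "all",
                           intervals = do.call(rbind, lapply(whole, function(r)
                             data.frame(chrom = r$chrom, start = r$start_bp,
                                        end = r$end_bp, gene = "all"))),
                      unresolved = character(0)), class = "gene_set")
  r_path <- pathway_prs(panel, ss, gs_all, p_threshold = 0.5)
  r_glob <- compute_prs(panel, ss, p_threshold = 0.5)
  expect_equal(r_path$scores$raw, r_glob$scores$raw)
})
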