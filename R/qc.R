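#' Variant QC configuration
#'
#' Threshold set for variant-level quality control. The `"array"` profile
#' uses hard-called genotype thresholds (MAF < 0.01 removed, missingness
#' > 0.02 removed, HWE exact p <= 1e-6 removed); the `"imputed"` profile
#' relaxes missingness to 0.05 and additionally removes variants with
#' imputation INFO <= 0.4 and converts dosages to hard calls, setting
#' genotypes whose implied posterior is <= 0.4 to missing. Comparison senses
#' (strict vs non-strict) are part of the contract: MAF and missingness are
#' strict inequalities, HWE and INFO are non-strict.
#'
#' @param profile `"array"` or `"imputed"`.
#' @param maf_min minimum minor-allele frequency (exclusive).
#' @param missing_max maximum missing fraction (exclusive).
#' @param hwe_p_min HWE exact-test p at or below which a variant is removed.
#' @param info_min INFO score at or below which a variant is removed
#'   (`NA` disables; default only active for the imputed profile).
#' @param hardcall_posterior_min genotype posterior at or below which a hard
#'   call is set missing (imputed profile only).
#' @param hwe_controls_only compute the HWE test in controls only (requires a
#'   status vector at [qc_metrics()] time). Default: all samples.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(profile = c("array", "imputed"),
                      maf_min = 0.01,
                      missing_max = NULL,
                      hwe_p_min = 1e-6,
                      info_min = NULL,
                      hardcall_posterior_min = NULL,
                      hwe_controls_only = FALSE) {
  profile <- match.arg(profile)
  if (is.null(missing_max)) missing_max <- if (profile == "array") 0.02 else 0.05
  if (is.null(info_min)) info_min <- if (profile == "imputed") 0.4 else NA_real_
  if (is.null(hardcall_posterior_min))
    hardcall_posterior_min <- if (profile == "imputed") 0.4 else NA_real_
  stopifnot(maf_min >= 0, maf_min <= 0.5, missing_max >= 0, missing_max <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1)
  structure(list(profile = profile, maf_min = maf_min,
                 missing_max = missing_max, hwe_p_min = hwe_p_min,
                 info_min = info_min,
                 hardcall_posterior_min = hardcall_posterior_min,
                 hwe_controls_only = isTRUE(hwe_controls_only)),
            class = "qc_config")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test: conditional on the observed allele counts, the
#' probability of every heterozygote count with probability at most that of
#' the observed count is summed, under the exact distribution of heterozygote
#' counts given allele counts in a diploid sample. Monomorphic tables return
#' p = 1. Probabilities are computed by the standard recurrence from the
#' modal heterozygote count, in floating point with renormalization.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, summing to at least 1).
#' @return The exact two-sided p-value.
#' @examples
#' hwe_exact_test(68, 28, 4)
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (length(n_AA) > 1L || length(n_Aa) > 1L || length(n_aa) > 1L)
    return(mapply(hwe_exact_test, n_AA, n_Aa, n_aa))
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype counts")
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) stop("empty genotype table")
  m <- 2L * n_aa + n_Aa                     # count of the 'a' allele
  if (m > n) m <- 2L * n - m                # fold to the minor allele
  if (m == 0L) return(1)
  dist <- hwe_het_distribution(n, m)
  obs <- dist$p[match(n_Aa, dist$het)]
  # relative tolerance guards against ties lost to rounding
  min(1, sum(dist$p[dist$p <= obs * (1 + 1e-12)]))
}

# exact distribution of heterozygote counts given n diploids and m copies of
# the minor allele, via the ratio recurrence anchored at the modal count
hwe_het_distribution <- function(n, m) {
  hets <- seq.int(m %% 2L, min(m, 2L * n - m), by = 2L)
  k <- length(hets)
  p <- numeric(k)
  mode_i <- which.max(
    -lgamma((m - hets) / 2 + 1) - lgamma(n - (m + hets) / 2 + 1) -
      lgamma(hets + 1) + hets * log(2))
  p[mode_i] <- 1
  # P(h+2)/P(h) = 4 * n_hom_a * n_hom_A / ((h+2)(h+1)) with
  # n_hom_a = (m-h)/2, n_hom_A = n - (m+h)/2 at heterozygote count h
  if (mode_i < k) for (i in (mode_i + 1L):k) {
    h <- hets[i - 1L]
    p[i] <- p[i - 1L] * 4 * ((m - h) / 2) * (n - (m + h) / 2) /
      ((h + 2) * (h + 1))
  }
  if (mode_i > 1L) for (i in (mode_i - 1L):1L) {
    h <- hets[i]
    p[i] <- p[i + 1L] * ((h + 2) * (h + 1)) /
      (4 * ((m - h) / 2) * (n - (m + h) / 2))
  }
  list(het = hets, p = p / sum(p))
}

# dosage -> hard call with posterior rule: the implied max genotype posterior
# for dosage d is max(frac, 1-frac) where frac = d - floor(d); a call is made
# only if that posterior exceeds the threshold (a no-op for integer dosages)
hard_calls <- function(dosages, posterior_min = NA_real_) {
  hc <- round(dosages)
  if (!is.na(posterior_min)) {
    post <- 1 - abs(dosages - hc)
    hc[!is.na(post) & post <= posterior_min] <- NA_real_
  }
  hc
}

#' Per-variant QC metrics
#'
#' Computes, per variant: minor-allele frequency from non-missing hard calls,
#' missingness fraction, exact HWE p-value and the pass-through INFO score.
#' Variants with all genotypes missing get `NA` MAF and are flagged.
#'
#' @param panel a [genotype_panel()].
#' @param config a [qc_config()]; governs the hard-call rule and whether HWE
#'   is computed in controls only.
#' @param status optional 0/1 case status aligned to samples, used when
#'   `config$hwe_controls_only` is set.
#' @return A data frame with columns `variant_id`, `maf`, `missingness`,
#'   `hwe_p`, `info`, `all_missing`.
#' @export
qc_metrics <- function(panel, config = qc_config(), status = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  hc <- hard_calls(panel$dosages, config$hardcall_posterior_min)
  nmiss <- colSums(is.na(hc))
  n_used <- nrow(hc) - nmiss
  af <- colSums(hc, na.rm = TRUE) / (2 * pmax(n_used, 1L))
  maf <- pmin(af, 1 - af)
  maf[n_used == 0L] <- NA_real_
  hwe_hc <- hc
  if (config$hwe_controls_only) {
    if (is.null(status)) stop("hwe_controls_only requires a status vector")
    hwe_hc <- hc[status == 0L, , drop = FALSE]
  }
  hwe_p <- vapply(seq_len(ncol(hwe_hc)), function(j) {
    g <- hwe_hc[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  data.frame(variant_id = panel$variants$id, maf = maf,
             missingness = nmiss / nrow(hc), hwe_p = hwe_p,
             info = panel$variants$info, all_missing = n_used == 0L,
             stringsAsFactors = FALSE)
}

#' Apply variant QC filters
#'
#' Removes variants failing any threshold of `config` and reports per-filter
#' attrition. A variant failing several filters is counted under each of them;
#' the `unique_removed` attribute (and the report's last row) gives the
#' deduplicated total, so per-filter counts sum to at least that number.
#' Filter senses: `maf < maf_min`, `missingness > missing_max`,
#' `hwe_p <= hwe_p_min`, `info <= info_min` (imputed profile); all-missing
#' variants are always removed.
#'
#' @param panel a [genotype_panel()].
#' @param metrics output of [qc_metrics()] aligned to the panel.
#' @param config a [qc_config()].
#' @return A list with `panel` (filtered; hard-call conversion applied for
#'   the imputed profile) and `report` (data frame: `filter`, `threshold`,
#'   `n_failed`).
#' @export
qc_filter <- function(panel, metrics, config = qc_config()) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!identical(metrics$variant_id, panel$variants$id))
    stop("metrics are not aligned to the panel's variants")
  fails <- list(
    maf = !is.na(metrics$maf) & metrics$maf < config$maf_min,
    missingness = metrics$missingness > config$missing_max,
    hwe = !is.na(metrics$hwe_p) & metrics$hwe_p <= config$hwe_p_min,
    info = if (is.na(config$info_min)) rep(FALSE, nrow(metrics))
           else metrics$info <= config$info_min,
    all_missing = metrics$all_missing)
  thresholds <- c(maf = config$maf_min, missingness = config$missing_max,
                  hwe = config$hwe_p_min, info = config$info_min,
                  all_missing = NA_real_)
  removed <- Reduce(`|`, fails)
  report <- data.frame(filter = c(names(fails), "unique_removed"),
                       threshold = c(unname(thresholds), NA_real_),
                       n_failed = c(vapply(fails, sum, integer(1)),
                                    sum(removed)),
                       stringsAsFactors = FALSE)
  out <- subset_variants(panel, panel$variants$id[!removed])
  if (config$profile == "imputed")
    out$dosages <- hard_calls(out$dosages, config$hardcall_posterior_min)
  list(panel = out, report = report)
}
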