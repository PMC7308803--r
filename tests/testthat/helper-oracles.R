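# Independent oracles used across the suite. These deliberately take the
# slow, direct route (closed forms, exhaustive enumeration, O(n^2) scans) and
# share no code with the implementation paths they check.

# Exact HWE p-value by brute-force enumeration: closed-form log-factorial
# probability of every heterozygote count compatible with the allele counts.
hwe_oracle_dist <- function(n, m) {
  hets <- seq(m %% 2, min(m, 2 * n - m), by = 2)
  logp <- vapply(hets, function(h) {
    hom_min <- (m - h) / 2
    hom_maj <- n - h - hom_min
    lfactorial(n) - lfactorial(h) - lfactorial(hom_min) -
      lfactorial(hom_maj) + h * log(2) +
      lfactorial(m) + lfactorial(2 * n - m) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  list(het = hets, p = p / sum(p))
}

hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  m <- 2 * n_aa + n_Aa
  if (m > n) m <- 2 * n - m
  if (m == 0) return(1)
  d <- hwe_oracle_dist(n, m)
  obs <- d$p[match(n_Aa, d$het)]
  min(1, sum(d$p[d$p <= obs * (1 + 1e-12)]))
}

# Greedy-by-p pruning checked directly against its definition: visit variants
# in (p, chrom, pos, id) order, keep unless squared correlation with any kept
# variant on the same chromosome within the window exceeds the threshold.
prune_oracle <- function(dosages, variants, p, r2_max, window_bp) {
  ord <- order(p, variants$chrom, variants$pos, variants$id)
  kept <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (k in kept) {
      if (variants$chrom[k] == variants$chrom[i] &&
          abs(variants$pos[k] - variants$pos[i]) <= window_bp &&
          stats::cor(dosages[, i], dosages[, k])^2 > r2_max) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) kept <- c(kept, i)
  }
  sort(variants$id[sort(kept)])
}

# O(n^2) AUC: mean over all case-control pairs of 1{case > control} with
# half-credit for ties.
auc_oracle <- function(score, outcome) {
  y <- as.integer(outcome >= 1)
  s1 <- score[y == 1]
  s0 <- score[y == 0]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}

# Small random panel with planted LD for pruning tests: duplicated/perturbed
# columns create high-r2 pairs, the rest are independent.
random_ld_panel <- function(m, n = 300) {
  dos <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)[rep(seq_len(m), each = n)]),
                n, m)
  ndup <- sample(0:(m %/% 3), 1)
  if (ndup > 0 && m >= 4) {
    for (k in seq_len(ndup)) {
      pair <- sample(seq_len(m), 2)
      dos[, pair[2]] <- pmin(pmax(dos[, pair[1]] + rbinom(n, 1, 0.05) -
                                    rbinom(n, 1, 0.05), 0), 2)
    }
  }
  chrom <- sort(sample(1:2, m, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample(seq(1e5, 3e6, by = 1e3), length(ix)))))
  variants <- data.frame(id = sprintf("v%03d", seq_len(m)),
                         chrom = as.character(chrom), pos = as.numeric(pos),
                         effect_allele = "A", other_allele = "G",
                         stringsAsFactors = FALSE)
  # guard against monomorphic columns (pruning assumes post-QC input)
  for (j in seq_len(m)) if (var(dos[, j]) == 0) dos[1, j] <- 1
  list(panel = genotype_panel(dos, variants),
       sumstats = data.frame(id = variants$id, chrom = variants$chrom,
                             pos = variants$pos, effect_allele = "A",
                             other_allele = "G", beta = rnorm(m), se = 0.1,
                             p = runif(m), stringsAsFactors = FALSE))
}

# small helper: simulated cohort ready for association fits
sim_cohort_fixture <- function(seed = 7, n_target = 2000, n_discovery = 800,
                               ...) {
  cfg <- sim_config(seed = seed, n_variants = 40, n_blocks = 5,
                    n_target = n_target, n_discovery = n_discovery,
                    n_causal = 15, ...)
  panel <- attach_apoe(simulate_genotypes(cfg), cfg)
  list(cfg = cfg, panel = panel,
       pheno = simulate_phenotype(panel, cfg),
       apoe = call_apoe_panel(panel))
}
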