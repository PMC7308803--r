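#' Squared genotype correlation between two variants
#'
#' Squared Pearson correlation of the two dosage vectors over jointly
#' non-missing samples. Zero-variance columns (monomorphic in the joint
#' sample) are treated as uncorrelated, with a warning: such variants should
#' not survive QC.
#'
#' @param panel a [genotype_panel()].
#' @param i,j variant indices or ids.
#' @return r-squared in `[0, 1]`.
#' @export
genotype_r2 <- function(panel, i, j) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.character(i)) i <- match(i, panel$variants$id)
  if (is.character(j)) j <- match(j, panel$variants$id)
  x <- panel$dosages[, i]
  y <- panel$dosages[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) stop("fewer than 2 jointly non-missing samples")
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero-variance dosage column; r^2 treated as 0 ",
            "(monomorphic variants should not survive QC)")
    return(0)
  }
  stats::cor(x, y)^2
}

#' Greedy LD pruning by discovery p-value (clumping)
#'
#' Reduces the panel to an approximately independent variant subset: variants
#' are visited in order of ascending discovery p-value (ties broken by
#' chromosome, position, id) and a variant is retained iff its r-squared with
#' every already-retained variant on the same chromosome within `window_bp`
#' base pairs is at most `r2_max` — so each LD neighbourhood keeps its most
#' significant variant. Variants absent from the summary statistics are
#' dropped before pruning. The window is the symmetric physical distance
#' `|pos_i - pos_j| <= window_bp`.
#'
#' @param panel a [genotype_panel()] supplying the genotypes r-squared is
#'   estimated on (the target panel or a reference subsample, see `ref_n`).
#' @param sumstats a `sumstats` data frame (see [read_sumstats()]).
#' @param r2_max r-squared threshold above which a variant is excluded
#'   (default 0.1).
#' @param window_bp physical window in base pairs (default 1e6, i.e. 1000 kb).
#' @param ref_n optional size of a seeded random reference subsample of the
#'   panel used for r-squared estimation (e.g. 1000 individuals); `NULL`
#'   uses all samples.
#' @param seed seed for the reference subsample draw.
#' @return Character vector of retained variant ids, in genomic order.
#' @export
ld_prune <- function(panel, sumstats, r2_max = 0.1, window_bp = 1e6,
                     ref_n = NULL, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"), r2_max > 0, r2_max <= 1,
            window_bp > 0)
  keep_ids <- intersect(panel$variants$id, sumstats$id)
  if (!length(keep_ids))
    stop("no variant is shared between the panel and the summary statistics")
  panel <- subset_variants(panel, keep_ids)
  if (!is.null(ref_n) && ref_n < nrow(panel$dosages)) {
    set.seed(seed)
    rows <- sort(sample.int(nrow(panel$dosages), ref_n))
    panel$dosages <- panel$dosages[rows, , drop = FALSE]
  }
  v <- panel$variants
  p <- sumstats$p[match(v$id, sumstats$id)]
  ord <- order(p, chrom_rank(v$chrom), v$pos, v$id)
  kept <- integer(0)
  for (cand in ord) {
    near <- kept[v$chrom[kept] == v$chrom[cand] &
                   abs(v$pos[kept] - v$pos[cand]) <= window_bp]
    ok <- TRUE
    for (k in near) {
      if (suppressWarnings(genotype_r2(panel, cand, k)) > r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, cand)
  }
  kept <- kept[order(chrom_rank(v$chrom[kept]), v$pos[kept])]
  v$id[kept]
}
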