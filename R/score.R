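#' Genomic region specification
#'
#' @param chrom chromosome label (a leading `"chr"` is stripped).
#' @param start_bp,end_bp 1-based inclusive bounds.
#' @return A list of class `region_spec`.
#' @export
region_spec <- function(chrom, start_bp, end_bp) {
  if (start_bp > end_bp) stop("region start exceeds end")
  structure(list(chrom = norm_chrom(chrom), start_bp = start_bp,
                 end_bp = end_bp), class = "region_spec")
}

#' The APOE region used for PRS exclusion
#'
#' Chromosome 19, 44.4-46.5 Mb (coordinates as conventionally quoted for this
#' analysis; the genome build is whatever the variant positions are in).
#'
#' @return A [region_spec()].
#' @export
apoe_region <- function() region_spec("19", 44.4e6, 46.5e6)

in_regions <- function(variants, regions) {
  if (is.null(regions)) return(rep(FALSE, nrow(variants)))
  if (inherits(regions, "region_spec")) regions <- list(regions)
  hit <- rep(FALSE, nrow(variants))
  ch <- norm_chrom(variants$chrom)
  for (r in regions)
    hit <- hit | (ch == r$chrom & variants$pos >= r$start_bp &
                    variants$pos <= r$end_bp)
  hit
}

#' Compute raw polygenic scores
#'
#' The score of sample s is the weighted sum over scored variants j of
#' `beta_j * dose_s(effect allele j)`, where the scored set is: variants in
#' `keep` (if given) with discovery `p <= p_threshold`, outside every
#' `exclude_regions` region and (if `include_regions` is given) inside at
#' least one of them. Allele orientation is reconciled per variant: when the
#' panel counts the summary statistics' other allele the dose is reflected
#' (`2 - dose`); variants whose alleles match neither way are dropped with a
#' warning and listed in the `dropped` element. Missing dosages follow
#' `missing_policy`: `"mean"` substitutes the cohort mean dose of the
#' variant, `"omit"` drops the variant for that sample and rescales the
#' sample's score by the ratio of total to observed variant count.
#'
#' @param panel a [genotype_panel()].
#' @param sumstats a `sumstats` data frame.
#' @param keep optional character vector of variant ids (e.g. from
#'   [ld_prune()]); defaults to all panel variants.
#' @param p_threshold discovery p-value threshold `p_T` (default 0.5).
#' @param exclude_regions a [region_spec()] or list of them (e.g.
#'   `apoe_region()`); `NULL` for none.
#' @param include_regions optional restriction to a [region_spec()] list —
#'   used for pathway scores.
#' @param missing_policy `"mean"` or `"omit"`.
#' @return A list of class `prs_raw`: `scores` (data frame `sample_id`,
#'   `raw`), `n_variants_used`, `dropped` (ids), and the configuration echo.
#' @export
compute_prs <- function(panel, sumstats, keep = NULL, p_threshold = 0.5,
                        exclude_regions = NULL, include_regions = NULL,
                        missing_policy = c("mean", "omit")) {
  stopifnot(inherits(panel, "genotype_panel"))
  missing_policy <- match.arg(missing_policy)
  if (p_threshold <= 0 || p_threshold > 1) stop("p_threshold must be in (0, 1]")
  if (is.null(keep)) keep <- panel$variants$id
  bad_keep <- setdiff(keep, intersect(panel$variants$id, sumstats$id))
  if (length(bad_keep))
    stop("keep list contains variants absent from panel or sumstats: ",
         paste(utils::head(bad_keep, 5), collapse = ", "))
  v <- panel$variants
  ss <- sumstats[match(v$id, sumstats$id), ]
  sel <- v$id %in% keep & !is.na(ss$p) & ss$p <= p_threshold &
    !in_regions(v, exclude_regions)
  if (!is.null(include_regions)) sel <- sel & in_regions(v, include_regions)

  idx <- which(sel)
  dropped <- character(0)
  w <- numeric(length(idx))
  D <- panel$dosages[, idx, drop = FALSE]
  for (k in seq_along(idx)) {
    j <- idx[k]
    if (v$effect_allele[j] == ss$effect_allele[j] &&
        v$other_allele[j] == ss$other_allele[j]) {
      w[k] <- ss$beta[j]
    } else if (v$effect_allele[j] == ss$other_allele[j] &&
               v$other_allele[j] == ss$effect_allele[j]) {
      w[k] <- ss$beta[j]
      D[, k] <- 2 - D[, k]                 # panel counts the other allele
    } else {
      w[k] <- NA_real_
      dropped <- c(dropped, v$id[j])
    }
  }
  if (length(dropped)) {
    warning(length(dropped), " variant(s) dropped: alleles match neither ",
            "orientation")
    D <- D[, !is.na(w), drop = FALSE]
    w <- w[!is.na(w)]
  }
  n_used <- ncol(D)
  if (n_used == 0L) {
    raw <- rep(0, nrow(panel$dosages))
  } else if (missing_policy == "mean") {
    for (k in seq_len(ncol(D))) {
      nas <- is.na(D[, k])
      if (any(nas)) D[nas, k] <- mean(D[, k], na.rm = TRUE)
    }
    raw <- as.vector(D %*% w)
  } else {
    obs <- !is.na(D)
    D0 <- D
    D0[!obs] <- 0
    raw <- as.vector(D0 %*% w)
    n_obs <- rowSums(obs)
    raw <- ifelse(n_obs > 0, raw * n_used / n_obs, 0)
  }
  structure(list(scores = data.frame(sample_id = panel$sample_ids, raw = raw,
                                     stringsAsFactors = FALSE),
                 n_variants_used = n_used, dropped = dropped,
                 p_threshold = p_threshold,
                 exclude_regions = exclude_regions,
                 include_regions = include_regions,
                 missing_policy = missing_policy),
            class = "prs_raw")
}

#' @export
print.prs_raw <- function(x, ...) {
  cat("prs_raw: ", nrow(x$scores), " samples, ", x$n_variants_used,
      " variants (p_T <= ", x$p_threshold, ")\n", sep = "")
  if (length(x$dropped))
    cat("  dropped (allele mismatch): ", length(x$dropped), "\n", sep = "")
  invisible(x)
}

#' Covariate-adjust and standardize polygenic scores
#'
#' Regresses the raw score on the covariates (ordinary least squares with
#' intercept) and standardizes the residuals to mean 0, SD 1 over the cohort
#' — the usual preparation of a score for association models.
#'
#' @param prs a `prs_raw` object from [compute_prs()], or a numeric vector of
#'   raw scores.
#' @param covariates a data frame of numeric covariates aligned to the
#'   samples (e.g. age, sex, principal components); `NULL` for
#'   intercept-only adjustment (plain z-scoring).
#' @param sd_tol residual SD below which standardization is flagged: the
#'   standardized score is returned as `NA` with a warning.
#' @return A data frame of class `score_result`: `sample_id`, `raw`,
#'   `adjusted`, `standardized`; `n_variants_used` kept as an attribute.
#' @export
adjust_standardize <- function(prs, covariates = NULL, sd_tol = 1e-12) {
  if (inherits(prs, "prs_raw")) {
    raw <- prs$scores$raw
    ids <- prs$scores$sample_id
    nvar <- prs$n_variants_used
  } else {
    raw <- as.numeric(prs)
    ids <- names(prs)
    if (is.null(ids)) ids <- sprintf("S%d", seq_along(raw))
    nvar <- NA_integer_
  }
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    adjusted <- raw - mean(raw)
  } else {
    X <- as.data.frame(covariates)
    num <- vapply(X, is.numeric, logical(1))
    if (!all(num)) stop("non-numeric covariate column(s): ",
                        paste(names(X)[!num], collapse = ", "))
    Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
    qrx <- qr(Xm)
    if (qrx$rank < ncol(Xm)) {
      aliased <- colnames(Xm)[qrx$pivot[(qrx$rank + 1L):ncol(Xm)]]
      stop("covariate matrix is rank deficient; collinear column(s): ",
           paste(aliased, collapse = ", "))
    }
    adjusted <- as.vector(qr.resid(qrx, raw))
  }
  s <- stats::sd(adjusted)
  if (is.na(s) || s < sd_tol) {
    warning("residual SD below tolerance (", format(s), "); ",
            "standardized score set to NA")
    std <- rep(NA_real_, length(adjusted))
  } else {
    std <- (adjusted - mean(adjusted)) / s
  }
  out <- data.frame(sample_id = ids, raw = raw, adjusted = adjusted,
                    standardized = std, stringsAsFactors = FALSE)
  attr(out, "n_variants_used") <- nvar
  class(out) <- c("score_result", "data.frame")
  out
}

#' Resolve a gene list against gene intervals
#'
#' Looks the genes up in a gene-interval table (e.g. from [read_bed()]);
#' duplicate rows for a gene contribute the union of their intervals; absent
#' genes are reported, not silently dropped.
#'
#' @param genes character vector of gene identifiers.
#' @param intervals data frame with columns `chrom`, `start`, `end`, `gene`
#'   (1-based inclusive coordinates, as returned by [read_bed()]).
#' @param name gene-set name.
#' @return A list of class `gene_set`: `name`, `genes`, `intervals`
#'   (resolved rows), `unresolved` (genes absent from the interval table).
#' @export
resolve_gene_set <- function(genes, intervals, name = "gene_set") {
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(intervals)))
  hit <- intervals[intervals$gene %in% genes, , drop = FALSE]
  unresolved <- setdiff(genes, hit$gene)
  if (!nrow(hit))
    stop("no gene of the set resolves against the interval table")
  hit <- unique(hit[, c("chrom", "start", "end", "gene")])
  hit$chrom <- norm_chrom(hit$chrom)
  rownames(hit) <- NULL
  structure(list(name = name, genes = genes, intervals = hit,
                 unresolved = unresolved), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$genes), " genes, ",
      nrow(x$intervals), " intervals", sep = "")
  if (length(x$unresolved))
    cat(" (", length(x$unresolved), " unresolved)", sep = "")
  cat("\n")
  invisible(x)
}

gene_set_regions <- function(gene_set)
  lapply(seq_len(nrow(gene_set$intervals)), function(i)
    region_spec(gene_set$intervals$chrom[i], gene_set$intervals$start[i],
                gene_set$intervals$end[i]))

#' Variants inside a gene set's intervals
#'
#' A variant belongs to the pathway iff `start <= pos <= end` (1-based,
#' inclusive both ends) for at least one resolved gene interval.
#'
#' @param gene_set a [resolve_gene_set()] result.
#' @param panel a [genotype_panel()].
#' @return Character vector of member variant ids.
#' @export
pathway_variants <- function(gene_set, panel) {
  stopifnot(inherits(gene_set, "gene_set"), inherits(panel, "genotype_panel"))
  panel$variants$id[in_regions(panel$variants, gene_set_regions(gene_set))]
}

#' Pathway-restricted polygenic score
#'
#' [compute_prs()] restricted to the gene set's intervals. Exclusion of the
#' APOE region is optional (`exclude_apoe`): pathway scores are routinely run
#' both with and without it, since a pathway may contain APOE-region genes
#' without containing APOE itself.
#'
#' @inheritParams compute_prs
#' @param gene_set a [resolve_gene_set()] result.
#' @param exclude_apoe drop variants in [apoe_region()]?
#' @return As [compute_prs()].
#' @export
pathway_prs <- function(panel, sumstats, gene_set, keep = NULL,
                        p_threshold = 0.5, exclude_apoe = FALSE,
                        missing_policy = "mean") {
  compute_prs(panel, sumstats, keep = keep, p_threshold = p_threshold,
              exclude_regions = if (exclude_apoe) apoe_region(),
              include_regions = gene_set_regions(gene_set),
              missing_policy = missing_policy)
}
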