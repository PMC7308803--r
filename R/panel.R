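#' Genotype panel container
#'
#' A `genotype_panel` holds a samples-by-variants dosage matrix together with
#' its variant map. Dosages count copies of the variant's effect allele and
#' lie in `[0, 2]`; missing genotypes are `NA`. The variant map records, per
#' variant: `id`, `chrom`, `pos` (1-based), `effect_allele`, `other_allele`,
#' and `info` (imputation quality in `[0, 1]`; 1 for simulated or hard-called
#' data).
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#' @param variants data.frame with columns `id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele` and optionally `info`.
#' @param sample_ids character vector of sample identifiers; defaults to the
#'   rownames of `dosages` or `S1..Sn`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, variants, sample_ids = NULL) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "effect_allele", "other_allele")
  miss <- setdiff(req, names(variants))
  if (length(miss))
    stop("variant map lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(variants$info)) variants$info <- 1
  variants$chrom <- norm_chrom(variants$chrom)
  if (anyDuplicated(variants$id))
    stop("duplicate variant ids: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  if (ncol(dosages) != nrow(variants))
    stop("dosage matrix has ", ncol(dosages), " columns but variant map has ",
         nrow(variants), " rows")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(nrow(dosages)))
  }
  dimnames(dosages) <- list(sample_ids, variants$id)
  bad <- !is.na(dosages) & (dosages < 0 | dosages > 2)
  if (any(bad)) stop("dosages outside [0, 2]")
  # positions must be strictly increasing within each chromosome
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  if (any(variants$effect_allele == variants$other_allele))
    stop("effect and other allele identical for some variant")
  structure(list(dosages = dosages, variants = variants,
                 sample_ids = sample_ids),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel: ", length(x$sample_ids), " samples x ",
      nrow(x$variants), " variants\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$variants$chrom), collapse = ", "),
      "\n", sep = "")
  nmiss <- sum(is.na(x$dosages))
  cat("  missing genotypes: ", nmiss, " (",
      format(100 * nmiss / length(x$dosages), digits = 3), "%)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Subset a panel by variant id
#'
#' @param panel a `genotype_panel`.
#' @param ids variant ids to keep, in panel order.
#' @return A `genotype_panel` restricted to `ids`.
#' @export
subset_variants <- function(panel, ids) {
  stopifnot(inherits(panel, "genotype_panel"))
  keep <- panel$variants$id %in% ids
  out <- panel
  out$dosages <- panel$dosages[, keep, drop = FALSE]
  out$variants <- panel$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  h <- attr(panel, "haplotypes")
  if (!is.null(h))   # haplotype matrices are keyed by variant id
    attr(out, "haplotypes") <-
      lapply(h, function(m) m[, intersect(colnames(m), out$variants$id),
                              drop = FALSE])
  attr(out, "apoe_haplotypes") <- attr(panel, "apoe_haplotypes")
  out
}

#' Missingness mask of a panel
#'
#' @param panel a `genotype_panel`.
#' @return Logical matrix, `TRUE` where the genotype is missing.
#' @export
missing_mask <- function(panel) is.na(panel$dosages)

# strip a leading "chr" so that "chr19" and "19" compare equal
norm_chrom <- function(x) sub("^chr", "", as.character(x))
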