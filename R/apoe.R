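# APOE epsilon haplotypes on (rs429358, rs7412):
#   e2 = (T, T); e3 = (T, C); e4 = (C, C)
# The rare e1 = (C, T) haplotype is not modelled; genotype combinations that
# require it are returned as diplotype "ambiguous" with NA doses.

#' Call APOE diplotypes from the two defining SNPs
#'
#' Maps unphased rs429358 (T/C) and rs7412 (C/T) genotypes to the
#' \eqn{\epsilon 2/\epsilon 3/\epsilon 4} diplotype and the per-sample
#' \eqn{\epsilon 2} and \eqn{\epsilon 4} allele doses. Six of the nine
#' genotype combinations resolve uniquely. The double heterozygote
#' (rs429358 C/T, rs7412 C/T) is returned as \eqn{\epsilon 2 \epsilon 4}
#' with `ambiguous = TRUE`: the alternative \eqn{\epsilon 1 \epsilon 3}
#' phase is vanishingly rare. The remaining three combinations are possible
#' only with an \eqn{\epsilon 1} haplotype and are returned as diplotype
#' `"ambiguous"` with `NA` doses. Missing genotypes give a missing call.
#'
#' @param g_rs429358 character vector of unphased genotypes at rs429358,
#'   e.g. `"TT"`, `"CT"`, `"CC"` (allele order irrelevant).
#' @param g_rs7412 character vector of unphased genotypes at rs7412.
#' @return A data frame: `diplotype` (one of `e2e2, e2e3, e2e4, e3e3, e3e4,
#'   e4e4, ambiguous`), `e2_dose`, `e4_dose`, `ambiguous` flag.
#' @examples
#' call_apoe(c("TT", "CT", "CC"), c("CC", "CT", "CC"))
#' @export
call_apoe <- function(g_rs429358, g_rs7412) {
  n <- length(g_rs429358)
  if (length(g_rs7412) != n) stop("genotype vectors differ in length")
  c4 <- genotype_allele_count(g_rs429358, "C", c("T", "C"), "rs429358")
  c2 <- genotype_allele_count(g_rs7412, "T", c("C", "T"), "rs7412")
  call_apoe_counts(c4, c2)
}

# count copies of `allele` in a 2-character unphased genotype string,
# validating against the expected allele pair
genotype_allele_count <- function(g, allele, expected, variant) {
  g <- toupper(gsub("[/|]", "", as.character(g)))
  out <- rep(NA_integer_, length(g))
  ok <- !is.na(g) & !g %in% c("", "..", "NN", "00")
  if (any(ok)) {
    a1 <- substr(g[ok], 1L, 1L)
    a2 <- substr(g[ok], 2L, 2L)
    bad <- !(a1 %in% expected) | !(a2 %in% expected) | nchar(g[ok]) != 2L
    if (any(bad))
      stop("unexpected allele(s) at ", variant, ": ",
           paste(unique(g[ok][bad]), collapse = ", "),
           " (expected alleles ", paste(expected, collapse = "/"), ")")
    out[ok] <- (a1 == allele) + (a2 == allele)
  }
  out
}

# diplotype from (count of C at rs429358, count of T at rs7412)
call_apoe_counts <- function(c4, c2) {
  key <- paste(c4, c2)
  tab <- c("0 0" = "e3e3", "0 1" = "e2e3", "0 2" = "e2e2",
           "1 0" = "e3e4", "2 0" = "e4e4", "1 1" = "e2e4",
           "2 1" = "ambiguous", "1 2" = "ambiguous", "2 2" = "ambiguous")
  dip <- unname(tab[key])
  dip[is.na(c4) | is.na(c2)] <- NA_character_
  e2 <- ifelse(dip %in% c("e2e2"), 2L,
               ifelse(dip %in% c("e2e3", "e2e4"), 1L,
                      ifelse(is.na(dip) | dip == "ambiguous", NA_integer_, 0L)))
  e4 <- ifelse(dip %in% c("e4e4"), 2L,
               ifelse(dip %in% c("e3e4", "e2e4"), 1L,
                      ifelse(is.na(dip) | dip == "ambiguous", NA_integer_, 0L)))
  # the resolvable double heterozygote: e2e4 with ambiguity flag
  amb <- !is.na(dip) & (dip == "ambiguous" |
                          (!is.na(c4) & !is.na(c2) & c4 == 1L & c2 == 1L))
  data.frame(diplotype = dip, e2_dose = e2, e4_dose = e4, ambiguous = amb,
             stringsAsFactors = FALSE)
}

#' Call APOE diplotypes for every sample of a panel
#'
#' Extracts rs429358 and rs7412 from the panel (hard-calling dosages) and
#' calls diplotypes with [call_apoe()]. The panel's dosage convention is
#' respected: whichever allele is counted, the genotype is reconstructed on
#' the standard allele pairs.
#'
#' @param panel a [genotype_panel()] containing rs429358 and rs7412.
#' @return As [call_apoe()], with a `sample_id` column prepended.
#' @export
call_apoe_panel <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  ids <- c("rs429358", "rs7412")
  idx <- match(ids, panel$variants$id)
  if (anyNA(idx))
    stop("panel lacks APOE SNP(s): ", paste(ids[is.na(idx)], collapse = ", "))
  counted <- panel$variants$effect_allele[idx]
  dose <- round(panel$dosages[, idx, drop = FALSE])
  # convert to counts of C (rs429358) and T (rs7412)
  c4 <- if (counted[1] == "C") dose[, 1] else 2 - dose[, 1]
  c2 <- if (counted[2] == "T") dose[, 2] else 2 - dose[, 2]
  chk1 <- sort(c(panel$variants$effect_allele[idx[1]],
                 panel$variants$other_allele[idx[1]]))
  chk2 <- sort(c(panel$variants$effect_allele[idx[2]],
                 panel$variants$other_allele[idx[2]]))
  if (!identical(chk1, c("C", "T")))
    stop("unexpected allele(s) at rs429358: ", paste(chk1, collapse = "/"))
  if (!identical(chk2, c("C", "T")))
    stop("unexpected allele(s) at rs7412: ", paste(chk2, collapse = "/"))
  cbind(data.frame(sample_id = panel$sample_ids, stringsAsFactors = FALSE),
        call_apoe_counts(as.integer(c4), as.integer(c2)))
}
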