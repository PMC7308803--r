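# Readers reject malformed values rather than coercing them; writers emit
# files the paired readers parse losslessly. Coordinates are 1-based
# inclusive internally (VCF convention); BED input is converted at the
# boundary. Chromosome labels have any leading "chr" stripped.

#' Read GWAS summary statistics
#'
#' Tab-separated with header columns `SNP`, `CHR`, `BP`, `A1` (effect
#' allele), `A2`, `BETA`, `SE`, `P`; extra columns are ignored. Rows with
#' non-numeric `BETA`/`SE`/`P`, `P` outside `(0, 1]` or `SE <= 0` are
#' rejected with their line numbers; duplicate SNP ids are an error.
#'
#' @param path file path.
#' @return A `sumstats` data frame (`id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `p`).
#' @export
read_sumstats <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  req <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("summary statistics lack required column(s): ",
         paste(miss, collapse = ", "))
  num <- function(x) suppressWarnings(as.numeric(x))
  beta <- num(raw$BETA); se <- num(raw$SE); p <- num(raw$P); pos <- num(raw$BP)
  bad <- is.na(beta) | is.na(se) | is.na(p) | is.na(pos) |
    p <= 0 | p > 1 | se <= 0
  if (any(bad))
    stop("invalid summary-statistic row(s) at line(s) ",
         paste(which(bad) + 1L, collapse = ", "),
         " (BETA/SE/P must be numeric, P in (0,1], SE > 0)")
  if (anyDuplicated(raw$SNP))
    stop("duplicated SNP id(s): ",
         paste(unique(raw$SNP[duplicated(raw$SNP)]), collapse = ", "))
  out <- data.frame(id = raw$SNP, chrom = norm_chrom(raw$CHR), pos = pos,
                    effect_allele = toupper(raw$A1),
                    other_allele = toupper(raw$A2),
                    beta = beta, se = se, p = p, stringsAsFactors = FALSE)
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Write summary statistics
#'
#' @param sumstats a `sumstats` data frame.
#' @param path output path (tab-separated, header `SNP CHR BP A1 A2 BETA SE P`).
#' @export
write_sumstats <- function(sumstats, path) {
  out <- data.frame(SNP = sumstats$id, CHR = sumstats$chrom,
                    BP = format(sumstats$pos, scientific = FALSE, trim = TRUE),
                    A1 = sumstats$effect_allele, A2 = sumstats$other_allele,
                    BETA = sumstats$beta, SE = sumstats$se, P = sumstats$p)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype panel
#'
#' Dialects: `"vcf"` (DS dosage field used when present, else GT hard
#' calls; multi-allelic records skipped with a reported count), `"raw"`
#' (PLINK additive `.raw`: one column per variant named `id_effectallele`,
#' with a paired `.map`-like variant file or positions parsed from an
#' accompanying map), or `"ped"` (`.ped` + `.map`). DS dosages outside
#' `[0, 2]` are clipped with a warning.
#'
#' @param path file path (for `"ped"`, the `.ped` path with the `.map`
#'   alongside; for `"raw"`, the `.raw` path with a `.map` alongside
#'   supplying positions).
#' @param dialect one of `"vcf"`, `"raw"`, `"ped"`.
#' @return A [genotype_panel()].
#' @export
read_panel <- function(path, dialect = c("vcf", "raw", "ped")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         vcf = read_panel_vcf(path),
         raw = read_panel_raw(path),
         ped = read_panel_ped(path))
}

read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fx$ALT)
  if (any(multi))
    message(sum(multi), " multi-allelic record(s) skipped")
  gt_all <- vcfR::extract.gt(v, element = "GT")
  ds_all <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                     error = function(e) NULL)
  keep <- which(!multi)
  if (!length(keep)) stop("no biallelic records in ", path)
  n <- ncol(gt_all)
  dos <- matrix(NA_real_, n, length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    if (!is.null(ds_all) && !all(is.na(ds_all[i, ]))) {
      d <- ds_all[i, ]
      if (any(d < 0 | d > 2, na.rm = TRUE)) {
        warning("DS dosages outside [0, 2] clipped")
        d <- pmin(pmax(d, 0), 2)
      }
      dos[, k] <- d
    } else {
      g <- gsub("\\|", "/", gt_all[i, ])
      dos[, k] <- vapply(strsplit(g, "/"), function(a) {
        if (any(is.na(a)) || any(a == ".")) return(NA_real_)
        sum(a == "1")
      }, numeric(1))
    }
  }
  ids <- fx$ID[keep]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fx$CHROM[keep][noid], ":", fx$POS[keep][noid])
  variants <- data.frame(id = ids, chrom = norm_chrom(fx$CHROM[keep]),
                         pos = as.numeric(fx$POS[keep]),
                         effect_allele = fx$ALT[keep],
                         other_allele = fx$REF[keep],
                         info = 1, stringsAsFactors = FALSE)
  genotype_panel(dos, variants, sample_ids = colnames(gt_all))
}

#' Write a genotype panel
#'
#' `"vcf"` writes a minimal VCF 4.2 with GT hard calls (rounded dosage) plus
#' a DS dosage field, ALT as the effect (counted) allele; `"raw"` writes the
#' PLINK additive dialect plus a `.map` alongside; `"ped"` writes `.ped` +
#' `.map`.
#'
#' @param panel a [genotype_panel()].
#' @param path output path.
#' @param dialect `"vcf"`, `"raw"`, or `"ped"`.
#' @export
write_panel <- function(panel, path, dialect = c("vcf", "raw", "ped")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         vcf = write_panel_vcf(panel, path),
         raw = write_panel_raw(panel, path),
         ped = write_panel_ped(panel, path))
  invisible(path)
}

write_panel_vcf <- function(panel, path) {
  v <- panel$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$sample_ids), collapse = "\t")),
             con)
  gt_of <- function(d) {
    hc <- round(d)
    out <- rep("./.", length(d))
    out[!is.na(hc) & hc == 0] <- "0/0"
    out[!is.na(hc) & hc == 1] <- "0/1"
    out[!is.na(hc) & hc == 2] <- "1/1"
    out
  }
  ord <- order(chrom_rank(v$chrom), v$pos)
  for (j in ord) {
    d <- panel$dosages[, j]
    ds <- ifelse(is.na(d), ".", format(d, trim = TRUE, digits = 10))
    fields <- paste(gt_of(d), ds, sep = ":")
    writeLines(paste(c(v$chrom[j],
                       format(v$pos[j], scientific = FALSE, trim = TRUE),
                       v$id[j], v$other_allele[j], v$effect_allele[j],
                       ".", "PASS", ".", "GT:DS", fields),
                     collapse = "\t"), con)
  }
  path
}

map_path_for <- function(path) sub("\\.(raw|ped)$", ".map", path)

write_map <- function(panel, path) {
  v <- panel$variants
  utils::write.table(
    data.frame(chrom = v$chrom, id = v$id, cm = 0,
               pos = format(v$pos, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

read_map <- function(path) {
  m <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(m) < 4L) stop("malformed .map file: fewer than 4 columns")
  data.frame(chrom = norm_chrom(m[[1]]), id = as.character(m[[2]]),
             pos = as.numeric(m[[4]]), stringsAsFactors = FALSE)
}

write_panel_raw <- function(panel, path) {
  v <- panel$variants
  hdr <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
           paste0(v$id, "_", v$effect_allele))
  dos <- panel$dosages
  body <- cbind(panel$sample_ids, panel$sample_ids, 0, 0, 0, -9,
                ifelse(is.na(dos), "NA",
                       format(dos, trim = TRUE, digits = 10)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = " "), con)
  writeLines(apply(body, 1L, paste, collapse = " "), con)
  write_map(panel, map_path_for(path))
  path
}

read_panel_raw <- function(path) {
  raw <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  miss <- setdiff(fixed, names(raw))
  if (length(miss)) stop(".raw file lacks column(s): ",
                         paste(miss, collapse = ", "))
  snp_cols <- setdiff(names(raw), fixed)
  us <- regexpr("_[^_]+$", snp_cols)
  ids <- substr(snp_cols, 1L, us - 1L)
  eff <- substring(snp_cols, us + 1L)
  dos <- as.matrix(raw[, snp_cols, drop = FALSE])
  storage.mode(dos) <- "double"
  mp <- map_path_for(path)
  if (!file.exists(mp))
    stop("variant map ", mp, " not found alongside .raw file")
  m <- read_map(mp)
  mi <- match(ids, m$id)
  if (anyNA(mi)) stop(".raw variant(s) absent from .map: ",
                      paste(ids[is.na(mi)], collapse = ", "))
  other <- rep("G", length(ids))
  other[eff == "G"] <- "A"
  variants <- data.frame(id = ids, chrom = m$chrom[mi], pos = m$pos[mi],
                         effect_allele = eff, other_allele = other,
                         info = 1, stringsAsFactors = FALSE)
  genotype_panel(dos, variants, sample_ids = as.character(raw$IID))
}

write_panel_ped <- function(panel, path) {
  v <- panel$variants
  hc <- round(panel$dosages)
  n <- nrow(hc)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    alleles <- character(2L * ncol(hc))
    for (j in seq_len(ncol(hc))) {
      g <- hc[i, j]
      pair <- if (is.na(g)) c("0", "0")
        else if (g == 0) rep(v$other_allele[j], 2L)
        else if (g == 1) c(v$other_allele[j], v$effect_allele[j])
        else rep(v$effect_allele[j], 2L)
      alleles[c(2L * j - 1L, 2L * j)] <- pair
    }
    writeLines(paste(c(panel$sample_ids[i], panel$sample_ids[i],
                       "0", "0", "0", "-9", alleles), collapse = " "), con)
  }
  write_map(panel, map_path_for(path))
  path
}

read_panel_ped <- function(path) {
  mp <- map_path_for(path)
  if (!file.exists(mp)) stop("variant map ", mp, " not found alongside .ped")
  m <- read_map(mp)
  lines <- readLines(path)
  if (!length(lines)) stop("empty .ped file")
  toks <- strsplit(trimws(lines), "[ \t]+")
  nfield <- 6L + 2L * nrow(m)
  badlen <- which(vapply(toks, length, integer(1)) != nfield)
  if (length(badlen))
    stop("malformed .ped record at line(s) ",
         paste(utils::head(badlen, 5), collapse = ", "),
         ": expected ", nfield, " fields")
  n <- length(toks)
  dos <- matrix(NA_real_, n, nrow(m))
  ids <- character(n)
  # counted allele per variant: established from the data (minor allele),
  # falling back to the first non-zero allele seen
  amat <- t(vapply(toks, function(x) x[-(1:6)], character(2L * nrow(m))))
  ids <- vapply(toks, function(x) x[2L], character(1))
  eff <- other <- character(nrow(m))
  for (j in seq_len(nrow(m))) {
    a <- c(amat[, 2L * j - 1L], amat[, 2L * j])
    obs <- a[a != "0"]
    lv <- names(sort(table(obs)))        # minor first
    if (length(lv) == 0L) { eff[j] <- "A"; other[j] <- "G" }
    else if (length(lv) == 1L) {
      eff[j] <- lv
      other[j] <- setdiff(c("A", "C", "G", "T"), lv)[1]
    } else if (length(lv) == 2L) {
      eff[j] <- lv[1]; other[j] <- lv[2]
    } else stop("multi-allelic variant in .ped: ", m$id[j])
    a1 <- amat[, 2L * j - 1L]; a2 <- amat[, 2L * j]
    missing <- a1 == "0" | a2 == "0"
    dos[, j] <- (a1 == eff[j]) + (a2 == eff[j])
    dos[missing, j] <- NA_real_
  }
  variants <- data.frame(id = m$id, chrom = m$chrom, pos = m$pos,
                         effect_allele = eff, other_allele = other,
                         info = 1, stringsAsFactors = FALSE)
  genotype_panel(dos, variants, sample_ids = ids)
}

#' Read gene intervals from a BED file
#'
#' BED4 (`chrom`, `start`, `end`, `gene`), 0-based half-open; converted to
#' 1-based inclusive coordinates on read.
#'
#' @param path BED file path.
#' @return Data frame `chrom`, `start`, `end`, `gene` (1-based inclusive).
#' @export
read_bed <- function(path) {
  b <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "#")
  if (ncol(b) < 4L) stop("BED file needs 4 columns (chrom, start, end, name)")
  start <- suppressWarnings(as.numeric(b[[2]]))
  end <- suppressWarnings(as.numeric(b[[3]]))
  if (anyNA(start) || anyNA(end)) stop("non-numeric BED coordinates")
  if (any(end <= start)) stop("BED intervals with end <= start")
  data.frame(chrom = norm_chrom(b[[1]]), start = start + 1, end = end,
             gene = as.character(b[[4]]), stringsAsFactors = FALSE)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t"), function(x) {
    if (length(x) < 3L) stop("malformed GMT line: fewer than 3 fields")
    x[-(1:2)]
  })
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1L)
  sets
}

#' Read a sample covariate/phenotype table
#'
#' Tab-separated with header; must contain `sample_id`. Numeric columns are
#' typed; non-numeric values in otherwise-numeric columns are rejected.
#'
#' @param path file path.
#' @return A `sample_table` data frame.
#' @export
read_sample_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  if (!"sample_id" %in% names(d)) stop("sample table lacks 'sample_id'")
  d$sample_id <- as.character(d$sample_id)
  class(d) <- c("sample_table", "data.frame")
  d
}

#' Write a sample table
#' @param samples a `sample_table`.
#' @param path output path.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(as.data.frame(samples), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a variant id list (one id per line)
#' @param ids character vector of variant ids.
#' @param path file path.
#' @export
write_variant_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' @rdname write_variant_list
#' @export
read_variant_list <- function(path) readLines(path)
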