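#' Pipeline configuration
#'
#' Reads a flat `key = value` text configuration (lines starting with `#`
#' ignored) or accepts the same keys as a named list, fills defaults, and
#' validates the sub-configurations. Recognised keys: the [sim_config()]
#' fields (`seed`, `n_variants`, `n_blocks`, `within_block_r`, `maf_lo`,
#' `maf_hi`, `n_discovery`, `n_target`, `prevalence`, `beta_e4_young`,
#' `beta_e4_old`, `beta_e2`, `n_causal`, `h2_poly`, `age_mean`, `age_sd`,
#' `age_cutoff`, `survival_shift_e4`, `proxy`), QC (`qc_profile`), pruning
#' (`r2_max`, `window_bp`), scoring (`p_threshold`, `exclude_apoe`), and
#' optional input paths (`panel_path`, `panel_dialect`, `sumstats_path`,
#' `samples_path`) that replace the simulated inputs.
#'
#' @param x path to a configuration file, or a named list.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) {
    lines <- readLines(x)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "\\s*=\\s*")
    bad <- vapply(kv, length, integer(1)) != 2L
    if (any(bad)) stop("malformed config line(s): ",
                       paste(lines[bad], collapse = "; "))
    x <- stats::setNames(lapply(kv, function(p) {
      v <- p[2]
      n <- suppressWarnings(as.numeric(v))
      if (!is.na(n)) n else v
    }), vapply(kv, `[`, character(1), 1L))
  }
  defaults <- list(seed = 1, n_variants = 200, n_blocks = 20,
                   within_block_r = 0.8, maf_lo = 0.1, maf_hi = 0.5,
                   n_discovery = 2000, n_target = 2000, prevalence = 0.2,
                   beta_e4_young = 0.5, beta_e4_old = 0.2, beta_e2 = -0.15,
                   n_causal = 50, h2_poly = 0.15, age_mean = 75, age_sd = 8,
                   age_cutoff = 80, survival_shift_e4 = -1, proxy = 0,
                   qc_profile = "array", r2_max = 0.1, window_bp = 1e6,
                   p_threshold = 0.5, exclude_apoe = 1,
                   panel_path = NA, panel_dialect = "vcf",
                   sumstats_path = NA, samples_path = NA,
                   log_level = "info")
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, x)
  cfg$sim <- sim_config(seed = cfg$seed, n_variants = cfg$n_variants,
                        n_blocks = cfg$n_blocks,
                        within_block_r = cfg$within_block_r,
                        maf_range = c(cfg$maf_lo, cfg$maf_hi),
                        n_discovery = cfg$n_discovery,
                        n_target = cfg$n_target, prevalence = cfg$prevalence,
                        beta_e4_young = cfg$beta_e4_young,
                        beta_e4_old = cfg$beta_e4_old, beta_e2 = cfg$beta_e2,
                        n_causal = cfg$n_causal, h2_poly = cfg$h2_poly,
                        age_distribution = c(cfg$age_mean, cfg$age_sd),
                        age_cutoff = cfg$age_cutoff,
                        survival_shift_e4 = cfg$survival_shift_e4,
                        proxy = cfg$proxy != 0)
  cfg$qc <- qc_config(profile = cfg$qc_profile)
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> variant QC -> LD pruning -> scoring ->
#' association in order, writing per-stage outputs under `out_dir`:
#' `sumstats.tsv`, `qc_report.tsv`, `retained_variants.txt`, `scores.tsv`,
#' `association.tsv` (age-stratified coefficient table), and when parental
#' proxies are simulated also `parental_association.tsv`,
#' `apoe_survival_ages.tsv`, `apoe_survival_proportions.tsv`; plus
#' `run_log.txt` recording every threshold actually applied, the seed and
#' package version. Fully deterministic under the configured seed.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   of all written files.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  log_lines <- c(paste0("prsage ", as.character(utils::packageVersion("prsage"))),
                 paste0("seed = ", config$seed))
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  simcfg <- config$sim
  if (!is.na(config$panel_path)) {
    panel <- stage("load", read_panel(config$panel_path,
                                      config$panel_dialect))
    sumstats <- stage("load", read_sumstats(config$sumstats_path))
    samples <- stage("load", read_sample_table(config$samples_path))
    parents <- NULL
    note("inputs: panel = ", config$panel_path,
         ", sumstats = ", config$sumstats_path)
  } else {
    panel <- stage("simulate",
                   attach_apoe(simulate_genotypes(simcfg), simcfg))
    sumstats <- stage("simulate", simulate_discovery_sumstats(simcfg))
    parents <- NULL
    if (simcfg$proxy) {
      parents <- stage("simulate", simulate_parents(panel, simcfg))
      samples <- parents$samples
    } else {
      samples <- stage("simulate", simulate_phenotype(panel, simcfg))
    }
    note("simulated: ", nrow(panel$dosages), " samples x ",
         nrow(panel$variants), " variants; discovery n = ",
         simcfg$n_discovery)
  }
  write_sumstats(sumstats, p("sumstats.tsv"))

  qcres <- stage("qc", {
    metrics <- qc_metrics(panel, config$qc,
                          status = if ("status" %in% names(samples))
                            samples$status)
    qc_filter(panel, metrics, config$qc)
  })
  utils::write.table(qcres$report, p("qc_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("qc: profile = ", config$qc$profile, ", maf_min = ",
       config$qc$maf_min, ", missing_max = ", config$qc$missing_max,
       ", hwe_p_min = ", config$qc$hwe_p_min, "; removed ",
       qcres$report$n_failed[qcres$report$filter == "unique_removed"],
       " of ", nrow(panel$variants), " variants")
  panel_qc <- qcres$panel

  retained <- stage("prune",
                    ld_prune(panel_qc, sumstats, r2_max = config$r2_max,
                             window_bp = config$window_bp,
                             seed = config$seed))
  write_variant_list(retained, p("retained_variants.txt"))
  note("prune: r2_max = ", config$r2_max, ", window_bp = ", config$window_bp,
       "; retained ", length(retained), " variants")

  apoe <- stage("score", call_apoe_panel(panel))
  scored <- stage("score", {
    excl <- if (config$exclude_apoe != 0) apoe_region()
    raw <- compute_prs(panel_qc, sumstats, keep = retained,
                       p_threshold = config$p_threshold,
                       exclude_regions = excl)
    if (raw$n_variants_used == 0L)
      warning("scoring used zero variants")
    covars <- intersect(c("age", "sex", grep("^PC", names(samples),
                                             value = TRUE)),
                        names(samples))
    adjust_standardize(raw, samples[covars])
  })
  utils::write.table(cbind(as.data.frame(scored),
                           n_variants_used = attr(scored, "n_variants_used")),
                     p("scores.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("score: p_threshold = ", config$p_threshold, ", exclude_apoe = ",
       config$exclude_apoe != 0, ", n_variants_used = ",
       attr(scored, "n_variants_used"))

  files <- c(p("sumstats.tsv"), p("qc_report.tsv"),
             p("retained_variants.txt"), p("scores.tsv"))
  assoc <- stage("associate", {
    if ("status" %in% names(samples)) {
      tab <- stratified_assoc(samples, scored, apoe, outcome = "status",
                              family = "binomial", age_var = "age",
                              cutoff = config$age_cutoff)
      utils::write.table(as.data.frame(tab), p("association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, p("association.tsv"))
      list(stratified = tab)
    } else {
      samples$parental_age <- (samples$maternal_age + samples$paternal_age) / 2
      tab <- stratified_assoc(samples, scored, apoe,
                              outcome = "parental_count",
                              family = "poisson", age_var = "parental_age",
                              cutoff = config$age_cutoff)
      par <- parental_assoc(samples, scored, apoe)
      surv <- apoe_survival_tables(samples, apoe,
                                   cutoff = config$age_cutoff)
      utils::write.table(as.data.frame(tab), p("association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      partab <- do.call(rbind, lapply(names(par), function(nm)
        cbind(model = nm, par[[nm]]$coefficients)))
      utils::write.table(partab, p("parental_association.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(surv$ages, p("apoe_survival_ages.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(surv$proportions, p("apoe_survival_proportions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, p("association.tsv"), p("parental_association.tsv"),
                 p("apoe_survival_ages.tsv"),
                 p("apoe_survival_proportions.tsv"))
      list(stratified = tab, parental = par, survival = surv)
    }
  })
  note("associate: cutoff = ", config$age_cutoff, " years")
  writeLines(log_lines, p("run_log.txt"))
  invisible(list(panel = panel, sumstats = sumstats, samples = samples,
                 qc = qcres, retained = retained, scores = scored,
                 apoe = apoe, association = assoc, parents = parents,
                 files = c(files, p("run_log.txt"))))
}
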