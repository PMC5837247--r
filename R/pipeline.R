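.load_config <- function(config) {
  if (is.null(config)) return(list(raw = list(), path = NA_character_))
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    return(list(raw = yaml::read_yaml(config), path = config))
  }
  list(raw = config, path = NA_character_)
}

.estimates_for_json <- function(estimates) {
  lapply(estimates, function(e)
    list(label = e$label, scale = e$scale, beta = e$beta, se = e$se,
         point = e$point, ci_lo = e$ci_lo, ci_hi = e$ci_hi, p = e$p,
         n = e$n))
}

write_json_atomic <- function(x, path) {
  write_atomic(function(p)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null"), path)
}

#' Run the statin-intolerance pipeline end to end
#'
#' Orchestrates the pipeline stages with seeded determinism and a run
#' manifest. `simulate` writes a synthetic cohort bundle to `out_dir`;
#' `phenotype` classifies the cohort in `out_dir` and writes the
#' assignment audit table; `associate` builds the analysis table(s) and
#' fits the covariate-adjusted dominant-model logistic regression with
#' backwards stepwise elimination; `meta` pools per-study odds ratios by
#' fixed-effects meta-analysis; `all` chains the four stages. Outputs are
#' written atomically, counts and exclusions are logged, and every run
#' writes `manifest.json` listing inputs, outputs, seed and the config
#' digest. Re-running with the same inputs and seed reproduces the output
#' files byte for byte.
#'
#' @param command one of `"simulate"`, `"phenotype"`, `"associate"`,
#'   `"meta"`, `"all"`.
#' @param config `NULL`, a YAML file path or a list with optional
#'   sections `simulation` (arguments to [simulation_config()]), `rules`
#'   (arguments to [rules_config()]) and `meta` (`studies_csv` path,
#'   defaulting to the packaged four-study table).
#' @param seed integer seed for every source of randomness.
#' @param out_dir directory for stage outputs (and inputs of later
#'   stages).
#' @param phenotype `"both"`, `"gsi"` or `"ldi"` for the association
#'   stage.
#' @param format genotype output format, `"csv"` or `"vcf"`.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(command = c("all", "simulate", "phenotype",
                                     "associate", "meta"),
                         config = NULL, seed = 1L,
                         out_dir = "statintol_run",
                         phenotype = c("both", "gsi", "ldi"),
                         format = c("csv", "vcf")) {
  command <- match.arg(command)
  phenotype <- match.arg(phenotype)
  format <- match.arg(format)
  cfg <- .load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rules <- do.call(rules_config, cfg$raw$rules %||% list())
  inputs <- character(0)
  outputs <- character(0)

  path_in <- function(file) {
    p <- file.path(out_dir, file)
    if (!file.exists(p))
      stopf("input %s not found in %s; run the earlier stage first",
            file, out_dir)
    inputs <<- c(inputs, p)
    p
  }

  if (command %in% c("simulate", "all")) {
    sim_args <- cfg$raw$simulation %||% list()
    sim_args$seed <- as.integer(seed)
    simcfg <- do.call(simulation_config, sim_args)
    bundle <- simulate_observational_cohort(simcfg, rules)
    outputs <- c(outputs, write_cohort(bundle, out_dir, format))
    log_info("simulated cohort of %d patients into %s",
             nrow(bundle$patients), out_dir)
  }

  if (command %in% c("phenotype", "all")) {
    rx <- read_prescriptions(path_in("prescriptions.csv"))
    labs <- read_labs(path_in("labs.csv"))
    cov <- read_covariates(path_in("patients.csv"))
    assignments <- classify_cohort(prescriptions = rx, labs = labs,
                                   patients = cov, rules = rules)
    excl <- attr(assignments, "excluded")
    p <- file.path(out_dir, "assignments.csv")
    write_csv_atomic(assignments, p)
    outputs <- c(outputs, p)
    if (nrow(excl)) {
      pe <- file.path(out_dir, "excluded.csv")
      write_csv_atomic(excl, pe)
      outputs <- c(outputs, pe)
    }
  }

  if (command %in% c("associate", "all")) {
    gfile <- if (file.exists(file.path(out_dir, "genotypes.vcf")))
      "genotypes.vcf" else "genotypes.csv"
    genotypes <- read_genotypes(path_in(gfile))
    cov <- read_covariates(path_in("patients.csv"))
    assignments <- as.data.table(utils::read.csv(path_in("assignments.csv"),
                                                 stringsAsFactors = FALSE))
    phens <- if (phenotype == "both") c("gsi", "ldi") else phenotype
    for (ph in phens) {
      tab <- build_analysis_table(assignments, genotypes, cov, ph)
      # CK is adjustable only for LDI: the GSI case definition conditions
      # on elevated CK, so CK separates GSI cases from CK-normal controls
      full <- c("age", "female", "comedication", "t2d")
      if (ph == "ldi") full <- c(full, "log10_ck")
      sel <- backward_eliminate(tab, full_terms = full)
      maf <- estimate_maf_and_hwe(merge(tab, genotypes, by = "patient_id")$genotype)
      report <- list(
        phenotype = toupper(ph), n = sel$fit$n,
        cases = sum(tab$outcome == 1), controls = sum(tab$outcome == 0),
        maf = maf$maf, hwe_p = maf$hwe_p,
        alpha = sel$alpha, terms = sel$terms,
        elimination_trace = sel$trace,
        estimates = .estimates_for_json(sel$fit$estimates))
      p <- file.path(out_dir, sprintf("association_%s.json", ph))
      write_json_atomic(report, p)
      outputs <- c(outputs, p)
      log_info("%s: genotype OR %.2f (p = %.3g) on %d cases / %d controls",
               toupper(ph), sel$fit$estimates[[1]]$point,
               sel$fit$estimates[[1]]$p, report$cases, report$controls)
    }
  }

  if (command %in% c("meta", "all")) {
    studies_path <- cfg$raw$meta$studies_csv %||%
      statintol_example("figure1_studies.csv")
    inputs <- c(inputs, studies_path)
    studies <- read_studies(studies_path)
    pooled <- pool_fixed_effects(studies)
    print(pooled)
    forest <- make_forest_table(studies, pooled)
    pf <- file.path(out_dir, "forest.tsv")
    write_atomic(function(p) utils::write.table(forest, p, sep = "\t",
                                                row.names = FALSE,
                                                quote = FALSE), pf)
    pj <- file.path(out_dir, "meta.json")
    write_json_atomic(
      list(pooled = .estimates_for_json(list(pooled$pooled))[[1]],
           z = pooled$z, q_stat = pooled$q_stat, q_df = pooled$q_df,
           q_p = pooled$q_p,
           weights = stats::setNames(as.list(pooled$studies$weight_fraction),
                                     pooled$studies$study)), pj)
    outputs <- c(outputs, pf, pj)
  }

  manifest <- list(
    command = command,
    config_path = cfg$path,
    config_hash = if (is.na(cfg$path)) NA_character_
                  else unname(tools::md5sum(cfg$path)),
    seed = as.integer(seed),
    phenotype = phenotype, format = format,
    inputs = unique(inputs), outputs = unique(outputs),
    tool_version = as.character(utils::packageVersion("statintol")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  write_json_atomic(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
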