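#' Statins recognised by the phenotyping rules
#' @export
statin_vocabulary <- c("simvastatin", "atorvastatin", "rosuvastatin",
                       "pravastatin", "fluvastatin", "lovastatin",
                       "pitavastatin")

# mg of simvastatin with comparable LDL-lowering potency per mg of drug
# (standard potency ladder: atorvastatin 20 mg ~ rosuvastatin 10 mg ~
#  simvastatin 40 mg ~ pravastatin/fluvastatin/lovastatin 80 mg ~
#  pitavastatin 4 mg)
default_dose_equivalence <- c(
  simvastatin = 1, atorvastatin = 2, rosuvastatin = 4,
  pravastatin = 0.5, fluvastatin = 0.5, lovastatin = 0.5,
  pitavastatin = 10)

# lowest approved daily starting dose, mg/day
default_lowest_start_dose <- c(
  simvastatin = 10, atorvastatin = 10, rosuvastatin = 5,
  pravastatin = 40, fluvastatin = 20, lovastatin = 20,
  pitavastatin = 2)

#' Phenotyping rules configuration
#'
#' Bundles every threshold the intolerance classifier uses so the whole
#' rule set is explicit, auditable and overridable. Defaults encode the
#' published definitions: tolerant controls require over 90% prescription
#' coverage for at least 5 years at a mean daily dose of at least 40 mg
#' simvastatin-equivalent; general statin intolerance requires an
#' on-statin CK above the sex-specific upper limit of normal (ULN) plus
#' two or more statin switches or total discontinuation; low-dose
#' intolerance requires two or more distinct statins with at least one
#' discontinued at its lowest approved starting dose. Systematic switches
#' to atorvastatin on or after its UK patent expiry are not counted as
#' switches.
#'
#' @param ck_uln named numeric, sex-specific CK upper limit of normal in
#'   IU/L (`male`, `female`). Labs publish their own ranges, so this is
#'   configurable; defaults 320/200.
#' @param sim_fold_uln fold-ULN threshold flagging candidate
#'   statin-induced myopathy (default 4, inclusive comparison).
#' @param dose_equivalence named numeric map drug -> mg
#'   simvastatin-equivalent per mg; must cover [statin_vocabulary].
#' @param lowest_start_dose named numeric map drug -> lowest approved
#'   starting dose in mg/day.
#' @param coverage_threshold fraction of the therapy window that must be
#'   covered for tolerant controls; comparison is strict `>` (default 0.9).
#' @param min_years minimum years on therapy for tolerant controls
#'   (`>=`, default 5).
#' @param min_equiv_dose minimum mean simvastatin-equivalent daily dose in
#'   mg for tolerant controls (`>=`, default 40).
#' @param discontinuation_gap_days a statin counts as discontinued when no
#'   further script for it starts within this many days after the covered
#'   interval ends (strict `>`, default 90).
#' @param atorvastatin_patent_date switches to atorvastatin starting on or
#'   after this date are treated as systematic patent-expiry shifts and
#'   not counted (default 2012-05-01, UK expiry).
#' @param min_switches_gsi switch count qualifying for general statin
#'   intolerance (default 2).
#' @param min_distinct_statins_ldi distinct statins required for low-dose
#'   intolerance (default 2).
#' @param switch_metric count `"events"` (drug changes between consecutive
#'   scripts, default) or `"distinct"` statins for the GSI switch rule.
#' @param dose_metric `"weighted_mean"` (days-supply-weighted mean
#'   equivalent dose, default) or `"minimum"` maintained dose for the
#'   tolerant-control dose criterion.
#' @return An object of class `rules_config`.
#' @examples
#' rules <- rules_config()
#' rules$ck_uln
#' @export
rules_config <- function(ck_uln = c(male = 320, female = 200),
                         sim_fold_uln = 4,
                         dose_equivalence = default_dose_equivalence,
                         lowest_start_dose = default_lowest_start_dose,
                         coverage_threshold = 0.90,
                         min_years = 5,
                         min_equiv_dose = 40,
                         discontinuation_gap_days = 90,
                         atorvastatin_patent_date = as.Date("2012-05-01"),
                         min_switches_gsi = 2L,
                         min_distinct_statins_ldi = 2L,
                         switch_metric = c("events", "distinct"),
                         dose_metric = c("weighted_mean", "minimum")) {
  switch_metric <- match.arg(switch_metric)
  dose_metric <- match.arg(dose_metric)
  if (!all(c("male", "female") %in% names(ck_uln)))
    stopf("ck_uln must be named with 'male' and 'female'")
  assert_positive(unname(ck_uln), "ck_uln")
  assert_positive(sim_fold_uln, "sim_fold_uln")
  missing_eq <- setdiff(statin_vocabulary, names(dose_equivalence))
  if (length(missing_eq))
    stopf("dose_equivalence lacks: %s", paste(missing_eq, collapse = ", "))
  missing_lo <- setdiff(statin_vocabulary, names(lowest_start_dose))
  if (length(missing_lo))
    stopf("lowest_start_dose lacks: %s", paste(missing_lo, collapse = ", "))
  assert_positive(unname(dose_equivalence), "dose_equivalence")
  assert_positive(unname(lowest_start_dose), "lowest_start_dose")
  assert_fraction(coverage_threshold, "coverage_threshold")
  assert_positive(min_years, "min_years")
  assert_positive(min_equiv_dose, "min_equiv_dose")
  assert_positive(discontinuation_gap_days, "discontinuation_gap_days")
  structure(
    list(ck_uln = ck_uln, sim_fold_uln = sim_fold_uln,
         dose_equivalence = dose_equivalence,
         lowest_start_dose = lowest_start_dose,
         coverage_threshold = coverage_threshold,
         min_years = min_years, min_equiv_dose = min_equiv_dose,
         discontinuation_gap_days = discontinuation_gap_days,
         atorvastatin_patent_date = as.Date(atorvastatin_patent_date),
         min_switches_gsi = as.integer(min_switches_gsi),
         min_distinct_statins_ldi = as.integer(min_distinct_statins_ldi),
         switch_metric = switch_metric, dose_metric = dose_metric),
    class = "rules_config")
}

#' @export
print.rules_config <- function(x, ...) {
  cat("Statin-intolerance phenotyping rules\n")
  cat(sprintf("  CK ULN: %g IU/L (male), %g IU/L (female); SIM flag >= %gx ULN\n",
              x$ck_uln[["male"]], x$ck_uln[["female"]], x$sim_fold_uln))
  cat(sprintf("  Tolerant: coverage > %g, >= %g years, mean dose >= %g mg simva-equivalent\n",
              x$coverage_threshold, x$min_years, x$min_equiv_dose))
  cat(sprintf("  Discontinuation gap > %d days; GSI switches >= %d (%s); LDI distinct statins >= %d\n",
              x$discontinuation_gap_days, x$min_switches_gsi,
              x$switch_metric, x$min_distinct_statins_ldi))
  cat(sprintf("  Atorvastatin patent date: %s\n",
              format(x$atorvastatin_patent_date)))
  invisible(x)
}

#' Read or write a rules configuration as YAML
#'
#' The three dose tables are stored inline as named maps; dates ISO-8601.
#'
#' @param path file path.
#' @param rules a [rules_config()] object (for writing).
#' @return `read_rules()` returns a `rules_config`; `write_rules()` the
#'   path, invisibly.
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("ck_uln", "dose_equivalence", "lowest_start_dose"))
    if (!is.null(raw[[nm]])) args[[nm]] <- unlist(raw[[nm]])
  for (nm in c("sim_fold_uln", "coverage_threshold", "min_years",
               "min_equiv_dose", "discontinuation_gap_days",
               "min_switches_gsi", "min_distinct_statins_ldi",
               "switch_metric", "dose_metric"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$atorvastatin_patent_date))
    args$atorvastatin_patent_date <- as.Date(raw$atorvastatin_patent_date)
  do.call(rules_config, args)
}

#' @rdname read_rules
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "rules_config"))
  out <- rules
  out$atorvastatin_patent_date <- format(out$atorvastatin_patent_date)
  out <- lapply(unclass(out), function(v) if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
  yaml::write_yaml(out, path)
  invisible(path)
}
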