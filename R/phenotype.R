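#' Convert a statin dose to its simvastatin-equivalent
#'
#' @param drug statin name(s) from [statin_vocabulary].
#' @param daily_dose_mg daily dose(s) in mg.
#' @param rules a [rules_config()] supplying the equivalence table.
#' @return mg/day of simvastatin with comparable potency.
#' @examples
#' dose_equivalent("atorvastatin", 20)  # 40
#' @export
dose_equivalent <- function(drug, daily_dose_mg, rules = rules_config()) {
  unknown <- setdiff(unique(drug), names(rules$dose_equivalence))
  if (length(unknown))
    stopf("unknown drug(s): %s", paste(unknown, collapse = ", "))
  if (any(daily_dose_mg <= 0)) stopf("daily_dose_mg must be positive")
  unname(daily_dose_mg * rules$dose_equivalence[drug])
}

# union length (days) of half-open covered intervals clipped to a window
.union_days <- function(start_i, end_i, win_lo, win_hi) {
  s <- pmax(start_i, win_lo)
  e <- pmin(end_i, win_hi)
  keep <- e > s
  if (!any(keep)) return(0L)
  s <- s[keep]; e <- e[keep]
  o <- order(s)
  s <- s[o]; e <- e[o]
  cm <- cummax(e)
  prev <- c(s[1], cm[-length(cm)])
  sum(pmax(0L, e - pmax(s, prev)))
}

#' Prescription coverage of a time window
#'
#' Coverage is the union of covered half-open intervals
#' `[start_date, start_date + days_supply)` clipped to the window, divided
#' by the window length; overlapping scripts never double-count.
#'
#' @param prescriptions data frame with `start_date`, `days_supply` (one
#'   patient).
#' @param window length-2 Date vector `[start, end)`; defaults to the
#'   therapy window (first script start to last covered day).
#' @return list with `coverage` (fraction in \[0, 1\]) and `therapy_years`
#'   (window length in years of 365.25 days).
#' @examples
#' rx <- data.frame(start_date = as.Date("2000-01-01"), days_supply = 90)
#' compute_coverage(rx, window = as.Date(c("2000-01-01", "2000-04-10")))
#' @export
compute_coverage <- function(prescriptions, window = NULL) {
  if (is.null(prescriptions) || nrow(prescriptions) == 0) {
    if (is.null(window)) return(list(coverage = 0, therapy_years = 0))
    len <- as.numeric(as.Date(window[2]) - as.Date(window[1]))
    if (len <= 0) stopf("window must be non-empty")
    return(list(coverage = 0, therapy_years = len / 365.25))
  }
  start_i <- as.integer(as.Date(prescriptions$start_date))
  end_i <- start_i + as.integer(prescriptions$days_supply)
  if (is.null(window)) {
    win_lo <- min(start_i); win_hi <- max(end_i)
  } else {
    win_lo <- as.integer(as.Date(window[1]))
    win_hi <- as.integer(as.Date(window[2]))
  }
  len <- win_hi - win_lo
  if (len <= 0) stopf("window must be non-empty")
  list(coverage = .union_days(start_i, end_i, win_lo, win_hi) / len,
       therapy_years = len / 365.25)
}

#' Count statin switches and distinct statins
#'
#' A switch is a change of drug between chronologically consecutive
#' scripts (ties broken by drug name). A simvastatin-to-atorvastatin
#' change whose atorvastatin script starts on or after the atorvastatin
#' patent-expiry date is treated as a systematic formulary shift and not
#' counted, although atorvastatin still counts as a distinct statin.
#'
#' @param prescriptions data frame with `drug`, `start_date` (one patient).
#' @param rules a [rules_config()].
#' @return list with `switches` and `distinct_statins`.
#' @export
count_switches <- function(prescriptions, rules = rules_config()) {
  if (nrow(prescriptions) == 0)
    return(list(switches = 0L, distinct_statins = 0L))
  o <- order(as.Date(prescriptions$start_date), prescriptions$drug)
  drug <- prescriptions$drug[o]
  start <- as.Date(prescriptions$start_date)[o]
  n <- length(drug)
  if (n == 1)
    return(list(switches = 0L, distinct_statins = 1L))
  change <- drug[-1] != drug[-n]
  patent_shift <- drug[-n] == "simvastatin" & drug[-1] == "atorvastatin" &
    start[-1] >= rules$atorvastatin_patent_date
  list(switches = sum(change & !patent_shift),
       distinct_statins = length(unique(drug)))
}

#' Detect per-drug discontinuation events
#'
#' A drug is discontinued at script `s` when no script for the same drug
#' starts within `discontinuation_gap_days` (strict `>`) after `s`'s
#' covered interval ends; courses still covered, or within the gap, at the
#' end of records are treated as ongoing, not discontinued.
#'
#' @param prescriptions data frame with `drug`, `daily_dose_mg`,
#'   `start_date`, `days_supply` (one patient).
#' @param records_end last date of the prescribing record
#'   (`>=` every script's covered end).
#' @param rules a [rules_config()].
#' @return `data.table` of events: `drug`, `daily_dose_mg`, `date`
#'   (end of the discontinued script's coverage).
#' @export
detect_discontinuations <- function(prescriptions, records_end,
                                    rules = rules_config()) {
  empty <- data.table(drug = character(), daily_dose_mg = numeric(),
                      date = as.Date(character()))
  if (nrow(prescriptions) == 0) return(empty)
  rx <- as.data.table(prescriptions)
  rx[, start_date := as.Date(start_date)]
  end_all <- rx$start_date + rx$days_supply
  records_end <- as.Date(records_end)
  if (any(end_all > records_end))
    stopf("records_end precedes the end of a script's coverage")
  setorder(rx, drug, start_date)
  rx[, end_i := as.integer(start_date) + as.integer(days_supply)]
  rx[, next_start := shift(as.integer(start_date), -1L), by = drug]
  rx[, gap := fifelse(is.na(next_start),
                      as.integer(records_end) - end_i,
                      next_start - end_i)]
  ev <- rx[gap > rules$discontinuation_gap_days,
           .(drug, daily_dose_mg, date = as.Date(end_i, origin = "1970-01-01"))]
  setorder(ev, date)
  ev[]
}

#' Flag on-statin creatine kinase elevations
#'
#' Only CK results dated on or after therapy start contribute. The
#' above-ULN comparison is strict (`>`); the myopathy-candidate
#' comparison (`sim_fold_uln` times ULN) is inclusive (`>=`).
#'
#' @param labs data frame with `analyte`, `date`, `value` (one patient).
#' @param therapy_start first statin script date.
#' @param sex `"M"` or `"F"`, selecting the ULN.
#' @param rules a [rules_config()].
#' @return list of tri-state logicals `any_on_statin_above_uln`,
#'   `any_on_statin_ge_4x_uln`, `all_on_statin_normal`; all `NA` when the
#'   patient has no on-statin CK result (such a patient cannot qualify as
#'   a CK-normal tolerant control).
#' @export
flag_ck <- function(labs, therapy_start, sex, rules = rules_config()) {
  uln <- rules$ck_uln[[if (sex == "F") "female" else "male"]]
  ck <- labs[labs$analyte == "CK" &
               as.Date(labs$date) >= as.Date(therapy_start), , drop = FALSE]
  if (nrow(ck) == 0)
    return(list(any_on_statin_above_uln = NA,
                any_on_statin_ge_4x_uln = NA,
                all_on_statin_normal = NA))
  mx <- max(ck$value)
  list(any_on_statin_above_uln = mx > uln,
       any_on_statin_ge_4x_uln = mx >= rules$sim_fold_uln * uln,
       all_on_statin_normal = mx <= uln)
}

# shared rule logic: flags -> GSI/LDI status labels (case takes
# precedence over control when both rule sets are met)
.apply_rules <- function(f, rules) {
  switch_stat <- if (rules$switch_metric == "events") f$switches_n else f$distinct_statins
  dose_stat <- if (rules$dose_metric == "weighted_mean") f$mean_equiv_dose else f$min_equiv_dose
  gsi_case <- !is.na(f$ck_above_uln) & f$ck_above_uln &
    (switch_stat >= rules$min_switches_gsi | f$total_discontinuation)
  st2 <- f$coverage > rules$coverage_threshold &
    f$years_on_therapy >= rules$min_years &
    dose_stat >= rules$min_equiv_dose &
    f$switches_n == 0L & !f$total_discontinuation
  st1 <- st2 & !is.na(f$ck_all_normal) & f$ck_all_normal
  ldi_case <- f$distinct_statins >= rules$min_distinct_statins_ldi &
    f$discontinued_lowest_dose
  list(gsi = fifelse(gsi_case, "case", fifelse(st1, "control", "unclassified")),
       ldi = fifelse(ldi_case, "case", fifelse(st2, "control", "unclassified")),
       st1_criteria = st1, st2_criteria = st2)
}

#' Classify one patient's statin-intolerance phenotypes
#'
#' Composes the rule primitives ([compute_coverage()], [count_switches()],
#' [detect_discontinuations()], [flag_ck()]) into the GSI/ST1 and LDI/ST2
#' assignment for a single patient. A general-statin-intolerance case has
#' an on-statin CK above the ULN plus two or more counted switches or
#' total discontinuation of statin therapy; a low-dose-intolerance case
#' used two or more distinct statins, at least one discontinued at (or
#' below) its lowest approved starting dose, irrespective of CK. ST1
#' controls have coverage above the threshold for the minimum years at
#' the minimum mean equivalent dose with no counted switch, no total
#' discontinuation and consistently normal on-statin CK; ST2 relaxes only
#' the CK criterion (so ST1 membership implies ST2 membership). Patients
#' meeting neither case nor control rules are unclassified; case rules
#' take precedence. Patients with fewer than two statin prescriptions do
#' not meet the study entry criterion and are marked `excluded`.
#'
#' @param prescriptions,labs single-patient tables.
#' @param sex `"M"` or `"F"`.
#' @param records_end end of the prescribing record.
#' @param rules a [rules_config()].
#' @param patient_id identifier copied into the output row.
#' @return One-row `data.table` with `gsi`, `ldi` status and all
#'   rule-evaluation flags (audit trail).
#' @export
classify_patient <- function(prescriptions, labs, sex, records_end,
                             rules = rules_config(), patient_id = NA_character_) {
  if (nrow(prescriptions) < 2) {
    log_warn("patient %s excluded: fewer than two statin prescriptions",
             patient_id)
    return(data.table(patient_id = patient_id, gsi = "excluded",
                      ldi = "excluded"))
  }
  rx <- as.data.table(prescriptions)
  rx[, start_date := as.Date(start_date)]
  setorder(rx, start_date, drug)
  cov <- compute_coverage(rx)
  sw <- count_switches(rx, rules)
  disc <- detect_discontinuations(rx, records_end, rules)
  disc_lowest <- nrow(disc) > 0 &&
    any(disc$daily_dose_mg <= rules$lowest_start_dose[disc$drug])
  # total discontinuation: a gap in all-statin coverage longer than the
  # permitted gap, including the tail up to records_end
  start_i <- as.integer(rx$start_date)
  end_i <- start_i + as.integer(rx$days_supply)
  o <- order(start_i)
  cm <- cummax(end_i[o])
  internal_gaps <- start_i[o][-1] - cm[-length(cm)]
  tail_gap <- as.integer(as.Date(records_end)) - max(end_i)
  total_disc <- any(c(internal_gaps, tail_gap) > rules$discontinuation_gap_days)
  equiv <- dose_equivalent(rx$drug, rx$daily_dose_mg, rules)
  ck <- flag_ck(labs, min(rx$start_date), sex, rules)
  on_ck <- labs[labs$analyte == "CK" &
                  as.Date(labs$date) >= min(rx$start_date), , drop = FALSE]
  any_ck <- labs[labs$analyte == "CK", , drop = FALSE]
  max_ck <- if (nrow(on_ck)) max(on_ck$value)
            else if (nrow(any_ck)) max(any_ck$value) else NA_real_
  flags <- data.table(
    patient_id = patient_id,
    coverage = cov$coverage, years_on_therapy = cov$therapy_years,
    mean_equiv_dose = sum(equiv * rx$days_supply) / sum(rx$days_supply),
    min_equiv_dose = min(equiv),
    switches_n = sw$switches, distinct_statins = sw$distinct_statins,
    discontinued_lowest_dose = disc_lowest,
    total_discontinuation = total_disc,
    ck_above_uln = ck$any_on_statin_above_uln,
    ck_ge_4x_uln = ck$any_on_statin_ge_4x_uln,
    ck_all_normal = ck$all_on_statin_normal,
    first_statin = rx$drug[1], last_statin = rx$drug[nrow(rx)],
    log10_ck = if (is.na(max_ck)) NA_real_ else log10(max_ck))
  st <- .apply_rules(flags, rules)
  cbind(data.table(patient_id = patient_id, gsi = st$gsi, ldi = st$ldi),
        flags[, -"patient_id"],
        data.table(st1_criteria = st$st1_criteria,
                   st2_criteria = st$st2_criteria))
}

#' Classify every patient in a cohort
#'
#' Vectorized implementation of the same rules as [classify_patient()],
#' evaluated with grouped `data.table` operations so whole simulated
#' cohorts classify in milliseconds. Classification is a pure function of
#' the inputs and the rules.
#'
#' @param bundle a [cohort_bundle()], or `NULL` if the component tables
#'   are passed directly.
#' @param prescriptions,labs,patients component tables (ignored when
#'   `bundle` is given); `patients` must carry `patient_id` and `sex`.
#' @param records_end end of the prescribing record window.
#' @param rules a [rules_config()].
#' @return `data.table` with one row per eligible patient: `gsi`, `ldi`
#'   status plus all rule flags. Patients with fewer than two
#'   prescriptions are excluded and reported in the `"excluded"`
#'   attribute and the log.
#' @export
classify_cohort <- function(bundle = NULL, prescriptions = NULL, labs = NULL,
                            patients = NULL, records_end = NULL,
                            rules = rules_config()) {
  if (!is.null(bundle)) {
    stopifnot(inherits(bundle, "cohort_bundle"))
    prescriptions <- bundle$prescriptions
    labs <- bundle$labs
    patients <- bundle$patients
    records_end <- records_end %||% bundle$records_end
  }
  rx <- as.data.table(prescriptions)
  rx[, start_date := as.Date(start_date)]
  labs <- as.data.table(labs)
  labs[, date := as.Date(date)]
  patients <- as.data.table(patients)
  records_end <- as.Date(records_end %||%
                           max(rx$start_date + rx$days_supply))
  re_i <- as.integer(records_end)

  n_rx <- rx[, .N, by = patient_id]
  excluded <- merge(patients[, .(patient_id)], n_rx, by = "patient_id",
                    all.x = TRUE)
  excluded[is.na(N), N := 0L]
  excluded <- excluded[N < 2L][, reason := "fewer than two statin prescriptions"]
  if (nrow(excluded))
    log_info("%d patient(s) excluded: fewer than two statin prescriptions",
             nrow(excluded))
  rx <- rx[patient_id %in% n_rx[N >= 2L, patient_id]]

  setorder(rx, patient_id, start_date, drug)
  rx[, `:=`(start_i = as.integer(start_date),
            end_i = as.integer(start_date) + as.integer(days_supply),
            equiv = daily_dose_mg * rules$dose_equivalence[drug])]
  if (any(rx$end_i > re_i))
    stopf("records_end precedes the end of a script's coverage")
  rx[, prev_cmax := shift(cummax(end_i), 1L), by = patient_id]
  rx[, prev_drug := shift(drug), by = patient_id]
  rx[, counted_switch := !is.na(prev_drug) & drug != prev_drug &
       !(prev_drug == "simvastatin" & drug == "atorvastatin" &
           start_date >= rules$atorvastatin_patent_date)]

  agg <- rx[, .(
    therapy_start = start_date[1],
    window = max(end_i) - min(start_i),
    union_days = sum(pmax(0L, end_i - pmax(start_i, fcoalesce(prev_cmax, start_i[1])))),
    max_internal_gap = max(c(0L, start_i[-1] - cummax(end_i)[-.N])),
    tail_gap = re_i - max(end_i),
    mean_equiv_dose = sum(equiv * days_supply) / sum(days_supply),
    min_equiv_dose = min(equiv),
    switches_n = sum(counted_switch),
    distinct_statins = uniqueN(drug),
    first_statin = drug[1], last_statin = drug[.N]
  ), by = patient_id]
  agg[, coverage := union_days / window]
  agg[, years_on_therapy := window / 365.25]
  agg[, total_discontinuation :=
        pmax(max_internal_gap, tail_gap) > rules$discontinuation_gap_days]

  # per-drug discontinuations at or below the lowest approved start dose
  rxd <- rx[order(patient_id, drug, start_i)]
  rxd[, next_start := shift(start_i, -1L), by = .(patient_id, drug)]
  rxd[, gap := fifelse(is.na(next_start), re_i - end_i, next_start - end_i)]
  rxd[, disc := gap > rules$discontinuation_gap_days]
  disc_agg <- rxd[, .(discontinued_lowest_dose =
                        any(disc & daily_dose_mg <= rules$lowest_start_dose[drug])),
                  by = patient_id]
  agg <- merge(agg, disc_agg, by = "patient_id", all.x = TRUE)

  # on-statin CK flags (tri-state) and log10 of the peak CK
  ck <- merge(labs[analyte == "CK"],
              agg[, .(patient_id, therapy_start)], by = "patient_id")
  ck_on <- ck[date >= therapy_start, .(max_on_ck = max(value)), by = patient_id]
  ck_any <- ck[, .(max_any_ck = max(value)), by = patient_id]
  agg <- Reduce(function(a, b) merge(a, b, by = "patient_id", all.x = TRUE),
                list(agg, ck_on, ck_any,
                     patients[, .(patient_id, sex)]))
  agg[, uln := fifelse(sex == "F", rules$ck_uln[["female"]],
                       rules$ck_uln[["male"]])]
  agg[, `:=`(ck_above_uln = max_on_ck > uln,
             ck_ge_4x_uln = max_on_ck >= rules$sim_fold_uln * uln,
             ck_all_normal = max_on_ck <= uln)]
  agg[, log10_ck := log10(fcoalesce(max_on_ck, max_any_ck))]

  st <- .apply_rules(agg, rules)
  agg[, `:=`(gsi = st$gsi, ldi = st$ldi,
             st1_criteria = st$st1_criteria, st2_criteria = st$st2_criteria)]
  out <- agg[, .(patient_id, gsi, ldi, coverage, years_on_therapy,
                 mean_equiv_dose, min_equiv_dose, switches_n,
                 distinct_statins, discontinued_lowest_dose,
                 total_discontinuation, ck_above_uln, ck_ge_4x_uln,
                 ck_all_normal, first_statin, last_statin, log10_ck,
                 st1_criteria, st2_criteria)]
  setorder(out, patient_id)
  log_info("classified %d patients: GSI %d case / %d control; LDI %d case / %d control",
           nrow(out), sum(out$gsi == "case"), sum(out$gsi == "control"),
           sum(out$ldi == "case"), sum(out$ldi == "control"))
  setattr(out, "excluded", excluded[, .(patient_id, reason)])
  out[]
}

#' Build the per-patient analysis table for one phenotype
#'
#' Joins phenotype assignments, genotypes and covariates into the
#' regression-ready table: one row per classified patient with a binary
#' outcome (case = 1, control = 0), the dominant genotype code and the
#' covariate columns. Unclassified or excluded patients and patients with
#' missing genotype are dropped, with counts logged.
#'
#' @param assignments output of [classify_cohort()].
#' @param genotypes table with `patient_id`, `genotype`.
#' @param covariates table with `patient_id`, `age`, `sex`, `t2d`,
#'   `comedication`.
#' @param phenotype `"gsi"` or `"ldi"`.
#' @return `data.table` with columns `patient_id`, `outcome`,
#'   `genotype_dom`, `age`, `female`, `t2d`, `comedication`,
#'   `first_statin`, `last_statin`, `mean_equiv_dose`, `log10_ck`.
#' @export
build_analysis_table <- function(assignments, genotypes, covariates,
                                 phenotype = c("gsi", "ldi")) {
  phenotype <- match.arg(phenotype)
  assignments <- as.data.table(assignments)
  genotypes <- as.data.table(genotypes)
  covariates <- as.data.table(covariates)
  for (nm in c("assignments", "genotypes", "covariates")) {
    if (anyDuplicated(get(nm)$patient_id))
      stopf("duplicated patient id in %s", nm)
  }
  status <- assignments[[phenotype]]
  keep <- assignments[status %in% c("case", "control")]
  n_uncl <- nrow(assignments) - nrow(keep)
  if (n_uncl > 0)
    log_info("%s: %d patient(s) unclassified, dropped", toupper(phenotype),
             n_uncl)
  tab <- merge(keep, genotypes[, .(patient_id, genotype)], by = "patient_id")
  tab[, genotype_dom := encode_dominant(genotype)]
  n_nog <- nrow(keep) - nrow(tab) + sum(is.na(tab$genotype_dom))
  if (n_nog > 0)
    log_info("%s: %d patient(s) without usable genotype, dropped",
             toupper(phenotype), n_nog)
  tab <- tab[!is.na(genotype_dom)]
  tab <- merge(tab, covariates, by = "patient_id")
  out <- tab[, .(patient_id,
                 outcome = as.integer(get(phenotype) == "case"),
                 genotype_dom, age, female = as.integer(sex == "F"),
                 t2d, comedication, first_statin, last_statin,
                 mean_equiv_dose, log10_ck)]
  setorder(out, patient_id)
  out[]
}
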