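library(data.table)

# one prescription row
rx_row <- function(id, drug, dose, start, supply) {
  data.table(patient_id = id, drug = drug, daily_dose_mg = dose,
             start_date = as.Date(start), days_supply = as.integer(supply))
}

# contiguous course of `k` scripts of `supply` days
rx_course <- function(id, drug, dose, start, k, supply = 56L) {
  start <- as.Date(start)
  rbindlist(lapply(seq_len(k), function(j)
    rx_row(id, drug, dose, start + (j - 1L) * supply, supply)))
}

lab_row <- function(id, date, value, analyte = "CK") {
  data.table(patient_id = id, date = as.Date(date), analyte = analyte,
             value = value)
}

# tolerant male patient: simvastatin 40 mg, ~6.2 years, ~93% coverage,
# no switches, ongoing at records_end, normal on-statin CK
fixture_tolerant <- function(id = "A", records_end = as.Date("2006-04-01")) {
  k <- 25L
  first <- records_end - 84L - (k - 1L) * 90L
  rx <- rbindlist(lapply(seq_len(k), function(j)
    rx_row(id, "simvastatin", 40, first + (j - 1L) * 90L, 84L)))
  labs <- rbind(lab_row(id, first + 200, 120), lab_row(id, first + 900, 150))
  list(rx = rx, labs = labs, sex = "M", records_end = records_end)
}

# GSI case: on-statin CK 1.5x ULN, two switches, then total discontinuation
fixture_gsi <- function(id = "B", records_end = as.Date("2010-01-01")) {
  rx <- rbind(rx_course(id, "simvastatin", 20, "2004-01-01", 4),
              rx_course(id, "pravastatin", 80, "2004-08-13", 4),
              rx_course(id, "fluvastatin", 40, "2005-03-26", 4))
  labs <- lab_row(id, "2004-06-01", 1.5 * 320)
  list(rx = rx, labs = labs, sex = "M", records_end = records_end)
}

# LDI case: rosuvastatin 5 mg discontinued, later atorvastatin 10 mg
# ongoing; CK always normal
fixture_ldi <- function(id = "C", records_end = as.Date("2010-01-01")) {
  k <- 30L
  first <- records_end - 56L - (k - 1L) * 56L
  ator <- rbindlist(lapply(seq_len(k), function(j)
    rx_row(id, "atorvastatin", 10, first + (j - 1L) * 56L, 56L)))
  rx <- rbind(rx_course(id, "rosuvastatin", 5, first - 300L, 4), ator)
  labs <- lab_row(id, first - 100, 100)
  list(rx = rx, labs = labs, sex = "F", records_end = records_end)
}

classify_fixture <- function(f, rules = rules_config()) {
  classify_patient(f$rx, f$labs, f$sex, f$records_end, rules,
                   patient_id = f$rx$patient_id[1])
}

# analysis table expanded from 2x2 cell counts
table_from_counts <- function(a, b, c, d) {
  data.table(
    patient_id = sprintf("X%04d", seq_len(a + b + c + d)),
    outcome = rep(c(1L, 1L, 0L, 0L), c(a, b, c, d)),
    genotype_dom = rep(c(1L, 0L, 1L, 0L), c(a, b, c, d)))
}

run_quiet <- function(expr) suppressMessages(expr)
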