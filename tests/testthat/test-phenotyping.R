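rules <- rules_config()

test_that("dose equivalence follows the potency ladder", {
  expect_equal(dose_equivalent("simvastatin", 40), 40)
  expect_equal(dose_equivalent("atorvastatin", 20), 40)
  expect_equal(dose_equivalent("rosuvastatin", 10), 40)
  expect_equal(dose_equivalent("pravastatin", 80), 40)
  expect_error(dose_equivalent("ezetimibe", 10), "ezetimibe")
})

test_that("coverage is the clipped interval union over the window", {
  win <- as.Date(c("2000-01-01", "2000-04-10"))  # 100 days
  one <- rx_row("p", "simvastatin", 40, "2000-01-05", 90)
  expect_equal(compute_coverage(one, win)$coverage, 0.90)

  two <- rbind(rx_row("p", "simvastatin", 40, "2000-01-01", 30),
               rx_row("p", "simvastatin", 40, "2000-01-01", 30))
  expect_equal(compute_coverage(two, as.Date(c("2000-01-01", "2000-03-01")))$coverage,
               30 / 60)

  tiling <- rbind(rx_row("p", "simvastatin", 40, "2000-01-01", 50),
                  rx_row("p", "simvastatin", 40, "2000-02-20", 50))
  expect_equal(compute_coverage(tiling)$coverage, 1.0)

  expect_equal(compute_coverage(one[0], win)$coverage, 0)
})

test_that("coverage is invariant under splitting a script into abutting scripts", {
  set.seed(42)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    starts <- as.Date("2000-01-01") + sort(sample(0:600, k))
    supplies <- sample(20:90, k, replace = TRUE)
    rx <- data.table(patient_id = "p", drug = "simvastatin",
                     daily_dose_mg = 40, start_date = starts,
                     days_supply = supplies)
    pick <- sample(k, 1)
    cut <- sample(supplies[pick] - 1, 1)
    split_rx <- rbind(
      rx[-pick],
      rx_row("p", "simvastatin", 40, starts[pick], cut),
      rx_row("p", "simvastatin", 40, starts[pick] + cut,
             supplies[pick] - cut))
    c1 <- compute_coverage(rx)
    c2 <- compute_coverage(split_rx)
    expect_equal(c1$coverage, c2$coverage)
    expect_true(c1$coverage >= 0 && c1$coverage <= 1)
  }
})

test_that("switch counting excludes the post-patent atorvastatin shift", {
  patent <- rbind(rx_row("p", "simvastatin", 40, "2011-01-01", 84),
                  rx_row("p", "simvastatin", 40, "2011-06-01", 84),
                  rx_row("p", "atorvastatin", 20, "2013-01-01", 84))
  sw <- count_switches(patent, rules)
  expect_equal(sw$switches, 0L)
  expect_equal(sw$distinct_statins, 2L)

  pre <- rbind(rx_row("p", "simvastatin", 40, "2005-01-01", 84),
               rx_row("p", "atorvastatin", 20, "2006-01-01", 84))
  expect_equal(count_switches(pre, rules)$switches, 1L)

  zigzag <- rbind(rx_row("p", "simvastatin", 40, "2005-01-01", 84),
                  rx_row("p", "pravastatin", 40, "2005-06-01", 84),
                  rx_row("p", "simvastatin", 40, "2006-01-01", 84))
  sw <- count_switches(zigzag, rules)
  expect_equal(sw$switches, 2L)
  expect_equal(sw$distinct_statins, 2L)

  single <- rx_course("p", "simvastatin", 40, "2005-01-01", 5)
  expect_equal(count_switches(single, rules)$switches, 0L)
  expect_equal(count_switches(single, rules)$distinct_statins, 1L)
})

test_that("switch count is invariant under duplicating a same-drug script", {
  rx <- rbind(rx_row("p", "simvastatin", 40, "2005-01-01", 84),
              rx_row("p", "pravastatin", 40, "2005-06-01", 84))
  dup <- rbind(rx, rx_row("p", "pravastatin", 40, "2005-06-01", 84))
  expect_equal(count_switches(rx, rules)$switches,
               count_switches(dup, rules)$switches)
})

test_that("discontinuation detection honours the gap boundary", {
  re <- as.Date("2010-01-01")
  lone <- rx_row("p", "rosuvastatin", 5, re - 256, 56)  # ends 200 d before
  ev <- detect_discontinuations(lone, re, rules)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$drug, "rosuvastatin")
  expect_equal(ev$daily_dose_mg, 5)

  ongoing <- rx_course("p", "simvastatin", 40, re - 224, 4)
  expect_equal(nrow(detect_discontinuations(ongoing, re, rules)), 0L)

  # tail gap exactly 90 days: strict >, no event
  boundary <- rx_row("p", "simvastatin", 40, re - 146, 56)
  expect_equal(nrow(detect_discontinuations(boundary, re, rules)), 0L)
  over <- rx_row("p", "simvastatin", 40, re - 147, 56)
  expect_equal(nrow(detect_discontinuations(over, re, rules)), 1L)

  expect_error(detect_discontinuations(rx_row("p", "simvastatin", 40,
                                              re - 10, 56), re, rules),
               "records_end")
})

test_that("CK flags respect therapy start and the 4x ULN boundary", {
  start <- as.Date("2005-01-01")
  f <- flag_ck(lab_row("p", "2005-06-01", 5 * 320), start, "M", rules)
  expect_true(f$any_on_statin_above_uln)
  expect_true(f$any_on_statin_ge_4x_uln)
  expect_false(f$all_on_statin_normal)

  # exactly 4x is inclusive
  f4 <- flag_ck(lab_row("p", "2005-06-01", 4 * 200), start, "F", rules)
  expect_true(f4$any_on_statin_ge_4x_uln)

  norm <- flag_ck(rbind(lab_row("p", "2005-03-01", 100),
                        lab_row("p", "2006-03-01", 150)), start, "M", rules)
  expect_true(norm$all_on_statin_normal)
  expect_false(norm$any_on_statin_above_uln)

  # pre-therapy elevation does not count; post-start normal keeps flags defined
  pre <- flag_ck(rbind(lab_row("p", "2004-06-01", 900),
                       lab_row("p", "2005-06-01", 120)), start, "M", rules)
  expect_false(pre$any_on_statin_above_uln)

  none <- flag_ck(lab_row("p", "2004-06-01", 900), start, "M", rules)
  expect_true(is.na(none$all_on_statin_normal))
})

test_that("fixture patients classify to their constructed phenotypes", {
  a <- classify_fixture(fixture_tolerant())
  expect_equal(a$gsi, "control")
  expect_equal(a$ldi, "control")
  expect_gt(a$coverage, 0.9)
  expect_gte(a$years_on_therapy, 5)
  expect_equal(a$mean_equiv_dose, 40)

  b <- classify_fixture(fixture_gsi())
  expect_equal(b$gsi, "case")
  expect_equal(b$ldi, "unclassified")
  expect_equal(b$switches_n, 2L)
  expect_true(b$total_discontinuation)

  c3 <- classify_fixture(fixture_ldi())
  expect_equal(c3$ldi, "case")
  expect_equal(c3$gsi, "unclassified")
  expect_true(c3$discontinued_lowest_dose)
  expect_false(c3$ck_above_uln)
})

test_that("patients with fewer than two prescriptions are excluded", {
  one <- rx_row("p1", "simvastatin", 40, "2005-01-01", 56)
  expect_message(
    res <- classify_patient(one, lab_row("p1", "2005-02-01", 100), "M",
                            as.Date("2010-01-01"), rules, "p1"),
    "excluded")
  expect_equal(res$gsi, "excluded")

  pats <- data.table(patient_id = c("p1", "p2"), sex = c("M", "F"))
  rx <- rbind(one, rx_course("p2", "simvastatin", 40, "2005-01-01", 4))
  labs <- rbind(lab_row("p1", "2005-02-01", 100),
                lab_row("p2", "2005-02-01", 100))
  a <- run_quiet(classify_cohort(prescriptions = rx, labs = labs,
                                 patients = pats,
                                 records_end = as.Date("2010-01-01")))
  expect_false("p1" %in% a$patient_id)
  expect_equal(attr(a, "excluded")$patient_id, "p1")
})

test_that("vectorized cohort classification agrees with the per-patient route", {
  b <- suppressWarnings(run_quiet(simulate_observational_cohort(
    simulation_config(n_patients = 150, seed = 17))))
  vec <- run_quiet(classify_cohort(b))
  for (pid in b$patients$patient_id[seq(1, 150, by = 3)]) {
    one <- classify_patient(
      b$prescriptions[b$prescriptions$patient_id == pid],
      b$labs[b$labs$patient_id == pid],
      b$patients$sex[b$patients$patient_id == pid],
      b$records_end, rules, pid)
    row <- vec[vec$patient_id == pid]
    expect_equal(one$gsi, row$gsi, info = pid)
    expect_equal(one$ldi, row$ldi, info = pid)
    expect_equal(one$coverage, row$coverage, info = pid)
    expect_equal(one$switches_n, row$switches_n, info = pid)
    expect_equal(one$mean_equiv_dose, row$mean_equiv_dose, info = pid)
  }
})

test_that("classification is deterministic and ST1 is nested in ST2", {
  b <- run_quiet(simulate_observational_cohort(
    simulation_config(n_patients = 800, seed = 23)))
  a1 <- run_quiet(classify_cohort(b))
  a2 <- run_quiet(classify_cohort(b))
  expect_identical(a1, a2)
  expect_true(all(a1$ldi[a1$gsi == "control"] == "control"))
  expect_true(all(a1$st2_criteria[a1$st1_criteria]))
})

test_that("generator truth labels round-trip through the classifier", {
  for (s in c(31, 32)) {
    b <- run_quiet(simulate_observational_cohort(
      simulation_config(n_patients = 1200, seed = s)))
    a <- run_quiet(classify_cohort(b))
    tr <- merge(b$truth, a, by = "patient_id")
    expect_true(all((tr$gsi == "case") == tr$is_gsi_case))
    expect_true(all((tr$ldi == "case") == tr$is_ldi_case))
    expect_true(all(tr$gsi[tr$class == "ST"] == "control"))
    expect_true(all(tr$ldi[tr$class == "ST"] == "control"))
    expect_true(all(tr$gsi[tr$class == "indeterminate"] == "unclassified"))
  }
})

test_that("analysis tables drop unclassified and genotype-missing patients with logs", {
  assignments <- data.table(
    patient_id = sprintf("p%d", 1:5),
    gsi = c("case", "control", "control", "unclassified", "unclassified"),
    ldi = c("case", "control", "control", "unclassified", "unclassified"),
    first_statin = "simvastatin", last_statin = "simvastatin",
    mean_equiv_dose = 40, log10_ck = 2)
  genotypes <- data.table(patient_id = sprintf("p%d", 1:5),
                          genotype = c("T/T", "T/C", "C/C", "T/T", "T/T"))
  covs <- data.table(patient_id = sprintf("p%d", 1:5), age = 60,
                     sex = "F", t2d = 1L, comedication = 0L)
  expect_message(tab <- build_analysis_table(assignments, genotypes, covs,
                                             "gsi"),
                 "2 patient\\(s\\) unclassified")
  expect_equal(nrow(tab), 3L)
  expect_equal(sum(tab$outcome), 1L)

  expect_message(
    tab2 <- build_analysis_table(assignments, genotypes[-2], covs, "gsi"),
    "without usable genotype")
  expect_equal(nrow(tab2), 2L)

  expect_error(build_analysis_table(rbind(assignments, assignments[1]),
                                    genotypes, covs, "gsi"),
               "duplicated")
})
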