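test_that("dominant coding contrasts Asp247 homozygotes with Gly carriers", {
  expect_equal(encode_dominant(c("T/T", "T/C", "C/C", "C/T")),
               c(1L, 0L, 0L, 0L))
  expect_true(is.na(encode_dominant("T/G")))
})

test_that("MAF and exact HWE test match enumeration and a permutation oracle", {
  hw <- estimate_maf_and_hwe(rep(c("T/T", "T/C", "C/C"), c(25, 50, 25)))
  expect_equal(hw$maf, 0.5)
  expect_gt(hw$hwe_p, 0.95)

  expect_equal(estimate_maf_and_hwe(rep("T/T", 30))$maf, 0)
  expect_equal(estimate_maf_and_hwe(rep("T/T", 30))$hwe_p, 1)

  extreme <- estimate_maf_and_hwe(rep(c("T/T", "C/C"), c(50, 50)))
  expect_lt(extreme$hwe_p, 1e-10)

  # Monte-Carlo oracle: permute the alleles into random pairs and measure
  # the probability-ordered tail of the heterozygote-count distribution
  counts <- c(tt = 11L, tc = 13L, cc = 6L)
  alleles <- rep(c("T", "C"), c(2 * counts["tt"] + counts["tc"],
                                2 * counts["cc"] + counts["tc"]))
  set.seed(1)
  hets <- replicate(40000, {
    perm <- sample(alleles)
    sum(perm[c(TRUE, FALSE)] != perm[c(FALSE, TRUE)])
  })
  tab <- table(hets) / length(hets)
  p_obs <- tab[[as.character(counts["tc"])]]
  p_mc <- sum(tab[tab <= p_obs + 1e-9])
  p_impl <- estimate_maf_and_hwe(
    rep(c("T/T", "T/C", "C/C"), counts))$hwe_p
  expect_equal(p_impl, p_mc, tolerance = 0.02)
  expect_error(estimate_maf_and_hwe(character(0)), "no genotype")
})

test_that("contingency odds ratios follow Woolf arithmetic", {
  est <- contingency_or(96, 133, 161, 271)
  # independent arithmetic oracle
  expect_equal(est$point, 96 * 271 / (133 * 161), tolerance = 1e-12)
  expect_equal(est$se, sqrt(1 / 96 + 1 / 133 + 1 / 161 + 1 / 271))
  expect_equal(round(est$point, 3), 1.215)
  expect_equal(round(est$ci_lo, 3), 0.876)
  expect_equal(round(est$ci_hi, 3), 1.685)

  expect_equal(contingency_or(10, 10, 10, 10)$point, 1.0)

  expect_message(deg <- contingency_or(1, 0, 10, 10), "Haldane")
  expect_true(is.finite(deg$point))

  expect_error(contingency_or(0, 0, 5, 5), "total is zero")
})

test_that("odds ratio inverts under swapping the exposure labels", {
  set.seed(7)
  for (i in 1:20) {
    cells <- sample(1:200, 4)
    a <- contingency_or(cells[1], cells[2], cells[3], cells[4])
    b <- contingency_or(cells[2], cells[1], cells[4], cells[3])
    expect_equal(a$point, 1 / b$point, tolerance = 1e-12)
    expect_equal(a$se, b$se)
  }
})

test_that("effect estimates keep exp/log and CI consistency", {
  set.seed(9)
  for (i in 1:20) {
    e <- effect_estimate("x", rnorm(1, sd = 0.5), runif(1, 0.2, 1))
    expect_equal(e$point, exp(e$beta))
    expect_equal(e$ci_lo, exp(e$beta - qnorm(0.975) * e$se))
    expect_equal(e$ci_hi, exp(e$beta + qnorm(0.975) * e$se))
    expect_equal(sqrt(e$ci_lo * e$ci_hi), e$point, tolerance = 1e-12)
    expect_true(e$ci_lo < e$point && e$point < e$ci_hi)
    expect_true(e$p > 0 && e$p <= 1)
  }
  expect_error(effect_estimate("x", 0, -1), "positive")
})

test_that("logistic regression on a collapsed 2x2 equals the crude odds ratio", {
  tab <- table_from_counts(40, 60, 55, 80)
  fit <- fit_logistic(tab)
  crude <- contingency_or(40, 60, 55, 80)
  expect_equal(fit$estimates$genotype_dom$beta, crude$beta,
               tolerance = 1e-6)
  expect_equal(fit$estimates$genotype_dom$se, crude$se, tolerance = 1e-4)
})

test_that("logistic fitting flags degenerate designs", {
  tab <- table_from_counts(30, 30, 30, 30)
  tab$copy_g <- tab$genotype_dom
  expect_error(fit_logistic(tab, "copy_g"), "collinear")
  sep <- data.table::data.table(outcome = rep(0:1, each = 30),
                                genotype_dom = rep(0:1, each = 30))
  expect_error(fit_logistic(sep), "separation")
  expect_error(fit_logistic(tab[tab$outcome == 1, ]), "both classes")
})

test_that("genotype Wald test holds its size under the null", {
  set.seed(101)
  reject <- pval <- numeric(200)
  for (i in 1:200) {
    d <- data.table::data.table(outcome = rbinom(2000, 1, 0.1),
                                genotype_dom = rbinom(2000, 1, 0.4),
                                age = rnorm(2000, 60, 10))
    pval[i] <- fit_logistic(d, "age")$estimates$genotype_dom$p
  }
  rate <- mean(pval < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.10)
})

test_that("backwards elimination removes noise and keeps signal deterministically", {
  set.seed(55)
  keep_strong <- drop_noise <- logical(20)
  for (i in 1:20) {
    n <- 4000
    g <- rbinom(n, 1, 0.4)
    strong <- rnorm(n)
    noise <- rnorm(n)
    y <- rbinom(n, 1, plogis(-2 + 0.4 * g + 1 * strong))
    d <- data.table::data.table(outcome = y, genotype_dom = g,
                                strong = strong, noise = noise)
    sel <- backward_eliminate(d, full_terms = c("strong", "noise"))
    keep_strong[i] <- "strong" %in% sel$terms
    drop_noise[i] <- !"noise" %in% sel$terms
  }
  expect_gte(sum(keep_strong), 19)
  expect_gte(sum(drop_noise), 18)

  # deterministic: identical data give identical traces
  d <- data.table::data.table(outcome = rbinom(500, 1, 0.2),
                              genotype_dom = rbinom(500, 1, 0.4),
                              a = rnorm(500), b = rnorm(500))
  s1 <- backward_eliminate(d, c("a", "b"))
  s2 <- backward_eliminate(d, c("a", "b"))
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$terms, s2$terms)
  # genotype is always retained even when only noise accompanies it
  expect_true("genotype_dom" %in% s1$terms)
  expect_error(backward_eliminate(d, "a", forced_terms = "zz"), "subset")
})

test_that("all-significant models are returned unchanged by elimination", {
  set.seed(77)
  n <- 3000
  g <- rbinom(n, 1, 0.4)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 0.5 * g + 0.8 * x))
  d <- data.table::data.table(outcome = y, genotype_dom = g, x = x)
  sel <- backward_eliminate(d, "x")
  expect_equal(nrow(sel$trace), 0L)
  expect_setequal(sel$terms, c("genotype_dom", "x"))
})

test_that("interaction model is null when stratum effects are equal", {
  betas <- vapply(1:20, function(s) {
    tr <- simulate_trial_cohort(trial_config(trial_hr_tt = 1,
                                             trial_hr_carrier = 1,
                                             trial_hr_genotype = 1.35,
                                             seed = 500 + s))
    fit_interaction_model(tr)$estimates$interaction$beta
  }, numeric(1))
  expect_lt(abs(mean(betas)), 0.06)
  single <- simulate_trial_cohort(trial_config(n_patients = 500, seed = 1))
  single$arm <- "placebo"
  expect_error(fit_interaction_model(single), "single-arm")
})

test_that("stratified hazard fit matches the closed-form rate ratio without censoring", {
  set.seed(33)
  n <- 6000
  treated <- rep(0:1, each = n / 2)
  rate <- ifelse(treated == 1, 0.8 * 0.5, 0.5)
  d <- data.table::data.table(
    patient_id = sprintf("s%d", 1:n),
    arm = ifelse(treated == 1, "rosuvastatin", "placebo"),
    genotype_dom = 1L,
    time_years = rexp(n, rate), myalgia = 1L,
    final_ck = 10^rnorm(n, 2, 0.2))
  est <- fit_stratified_hazard(d, "tt")
  # with full follow-up the exponential MLE of the HR is the event-rate ratio
  rr <- (sum(d$myalgia[treated == 1]) / sum(d$time_years[treated == 1])) /
        (sum(d$myalgia[treated == 0]) / sum(d$time_years[treated == 0]))
  expect_equal(est$point, rr, tolerance = 0.03)
  expect_equal(est$point, 0.8, tolerance = 0.08)
  expect_equal(est$scale, "log-hazard")

  no_events <- d[d$myalgia == 1 & treated == 0][1:10]
  no_events$myalgia[1:5] <- 0L
  no_events$arm[1:5] <- "rosuvastatin"
  expect_error(fit_stratified_hazard(no_events, "tt"), "no events")
})
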