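#' Dominant genotype coding
#'
#' All association tests contrast Asp247 homozygotes (T/T, coded 1, the
#' exposure group) against Gly carriers (T/C or C/C, coded 0).
#'
#' @param genotype character vector of `"T/T"`, `"T/C"` (or `"C/T"`),
#'   `"C/C"`.
#' @return integer vector of 0/1; unknown or missing genotypes give `NA`
#'   and are excluded downstream.
#' @examples
#' encode_dominant(c("T/T", "T/C", "C/C"))
#' @export
encode_dominant <- function(genotype) {
  code <- c("T/T" = 1L, "T/C" = 0L, "C/T" = 0L, "C/C" = 0L)
  unname(code[as.character(genotype)])
}

# exact test of Hardy-Weinberg proportions conditional on allele counts:
# sum the probabilities of all heterozygote counts no more likely than
# the observed one
.hwe_exact_p <- function(n_het, n_hom_ref, n_hom_alt) {
  n <- n_het + n_hom_ref + n_hom_alt
  n_rare <- n_het + 2L * min(n_hom_ref, n_hom_alt)
  if (n_rare == 0L) return(1)
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  n_a <- n_rare; n_b <- 2L * n - n_rare
  hom_r <- (n_a - hets) / 2
  hom_c <- (n_b - hets) / 2
  lp <- lfactorial(n) - lfactorial(hom_r) - lfactorial(hets) -
    lfactorial(hom_c) + hets * log(2) +
    lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' Minor allele frequency and exact Hardy-Weinberg test
#'
#' @param calls character vector of genotypes, or a data frame with a
#'   `genotype` column.
#' @return list with `maf` (minor allele frequency), `hwe_p` (exact-test
#'   p-value conditional on allele counts) and the genotype `counts`.
#' @examples
#' g <- c(rep("T/T", 25), rep("T/C", 50), rep("C/C", 25))
#' estimate_maf_and_hwe(g)
#' @export
estimate_maf_and_hwe <- function(calls) {
  if (is.data.frame(calls)) calls <- calls$genotype
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0) stopf("no genotype calls")
  calls[calls == "C/T"] <- "T/C"
  bad <- setdiff(unique(calls), c("T/T", "T/C", "C/C"))
  if (length(bad)) stopf("invalid genotype(s): %s", paste(bad, collapse = ", "))
  n_tt <- sum(calls == "T/T")
  n_tc <- sum(calls == "T/C")
  n_cc <- sum(calls == "C/C")
  n <- n_tt + n_tc + n_cc
  p_alt <- (n_tc + 2 * n_cc) / (2 * n)
  list(maf = min(p_alt, 1 - p_alt),
       hwe_p = .hwe_exact_p(n_tc, n_tt, n_cc),
       counts = c(`T/T` = n_tt, `T/C` = n_tc, `C/C` = n_cc))
}

#' Crude odds ratio from a 2x2 contingency table
#'
#' `OR = (a*d)/(b*c)` with the Woolf standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)` on the log scale. When a cell is zero
#' the Haldane-Anscombe correction adds 0.5 to every cell (logged as a
#' warning).
#'
#' @param a,b,c,d cell counts laid out as case-exposed, case-unexposed,
#'   control-exposed, control-unexposed.
#' @param level confidence level.
#' @return An [effect_estimate()] labelled `"crude OR"`.
#' @examples
#' contingency_or(96, 133, 161, 271)
#' @export
contingency_or <- function(a, b, c, d, level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || anyNA(cells)) stopf("cell counts must be >= 0")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    stopf("a row or column total is zero; odds ratio undefined")
  if (any(cells == 0)) {
    if (sum(cells == 0) > 1)
      log_warn("more than one zero cell; Haldane-Anscombe correction applied to all cells")
    else
      log_warn("zero cell; Haldane-Anscombe 0.5 correction applied to all cells")
    cells <- cells + 0.5
  }
  beta <- log(cells[["a"]] * cells[["d"]] / (cells[["b"]] * cells[["c"]]))
  se <- sqrt(sum(1 / cells))
  effect_estimate("crude OR", beta, se, n = as.integer(a + b + c + d),
                  level = level)
}

#' Covariate-adjusted logistic association model
#'
#' Maximum-likelihood logistic regression of the binary phenotype on the
#' dominant genotype code plus covariates, reporting Wald standard errors
#' and two-sided p-values per coefficient. CK should enter through the
#' pre-computed `log10_ck` column.
#'
#' @param table analysis table from [build_analysis_table()] (or any data
#'   frame with the named columns).
#' @param terms character vector of covariate column names; the genotype
#'   column is always included first.
#' @param outcome,genotype column names of the 0/1 outcome and the
#'   dominant genotype code.
#' @param level confidence level for the reported intervals.
#' @return An object of class `assoc_fit`: list with the `glm` `fit`, a
#'   named list of [effect_estimate()]s (one per non-intercept
#'   coefficient), `terms` and `n`.
#' @export
fit_logistic <- function(table, terms = character(0), outcome = "outcome",
                         genotype = "genotype_dom", level = 0.95) {
  table <- as.data.frame(table)
  rhs <- unique(c(genotype, terms))
  missing_cols <- setdiff(c(outcome, rhs), names(table))
  if (length(missing_cols))
    stopf("missing column(s): %s", paste(missing_cols, collapse = ", "))
  dat <- table[stats::complete.cases(table[, c(outcome, rhs), drop = FALSE]),
               c(outcome, rhs), drop = FALSE]
  for (nm in rhs) if (is.character(dat[[nm]])) dat[[nm]] <- factor(dat[[nm]])
  if (length(unique(dat[[outcome]])) < 2)
    stopf("outcome must contain both classes")
  f <- stats::reformulate(rhs, response = outcome)
  fit <- suppressWarnings(stats::glm(f, family = stats::binomial(), data = dat))
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stopf("rank-deficient design; collinear term(s): %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  if (!fit$converged || any(abs(cf[-1]) > 15))
    stopf("(quasi-)complete separation suspected for term '%s'",
          names(which.max(abs(cf[-1]))))
  sm <- stats::coef(summary(fit))
  keep <- setdiff(rownames(sm), "(Intercept)")
  ests <- lapply(keep, function(nm)
    effect_estimate(nm, sm[nm, 1], sm[nm, 2], n = stats::nobs(fit),
                    level = level))
  names(ests) <- keep
  structure(list(fit = fit, estimates = ests, terms = rhs,
                 n = stats::nobs(fit), outcome = outcome,
                 genotype = genotype),
            class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("Logistic association model (n = %d)\n", x$n))
  for (e in x$estimates) print(e)
  invisible(x)
}

# joint Wald p-value per model term; indicator blocks of a factor are
# tested as one block (chi-square with df = number of levels - 1)
term_wald_p <- function(fit) {
  asn <- attr(stats::model.matrix(fit), "assign")
  labs <- attr(stats::terms(fit), "term.labels")
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  p <- vapply(seq_along(labs), function(i) {
    idx <- which(asn == i)
    bi <- b[idx]
    stat <- drop(crossprod(bi, solve(V[idx, idx, drop = FALSE], bi)))
    stats::pchisq(stat, df = length(idx), lower.tail = FALSE)
  }, numeric(1))
  stats::setNames(p, labs)
}

#' Backwards stepwise covariate elimination
#'
#' Starting from the full covariate set, iteratively refits the logistic
#' model and removes the single non-forced term with the largest joint
#' Wald p-value above `alpha`, until every remaining removable term is
#' significant. The genotype term is always forced. Removal is
#' deterministic (largest-p-first); multi-level factors are removed as a
#' block on the block's joint Wald p-value.
#'
#' @inheritParams fit_logistic
#' @param full_terms covariates in the starting model.
#' @param forced_terms covariates never removed (genotype is forced
#'   implicitly).
#' @param alpha retention threshold for the Wald p-value (default 0.05).
#' @return list with `fit` (final `assoc_fit`), `terms` (retained,
#'   genotype first), `trace` (data frame of removals in order) and
#'   `alpha`.
#' @export
backward_eliminate <- function(table, full_terms,
                               forced_terms = character(0), alpha = 0.05,
                               outcome = "outcome",
                               genotype = "genotype_dom") {
  if (!all(forced_terms %in% full_terms))
    stopf("forced_terms must be a subset of full_terms")
  current <- setdiff(full_terms, genotype)
  trace <- list()
  repeat {
    fitobj <- fit_logistic(table, current, outcome = outcome,
                           genotype = genotype)
    p <- term_wald_p(fitobj$fit)
    removable <- p[setdiff(names(p), c(genotype, forced_terms))]
    if (length(removable) == 0 || max(removable) <= alpha) break
    worst <- names(removable)[which.max(removable)]
    trace[[length(trace) + 1L]] <- data.frame(step = length(trace) + 1L,
                                              removed = worst,
                                              p = unname(removable[worst]))
    current <- setdiff(current, worst)
  }
  list(fit = fitobj, terms = c(genotype, current),
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(step = integer(), removed = character(),
                               p = numeric()),
       alpha = alpha)
}

.prep_trial <- function(trial) {
  d <- as.data.frame(trial)
  need <- c("arm", "myalgia", "final_ck")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stopf("trial table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (!"genotype_dom" %in% names(d)) {
    if (!"genotype" %in% names(d)) stopf("trial table lacks a genotype column")
    d$genotype_dom <- encode_dominant(d$genotype)
  }
  if (length(unique(d$arm)) < 2) stopf("single-arm input: need both arms")
  d$treated <- as.integer(d$arm != "placebo")
  d$log10_ck <- log10(d$final_ck)
  d
}

#' Genotype-by-treatment interaction model for trial myalgia
#'
#' Logistic model
#' `myalgia ~ genotype_dom + treatment + log10(final CK) +
#' genotype_dom:treatment`, reporting beta, OR, CI and p for each term.
#' A negative interaction coefficient means the statin's effect on
#' myalgia is weaker among Asp247 homozygotes than among Gly carriers.
#'
#' @param trial trial table from [simulate_trial_cohort()] (columns
#'   `arm`, `myalgia`, `final_ck`, and `genotype_dom` or `genotype`).
#' @param level confidence level.
#' @return An `assoc_fit` whose estimates are named `genotype`,
#'   `treatment`, `log10_ck`, `interaction`.
#' @export
fit_interaction_model <- function(trial, level = 0.95) {
  d <- .prep_trial(trial)
  fit <- suppressWarnings(stats::glm(
    myalgia ~ genotype_dom + treated + log10_ck + genotype_dom:treated,
    family = stats::binomial(), data = d))
  sm <- stats::coef(summary(fit))
  nm_map <- c(genotype = "genotype_dom", treatment = "treated",
              log10_ck = "log10_ck", interaction = "genotype_dom:treated")
  ests <- lapply(names(nm_map), function(nm)
    effect_estimate(nm, sm[nm_map[[nm]], 1], sm[nm_map[[nm]], 2],
                    n = stats::nobs(fit), level = level))
  names(ests) <- names(nm_map)
  structure(list(fit = fit, estimates = ests,
                 terms = unname(nm_map), n = stats::nobs(fit),
                 outcome = "myalgia", genotype = "genotype_dom"),
            class = "assoc_fit")
}

#' Treatment hazard ratio within a genotype stratum
#'
#' Cox proportional-hazards fit of treatment (statin vs placebo) on time
#' to myalgia within one genotype stratum, adjusted for log10 final CK.
#'
#' @param trial trial table (columns `arm`, `time_years`, `myalgia`,
#'   `final_ck`, `genotype_dom`/`genotype`).
#' @param stratum `"tt"` (Asp247 homozygotes) or `"carrier"` (Gly
#'   carriers).
#' @param level confidence level.
#' @return An [effect_estimate()] on the log-hazard scale for treatment.
#' @export
fit_stratified_hazard <- function(trial, stratum = c("tt", "carrier"),
                                  level = 0.95) {
  stratum <- match.arg(stratum)
  d <- .prep_trial(trial)
  if (!all(c("time_years") %in% names(d)))
    stopf("trial table lacks 'time_years'")
  d <- d[d$genotype_dom == (stratum == "tt"), , drop = FALSE]
  if (nrow(d) == 0) stopf("empty genotype stratum")
  ev <- tapply(d$myalgia, d$treated, sum)
  if (length(ev) < 2 || any(ev == 0))
    stopf("no events in one arm of the %s stratum", stratum)
  fit <- survival::coxph(survival::Surv(time_years, myalgia) ~
                           treated + log10_ck, data = d)
  sm <- stats::coef(summary(fit))
  effect_estimate(sprintf("rosuvastatin vs placebo (%s)", stratum),
                  sm["treated", "coef"], sm["treated", "se(coef)"],
                  n = nrow(d), scale = "log-hazard", level = level)
}
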