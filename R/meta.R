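#' Reconstruct the log-OR standard error from a printed confidence
#' interval
#'
#' `SE = (ln(ci_hi) - ln(ci_lo)) / (2 * z)` with `z` the two-sided normal
#' quantile for the interval's level. Warns when the printed point
#' estimate is more than 2% away from the geometric mean of the bounds,
#' which indicates heavy display rounding or a non-Wald interval.
#'
#' @param or_point point estimate (odds or hazard ratio).
#' @param ci_lo,ci_hi interval bounds.
#' @param level confidence level of the interval (default 0.95).
#' @return standard error(s) of the log effect.
#' @examples
#' se_from_ci(1.43, 1.10, 1.86)
#' @export
se_from_ci <- function(or_point, ci_lo, ci_hi, level = 0.95) {
  if (any(ci_lo <= 0) || any(ci_hi <= 0))
    stopf("confidence bounds must be positive")
  if (any(ci_hi <= ci_lo)) stopf("ci_hi must exceed ci_lo")
  assert_fraction(level, "level")
  asym <- abs(or_point - sqrt(ci_lo * ci_hi)) / or_point
  if (any(asym > 0.02))
    log_warn("point estimate differs from the geometric mean of the CI by >2%% (study %s)",
             paste(which(asym > 0.02), collapse = ", "))
  (log(ci_hi) - log(ci_lo)) / (2 * z_crit(level))
}

.as_study_table <- function(effects) {
  eff <- as.data.table(effects)
  if ("or_point" %in% names(eff) && !"or" %in% names(eff))
    setnames(eff, "or_point", "or")
  need <- c("study", "or", "ci_lo", "ci_hi")
  missing_cols <- setdiff(need, names(eff))
  if (length(missing_cols))
    stopf("study table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (nrow(eff) == 0) stopf("no studies to pool")
  if (any(eff$ci_lo > eff$or | eff$or > eff$ci_hi))
    stopf("each study must satisfy ci_lo <= or <= ci_hi")
  if (!"n" %in% names(eff)) eff[, n := NA_integer_]
  eff
}

#' Inverse-variance fixed-effects meta-analysis of odds ratios
#'
#' Per-study log odds ratios (`beta_i = ln(or_i)`, reconstructed from the
#' printed point estimate, with the CI supplying only the standard error)
#' are pooled with weights `w_i = 1/SE_i^2`:
#' `pooled beta = sum(w_i beta_i) / sum(w_i)`,
#' `pooled SE = 1/sqrt(sum(w_i))`, with a two-sided z-test and Cochran's
#' `Q = sum(w_i (beta_i - pooled beta)^2)` reported descriptively.
#'
#' @param effects data frame of per-study estimates: `study`, `or` (or
#'   `or_point`), `ci_lo`, `ci_hi`, optional `n`.
#' @param level confidence level of the input intervals and the pooled
#'   interval.
#' @return An object of class `meta_result`: list with `pooled` (an
#'   [effect_estimate()]), `studies` (the input table augmented with
#'   `beta`, `se`, `weight`, `weight_fraction`), `q_stat`, `q_df`, `q_p`
#'   and `z`.
#' @examples
#' studies <- data.frame(
#'   study = c("discovery LDI", "replication 1", "replication 2", "trial"),
#'   or = c(1.43, 1.03, 1.48, 1.35),
#'   ci_lo = c(1.10, 0.72, 1.05, 1.07),
#'   ci_hi = c(1.86, 1.49, 2.10, 1.71))
#' pool_fixed_effects(studies)
#' @export
pool_fixed_effects <- function(effects, level = 0.95) {
  eff <- .as_study_table(effects)
  eff[, beta := log(or)]
  eff[, se := se_from_ci(or, ci_lo, ci_hi, level)]
  eff[, weight := 1 / se^2]
  eff[, weight_fraction := weight / sum(weight)]
  w <- eff$weight
  pb <- sum(w * eff$beta) / sum(w)
  pse <- 1 / sqrt(sum(w))
  q <- sum(w * (eff$beta - pb)^2)
  q_df <- nrow(eff) - 1L
  total_n <- if (all(is.na(eff$n))) NA_integer_ else sum(eff$n, na.rm = TRUE)
  structure(
    list(pooled = effect_estimate("pooled (fixed effects)", pb, pse,
                                  n = total_n, level = level),
         studies = eff[],
         q_stat = q, q_df = q_df,
         q_p = if (q_df > 0) stats::pchisq(q, q_df, lower.tail = FALSE) else NA_real_,
         z = pb / pse),
    class = "meta_result")
}

#' @export
print.meta_result <- function(x, digits = 2, ...) {
  cat("Fixed-effects meta-analysis\n")
  for (i in seq_len(nrow(x$studies))) {
    s <- x$studies[i]
    cat(sprintf("  %-22s OR %.2f (%.2f-%.2f)  weight %.1f%%\n",
                s$study, s$or, s$ci_lo, s$ci_hi, 100 * s$weight_fraction))
  }
  p <- x$pooled
  cat(sprintf("  Pooled OR %.2f (%d%% CI %.2f-%.2f), z = %.2f, p = %.2g\n",
              round_half_up(p$point, digits), round(100 * p$level),
              round_half_up(p$ci_lo, digits), round_half_up(p$ci_hi, digits),
              x$z, p$p))
  if (x$q_df > 0)
    cat(sprintf("  Heterogeneity Q = %.2f (df = %d), p = %.2g\n",
                x$q_stat, x$q_df, x$q_p))
  invisible(x)
}

#' Forest table of per-study and pooled estimates
#'
#' One row per study in input order plus a pooled summary row;
#' serializable to TSV for forest-plot rendering.
#'
#' @param effects the study table passed to [pool_fixed_effects()].
#' @param pooled the corresponding [pool_fixed_effects()] result.
#' @return `data.frame` with columns `study`, `or`, `ci_lo`, `ci_hi`,
#'   `weight_pct`, `n`.
#' @export
make_forest_table <- function(effects, pooled) {
  stopifnot(inherits(pooled, "meta_result"))
  eff <- .as_study_table(effects)
  if (nrow(eff) != nrow(pooled$studies) ||
      !isTRUE(all.equal(eff$or, pooled$studies$or)))
    stopf("pooled result was not computed from these effects")
  p <- pooled$pooled
  data.frame(
    study = c(eff$study, "Pooled (fixed effects)"),
    or = c(eff$or, p$point),
    ci_lo = c(eff$ci_lo, p$ci_lo),
    ci_hi = c(eff$ci_hi, p$ci_hi),
    weight_pct = c(100 * pooled$studies$weight_fraction, 100),
    n = c(eff$n, p$n),
    stringsAsFactors = FALSE)
}
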