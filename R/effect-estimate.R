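#' Construct an effect estimate on the log-odds or log-hazard scale
#'
#' The common currency of the association and meta-analysis stages: a
#' labelled coefficient with its Wald standard error, exponentiated point
#' estimate (odds or hazard ratio), Wald confidence interval and two-sided
#' p-value.
#'
#' @param label character label for the term (e.g. `"genotype_dom"`).
#' @param beta coefficient on the log scale.
#' @param se positive standard error of `beta`.
#' @param n number of observations behind the estimate (optional).
#' @param scale `"log-odds"` or `"log-hazard"`.
#' @param level confidence level, default 0.95.
#' @return An object of class `effect_estimate`: a list with elements
#'   `label`, `scale`, `beta`, `se`, `point` (`exp(beta)`), `ci_lo`,
#'   `ci_hi`, `p`, `n`, `level`.
#' @examples
#' effect_estimate("genotype_dom", beta = 0.30, se = 0.12)
#' @export
effect_estimate <- function(label, beta, se, n = NA_integer_,
                            scale = c("log-odds", "log-hazard"),
                            level = 0.95) {
  scale <- match.arg(scale)
  if (!is.finite(beta)) stopf("beta for '%s' is not finite", label)
  if (!is.finite(se) || se <= 0) stopf("se for '%s' must be positive", label)
  assert_fraction(level, "level")
  z <- z_crit(level)
  structure(
    list(label = as.character(label), scale = scale,
         beta = beta, se = se,
         point = exp(beta),
         ci_lo = exp(beta - z * se),
         ci_hi = exp(beta + z * se),
         p = 2 * stats::pnorm(-abs(beta / se)),
         n = n, level = level),
    class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, digits = 2, ...) {
  unit <- if (x$scale == "log-hazard") "HR" else "OR"
  cat(sprintf("%s: %s %.2f (%d%% CI %.2f-%.2f), p = %.2g%s\n",
              x$label, unit,
              round_half_up(x$point, digits),
              round(100 * x$level),
              round_half_up(x$ci_lo, digits),
              round_half_up(x$ci_hi, digits),
              x$p,
              if (is.na(x$n)) "" else sprintf(", n = %d", x$n)))
  invisible(x)
}

#' @export
as.data.frame.effect_estimate <- function(x, ...) {
  data.frame(label = x$label, scale = x$scale, beta = x$beta, se = x$se,
             point = x$point, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
             p = x$p, n = x$n, stringsAsFactors = FALSE)
}

estimates_to_df <- function(estimates) {
  do.call(rbind, lapply(estimates, as.data.frame))
}
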