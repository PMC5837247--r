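#' @importFrom stats qnorm pnorm plogis rbinom rexp rnorm runif uniroot
#'   glm binomial coef vcov pchisq reformulate as.formula setNames
#'   complete.cases
#' @importFrom utils read.csv write.csv packageVersion
#' @import data.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Display rounding used when comparing against published tables, which
#' round 1.345 to 1.35 (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

z_crit <- function(level) stats::qnorm((1 + level) / 2)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

log_info <- function(...) message("INFO: ", sprintf(...))
log_warn <- function(...) message("WARN: ", sprintf(...))

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single fraction in [0, 1], got %s", name,
          paste(format(x), collapse = ", "))
  invisible(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0))
    stopf("'%s' must be strictly positive", name)
  invisible(x)
}

as_date_safe <- function(x, what) {
  out <- tryCatch(as.Date(x), error = function(e) NULL)
  if (is.null(out) || anyNA(out))
    stopf("could not parse %s as ISO-8601 dates", what)
  out
}
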