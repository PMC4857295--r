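# Shared validation and display helpers.

check_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(name, " must be a single non-missing number", call. = FALSE)
  invisible(x)
}

check_numeric <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x))
    stop(name, " must be numeric with no missing values", call. = FALSE)
  invisible(x)
}

check_prevalence <- function(prevalence) {
  check_number(prevalence, "prevalence")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly inside (0, 1), got ", prevalence,
         call. = FALSE)
  invisible(prevalence)
}

check_level <- function(level) {
  check_number(level, "level")
  if (level <= 0 || level >= 1)
    stop("confidence level must lie strictly inside (0, 1), got ", level,
         call. = FALSE)
  invisible(level)
}

# Round half away from zero (all quantities here are positive, so half-up).
# base::round() rounds half to even, which does not reproduce the field's
# conventional printed values (e.g. 1/0.8 -> 1.3).  A relative epsilon
# absorbs floating-point dust just below the .5 boundary (e.g. 1/PPV at
# sensitivity = specificity = 0.8, prevalence 0.05 evaluates to
# 5.749999999999997 where the exact value is 5.75).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  scaled <- abs(x) * m
  out <- floor(scaled + 0.5 + scaled * 1e-12) / m * sign(x)
  out[is.infinite(x)] <- x[is.infinite(x)]
  out
}

#' Display formatting used throughout reports
#'
#' NNT values print with one decimal up to 100 and three significant digits
#' above; infinite values print as `"Inf"`.  Predictive values print as whole
#' percents; sensitivity and specificity as percents with one decimal.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @name formatting
NULL

#' @rdname formatting
#' @export
fmt_nnt <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return("Inf")
    if (v <= 100) sprintf("%.1f", round_half_up(v, 1))
    else format(signif(v, 3), scientific = FALSE, trim = TRUE)
  }, character(1L))
}

#' @rdname formatting
#' @export
fmt_percent <- function(x) {
  sprintf("%.0f%%", round_half_up(100 * x, 0))
}

#' @rdname formatting
#' @export
fmt_percent1 <- function(x) {
  sprintf("%.1f%%", round_half_up(100 * x, 1))
}

# Strip classes and non-name attributes recursively; used to compare and
# serialize report structures.
strip_classes <- function(x) {
  if (is.list(x)) {
    out <- lapply(x, strip_classes)
    attributes(out) <- list(names = names(out))
    out
  } else {
    attributes(x) <- if (is.null(names(x))) NULL else list(names = names(x))
    x
  }
}
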