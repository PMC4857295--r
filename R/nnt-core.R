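# Core NNT <-> predictive-value mappings and the discomfort-range calculus.
#
# The number needed to treat (NNT) in a test-defined subgroup is the expected
# number of patients one must treat for one to benefit.  In a group of
# NNT_Pos treated test-positive patients exactly one is a true positive, so
# PPV = 1/NNT_Pos; among NNT_Neg untreated test-negative patients exactly one
# is a false negative, so NPV = 1 - 1/NNT_Neg.

#' Construct and validate an NNT discomfort range
#'
#' The discomfort range `(nnt_lower, nnt_upper)` is the elicited interval of
#' NNT values for which neither treating everyone nor withholding treatment
#' from everyone is ethically comfortable.  A useful test must push the
#' test-positive group below `nnt_lower` and the test-negative group above
#' `nnt_upper`.
#'
#' Both endpoints must be finite, at least 1 (an NNT is an expected count of
#' patients treated per patient benefitted), and strictly ordered
#' `nnt_lower < nnt_upper`.  Elicited values violating the ordering -- e.g.
#' a stated PPV of 15\% and NPV of 70\%, which translate to
#' `nnt_lower = 6.7 > nnt_upper = 3.3` -- are rejected as an inconsistent
#' range, because they would demand that a *positive* result tolerate more
#' overtreatment than a *negative* one.
#'
#' @param nnt_lower Lower endpoint: largest NNT at which treating the whole
#'   group is still comfortable.
#' @param nnt_upper Upper endpoint: smallest NNT at which withholding
#'   treatment from the whole group is comfortable.
#' @return An object of class `discomfort_range` with fields `nnt_lower`
#'   and `nnt_upper`.
#' @examples
#' discomfort_range(2, 30)
#' try(discomfort_range(6.7, 3.3))  # inconsistent elicitation
#' @export
discomfort_range <- function(nnt_lower, nnt_upper) {
  check_number(nnt_lower, "nnt_lower")
  check_number(nnt_upper, "nnt_upper")
  if (!is.finite(nnt_lower) || !is.finite(nnt_upper))
    stop("discomfort range endpoints must be finite, got (",
         nnt_lower, ", ", nnt_upper, ")", call. = FALSE)
  if (nnt_lower < 1 || nnt_upper < 1)
    stop("NNT values below 1 are not meaningful: got (",
         nnt_lower, ", ", nnt_upper, ")", call. = FALSE)
  if (nnt_lower >= nnt_upper)
    stop("inconsistent range: nnt_lower (", fmt_nnt(nnt_lower),
         ") must be strictly smaller than nnt_upper (", fmt_nnt(nnt_upper),
         "); the elicited values do not describe a discomfort interval",
         call. = FALSE)
  structure(list(nnt_lower = nnt_lower, nnt_upper = nnt_upper),
            class = "discomfort_range")
}

#' Alias for [discomfort_range()], emphasising the validation step
#' @inheritParams discomfort_range
#' @return A validated `discomfort_range`.
#' @export
validate_discomfort_range <- function(nnt_lower, nnt_upper) {
  discomfort_range(nnt_lower, nnt_upper)
}

#' @export
print.discomfort_range <- function(x, ...) {
  cat("NNT discomfort range: (", fmt_nnt(x$nnt_lower), ", ",
      fmt_nnt(x$nnt_upper), ")\n", sep = "")
  invisible(x)
}

#' Construct an NNT pair for the test-positive and test-negative groups
#'
#' @param nnt_pos NNT among test-positive patients; finite, `>= 1`.
#' @param nnt_neg NNT among test-negative patients; `> 1`, may be `Inf`
#'   (a test whose negatives are never `BestToAct`, i.e. NPV = 1).
#'   Values may be vectors of equal length.
#' @return An object of class `nnt_pair`.
#' @export
nnt_pair <- function(nnt_pos, nnt_neg) {
  check_numeric(nnt_pos, "nnt_pos")
  check_numeric(nnt_neg, "nnt_neg")
  stopifnot(length(nnt_pos) == length(nnt_neg))
  if (any(!is.finite(nnt_pos)))
    stop("nnt_pos must be finite (an infinite NNT_Pos has no clinical meaning here)",
         call. = FALSE)
  if (any(nnt_pos < 1))
    stop("nnt_pos must be >= 1, got ", min(nnt_pos), call. = FALSE)
  if (any(nnt_neg <= 1))
    stop("nnt_neg must be > 1, got ", min(nnt_neg), call. = FALSE)
  structure(list(nnt_pos = nnt_pos, nnt_neg = nnt_neg), class = "nnt_pair")
}

#' @export
print.nnt_pair <- function(x, ...) {
  cat("NNT pair: positive group ", fmt_nnt(x$nnt_pos[1L]),
      ", negative group ", fmt_nnt(x$nnt_neg[1L]), "\n", sep = "")
  if (length(x$nnt_pos) > 1L)
    cat("  (", length(x$nnt_pos), " pairs in total)\n", sep = "")
  invisible(x)
}

#' Construct a pair of predictive values
#'
#' @param ppv Positive predictive value(s), in (0, 1].
#' @param npv Negative predictive value(s), in (0, 1].
#' @return An object of class `predictive_values`.
#' @export
predictive_values <- function(ppv, npv) {
  check_numeric(ppv, "ppv")
  check_numeric(npv, "npv")
  stopifnot(length(ppv) == length(npv))
  if (any(ppv <= 0 | ppv > 1))
    stop("ppv must lie in (0, 1], got ", ppv[which(ppv <= 0 | ppv > 1)[1L]],
         call. = FALSE)
  if (any(npv <= 0 | npv > 1))
    stop("npv must lie in (0, 1], got ", npv[which(npv <= 0 | npv > 1)[1L]],
         call. = FALSE)
  structure(list(ppv = ppv, npv = npv), class = "predictive_values")
}

#' @export
print.predictive_values <- function(x, ...) {
  cat("Predictive values: PPV ", fmt_percent(x$ppv[1L]),
      ", NPV ", fmt_percent(x$npv[1L]), "\n", sep = "")
  if (length(x$ppv) > 1L)
    cat("  (", length(x$ppv), " pairs in total)\n", sep = "")
  invisible(x)
}

#' Positive predictive value implied by an NNT in the test-positive group
#'
#' In a group of `nnt_pos` treated test-positive patients exactly one
#' benefits (one true positive), so `PPV = 1/nnt_pos`.
#'
#' @param nnt_pos NNT among test-positive patients; finite, `>= 1`.
#'   Vectorised.
#' @return `1/nnt_pos`, a probability in (0, 1].
#' @examples
#' ppv_from_nnt_pos(2)    # 0.5
#' ppv_from_nnt_pos(5.8)  # about 0.172
#' @export
ppv_from_nnt_pos <- function(nnt_pos) {
  check_numeric(nnt_pos, "nnt_pos")
  if (any(!is.finite(nnt_pos) | nnt_pos < 1))
    stop("nnt_pos must be finite and >= 1, got ",
         nnt_pos[which(!is.finite(nnt_pos) | nnt_pos < 1)[1L]], call. = FALSE)
  1 / nnt_pos
}

#' Negative predictive value implied by an NNT in the test-negative group
#'
#' Among `nnt_neg` untreated test-negative patients exactly one would have
#' benefitted (one false negative), so `NPV = 1 - 1/nnt_neg`.  An infinite
#' `nnt_neg` corresponds to a perfect negative arm, `NPV = 1`.
#'
#' @param nnt_neg NNT among test-negative patients; `> 1` or `Inf`.
#'   Vectorised.
#' @return `1 - 1/nnt_neg`, a probability in (0, 1].
#' @examples
#' npv_from_nnt_neg(30)   # about 0.967, i.e. 97%
#' npv_from_nnt_neg(Inf)  # exactly 1
#' @export
npv_from_nnt_neg <- function(nnt_neg) {
  check_numeric(nnt_neg, "nnt_neg")
  if (any(nnt_neg <= 1))
    stop("nnt_neg must be > 1, got ", nnt_neg[which(nnt_neg <= 1)[1L]],
         call. = FALSE)
  out <- 1 - 1 / nnt_neg
  out[is.infinite(nnt_neg)] <- 1
  out
}

#' NNT pair implied by a pair of predictive values
#'
#' Inverts the PPV/NPV mappings: `nnt_pos = 1/ppv` and
#' `nnt_neg = 1/(1 - npv)` (infinite when `npv = 1`).
#'
#' @param pv A [predictive_values()] object, or a PPV when `npv` is given.
#' @param npv Optional NPV when `pv` is given as a bare PPV.
#' @return An [nnt_pair()].
#' @examples
#' nnt_pair_from_predictive_values(0.15, 0.70)  # (6.7, 3.3): inconsistent range
#' @export
nnt_pair_from_predictive_values <- function(pv, npv = NULL) {
  if (!inherits(pv, "predictive_values")) pv <- predictive_values(pv, npv)
  nnt_neg <- ifelse(pv$npv == 1, Inf, 1 / (1 - pv$npv))
  nnt_pair(1 / pv$ppv, nnt_neg)
}

#' Minimum predictive values required by a discomfort range
#'
#' A test is clinically useful when `nnt_pos < nnt_lower` and
#' `nnt_neg > nnt_upper`.  Equivalently the predictive values must exceed
#' `PPV > 1/nnt_lower` and `NPV > 1 - 1/nnt_upper`; this returns those two
#' strict lower thresholds.
#'
#' @param dr A [discomfort_range()].
#' @return A [predictive_values()] object carrying the thresholds, with
#'   attribute `threshold = "strict lower bound"`.
#' @examples
#' required_predictive_values(discomfort_range(2, 30))  # PPV > 50%, NPV > 97%
#' @export
required_predictive_values <- function(dr) {
  stopifnot(inherits(dr, "discomfort_range"))
  out <- predictive_values(1 / dr$nnt_lower, 1 - 1 / dr$nnt_upper)
  attr(out, "threshold") <- "strict lower bound"
  out
}

#' Does an NNT pair clear the discomfort range?
#'
#' Implements the clinical-usefulness criterion
#' `nnt_pos < nnt_lower < nnt_upper < nnt_neg` with strict inequalities on
#' both sides, and reports which side (if any) fails.
#'
#' @param nnt An [nnt_pair()] (scalar fields).
#' @param dr A [discomfort_range()].
#' @return An object of class `clinical_usefulness`: a list with logical
#'   `useful`, per-side logicals `positive_ok` and `negative_ok`, and a
#'   human-readable `message`.
#' @examples
#' is_clinically_useful(nnt_pair(7, 17), discomfort_range(8, 16))
#' @export
is_clinically_useful <- function(nnt, dr) {
  stopifnot(inherits(nnt, "nnt_pair"), inherits(dr, "discomfort_range"),
            length(nnt$nnt_pos) == 1L)
  positive_ok <- nnt$nnt_pos < dr$nnt_lower
  negative_ok <- nnt$nnt_neg > dr$nnt_upper
  failed <- c(if (!positive_ok) "positive group (NNT_Pos not below nnt_lower)",
              if (!negative_ok) "negative group (NNT_Neg not above nnt_upper)")
  msg <- if (positive_ok && negative_ok) {
    "test clears the discomfort range on both sides"
  } else {
    paste("test fails on:", paste(failed, collapse = " and "))
  }
  structure(list(useful = positive_ok && negative_ok,
                 positive_ok = positive_ok,
                 negative_ok = negative_ok,
                 message = msg),
            class = "clinical_usefulness")
}

#' @export
print.clinical_usefulness <- function(x, ...) {
  cat(if (x$useful) "Clinically useful: " else "Not clinically useful: ",
      x$message, "\n", sep = "")
  invisible(x)
}
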