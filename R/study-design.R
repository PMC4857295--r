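# Prospective and retrospective design summaries: anticipated counts, exact
# (Clopper-Pearson) confidence intervals, their transforms to the NNT scale,
# and Monte-Carlo Bayes predictive intervals for NNT under independent
# Jeffreys posteriors on sensitivity and specificity.

#' Construct a binomial outcome (successes out of trials)
#'
#' @param successes Non-negative integer count of successes.
#' @param trials Positive integer count of trials, `>= successes`.
#' @return An object of class `binomial_outcome` with an `estimate` field
#'   `successes/trials`.
#' @export
binomial_outcome <- function(successes, trials) {
  check_number(successes, "successes")
  check_number(trials, "trials")
  if (trials < 1 || trials != round(trials))
    stop("trials must be a positive integer, got ", trials, call. = FALSE)
  if (successes < 0 || successes > trials || successes != round(successes))
    stop("successes must be an integer in [0, trials], got ", successes,
         " of ", trials, call. = FALSE)
  structure(list(successes = successes, trials = trials,
                 estimate = successes / trials),
            class = "binomial_outcome")
}

#' @export
print.binomial_outcome <- function(x, ...) {
  cat(x$successes, "/", x$trials, " = ", fmt_percent(x$estimate), "\n",
      sep = "")
  invisible(x)
}

#' Construct an interval estimate
#'
#' @param lower,upper Interval endpoints, `lower <= upper`.
#' @param level Coverage level in (0, 1).
#' @param method Character tag, e.g. `"exact-binomial"` or
#'   `"bayes-predictive"`.
#' @param estimate Optional point estimate.
#' @return An object of class `interval_estimate`.
#' @export
interval_estimate <- function(lower, upper, level, method, estimate = NULL) {
  check_level(level)
  if (lower > upper)
    stop("interval lower bound exceeds upper bound", call. = FALSE)
  structure(list(lower = lower, upper = upper, level = level,
                 method = method, estimate = estimate),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%.0f%% %s interval: (%s, %s)\n", 100 * x$level, x$method,
              format(signif(x$lower, 4)),
              if (is.finite(x$upper)) format(signif(x$upper, 4)) else "Inf"))
  invisible(x)
}

#' Exact (Clopper-Pearson) confidence interval for a binomial proportion
#'
#' Two-sided exact interval from the beta-quantile closed form:
#' lower `= qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`) and upper
#' `= qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).  The interval is
#' conservative: its coverage is at least the nominal level for every true
#' proportion.
#'
#' @param x Number of successes, or a [binomial_outcome()].
#' @param n Number of trials (ignored when `x` is a `binomial_outcome`).
#' @param level Two-sided confidence level, default 0.95.
#' @return An [interval_estimate()] with method `"exact-binomial"`.
#' @examples
#' exact_binomial_ci(5, 10)   # (0.19, 0.81) at whole-percent rounding
#' exact_binomial_ci(29, 30)  # (0.83, 1.00)
#' @export
exact_binomial_ci <- function(x, n = NULL, level = 0.95) {
  o <- if (inherits(x, "binomial_outcome")) x else binomial_outcome(x, n)
  check_level(level)
  alpha <- 1 - level
  lower <- if (o$successes == 0) 0 else
    stats::qbeta(alpha / 2, o$successes, o$trials - o$successes + 1)
  upper <- if (o$successes == o$trials) 1 else
    stats::qbeta(1 - alpha / 2, o$successes + 1, o$trials - o$successes)
  interval_estimate(lower, upper, level, "exact-binomial",
                    estimate = o$estimate)
}

#' Transform a predictive-value interval to the NNT scale
#'
#' The positive side uses the order-reversing reciprocal
#' `NNT_Pos = 1/PPV`, so a PPV interval `(l, u)` becomes `(1/u, 1/l)`.
#' The negative side uses `NNT_Neg = 1/(1 - NPV)`, so an NPV interval
#' `(l, u)` becomes `(1/(1 - l), 1/(1 - u))`; an NPV upper bound of 1 gives
#' an infinite NNT upper bound.
#'
#' @param iv An [interval_estimate()] on the probability scale.
#' @param side `"pos"` (PPV -> NNT_Pos) or `"neg"` (NPV -> NNT_Neg).
#' @return An [interval_estimate()] on the NNT scale, same level and method.
#' @examples
#' nnt_interval_from_pv_interval(exact_binomial_ci(5, 10), "pos")
#' @export
nnt_interval_from_pv_interval <- function(iv, side = c("pos", "neg")) {
  stopifnot(inherits(iv, "interval_estimate"))
  side <- match.arg(side)
  if (side == "pos") {
    if (iv$lower <= 0)
      stop("cannot transform a PPV interval with lower bound 0 to the NNT ",
           "scale (NNT_Pos would be unbounded)", call. = FALSE)
    out <- interval_estimate(1 / iv$upper, 1 / iv$lower, iv$level, iv$method,
                             estimate = if (!is.null(iv$estimate) &&
                                            iv$estimate > 0)
                               1 / iv$estimate)
  } else {
    if (iv$lower < 0 || iv$upper > 1)
      stop("NPV interval must lie within [0, 1]", call. = FALSE)
    upper <- if (iv$upper == 1) Inf else 1 / (1 - iv$upper)
    out <- interval_estimate(1 / (1 - iv$lower), upper, iv$level, iv$method,
                             estimate = if (!is.null(iv$estimate) &&
                                            iv$estimate < 1)
                               1 / (1 - iv$estimate)
                             else if (!is.null(iv$estimate)) Inf)
  }
  attr(out, "scale") <- "nnt"
  out
}

#' Specify a prospective validation design
#'
#' A cohort of `n_total` patients is tested and followed; the test is hoped
#' to split them into a fraction `positive_fraction` of positives achieving
#' `nnt_pos` and negatives achieving `nnt_neg`.
#'
#' @param n_total Total number of patients recruited (`>= 2`).
#' @param positive_fraction Anticipated fraction testing positive, in (0, 1).
#' @param target An [nnt_pair()] of hoped-for NNT values, or `nnt_pos` when
#'   `nnt_neg` is supplied.
#' @param nnt_neg Optional, with a bare `nnt_pos` passed as `target`.
#' @param followup_note Free-text note on follow-up duration.
#' @return An object of class `prospective_design`.
#' @examples
#' prospective_design(40, 0.25, nnt_pair(2, 30))
#' @export
prospective_design <- function(n_total, positive_fraction, target,
                               nnt_neg = NULL, followup_note = "") {
  check_number(n_total, "n_total")
  check_number(positive_fraction, "positive_fraction")
  if (n_total < 2 || n_total != round(n_total))
    stop("n_total must be an integer >= 2", call. = FALSE)
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop("positive_fraction must lie strictly inside (0, 1)", call. = FALSE)
  if (!inherits(target, "nnt_pair")) target <- nnt_pair(target, nnt_neg)
  structure(list(n_total = n_total, positive_fraction = positive_fraction,
                 target = target, followup_note = followup_note),
            class = "prospective_design")
}

#' Anticipated counts in a prospective design
#'
#' Splits the cohort into `n_pos = round(n_total * positive_fraction)`
#' positives and `n_neg = n_total - n_pos` negatives, then assumes estimates
#' match the hoped-for NNT values: the positive group contributes
#' `round(n_pos / nnt_pos)` true positives out of `n_pos`, and the negative
#' group `n_neg - round(n_neg / nnt_neg)` true negatives out of `n_neg`
#' (the NPV numerator).  Rounding is to the nearest integer, ties away from
#' zero.
#'
#' @param d A [prospective_design()].
#' @return A list with [binomial_outcome()] elements `positives` (PPV
#'   numerator/denominator) and `negatives` (NPV numerator/denominator).
#' @examples
#' anticipated_prospective_counts(prospective_design(40, 0.25, nnt_pair(2, 30)))
#' @export
anticipated_prospective_counts <- function(d) {
  stopifnot(inherits(d, "prospective_design"))
  n_pos <- round_half_up(d$n_total * d$positive_fraction)
  n_neg <- d$n_total - n_pos
  if (n_pos < 1 || n_neg < 1)
    stop("design yields an empty test-positive or test-negative group",
         call. = FALSE)
  x_pos <- round_half_up(n_pos / d$target$nnt_pos)
  x_neg <- n_neg - if (is.finite(d$target$nnt_neg))
    round_half_up(n_neg / d$target$nnt_neg) else 0
  if (x_pos < 0 || x_pos > n_pos || x_neg < 0 || x_neg > n_neg)
    stop("anticipated success count falls outside [0, group size]; the ",
         "target NNT pair is inconsistent with the group sizes",
         call. = FALSE)
  list(positives = binomial_outcome(x_pos, n_pos),
       negatives = binomial_outcome(x_neg, n_neg))
}

#' Prospective design summary
#'
#' Composes [anticipated_prospective_counts()], [exact_binomial_ci()] and
#' [nnt_interval_from_pv_interval()]: exact confidence intervals for PPV and
#' NPV at the anticipated counts, their NNT-scale transforms, and (when a
#' discomfort range is supplied) whether the NNT interval endpoints clear it.
#'
#' @param d A [prospective_design()].
#' @param dr Optional [discomfort_range()] to check clearance against.
#' @param level Two-sided confidence level, default 0.95.
#' @return An object of class `prospective_summary`.
#' @examples
#' prospective_summary(prospective_design(40, 0.25, nnt_pair(2, 30)),
#'                     discomfort_range(2, 30))
#' @export
prospective_summary <- function(d, dr = NULL, level = 0.95) {
  stopifnot(inherits(d, "prospective_design"))
  if (!is.null(dr)) stopifnot(inherits(dr, "discomfort_range"))
  counts <- anticipated_prospective_counts(d)
  ppv_ci <- exact_binomial_ci(counts$positives, level = level)
  npv_ci <- exact_binomial_ci(counts$negatives, level = level)
  nnt_pos_ci <- nnt_interval_from_pv_interval(ppv_ci, "pos")
  nnt_neg_ci <- nnt_interval_from_pv_interval(npv_ci, "neg")
  clears <- if (is.null(dr)) NULL else
    list(positive = nnt_pos_ci$upper < dr$nnt_lower,
         negative = nnt_neg_ci$lower > dr$nnt_upper)
  structure(list(design = d, counts = counts,
                 ppv_ci = ppv_ci, npv_ci = npv_ci,
                 nnt_pos_ci = nnt_pos_ci, nnt_neg_ci = nnt_neg_ci,
                 discomfort_range = dr, clears = clears, level = level),
            class = "prospective_summary")
}

#' @export
print.prospective_summary <- function(x, ...) {
  d <- x$design
  cat("Prospective design: n =", d$n_total, "with",
      fmt_percent(d$positive_fraction), "anticipated positive\n")
  cat("  target NNT_Pos ", fmt_nnt(d$target$nnt_pos), ", NNT_Neg ",
      fmt_nnt(d$target$nnt_neg), "\n", sep = "")
  cat("  anticipated PPV ", x$counts$positives$successes, "/",
      x$counts$positives$trials, ": ", fmt_percent(x$ppv_ci$lower), "-",
      fmt_percent(x$ppv_ci$upper), " CI, NNT_Pos (",
      fmt_nnt(x$nnt_pos_ci$lower), ", ", fmt_nnt(x$nnt_pos_ci$upper), ")\n",
      sep = "")
  cat("  anticipated NPV ", x$counts$negatives$successes, "/",
      x$counts$negatives$trials, ": ", fmt_percent(x$npv_ci$lower), "-",
      fmt_percent(x$npv_ci$upper), " CI, NNT_Neg (",
      fmt_nnt(x$nnt_neg_ci$lower), ", ", fmt_nnt(x$nnt_neg_ci$upper), ")\n",
      sep = "")
  if (!is.null(x$clears))
    cat("  clears discomfort range: positive side ", x$clears$positive,
        ", negative side ", x$clears$negative, "\n", sep = "")
  invisible(x)
}

#' Specify a retrospective (case-control) validation design
#'
#' Cases are `BestToAct` patients sampled by known outcome, controls are
#' `BestToWait`; the study estimates sensitivity from the cases and
#' specificity from the controls, and a stated prevalence is needed to
#' recover predictive values.
#'
#' @param n_cases,n_controls Group sizes.
#' @param sn_successes Anticipated positives among cases (SN numerator).
#' @param sp_successes Anticipated negatives among controls (SP numerator).
#' @param prevalence Prevalence of `BestToAct` in the deployment population.
#' @return An object of class `retrospective_design` with
#'   [binomial_outcome()] fields `anticipated_sn` and `anticipated_sp`.
#' @examples
#' retrospective_design(22, 40, 18, 34, 0.15)
#' @export
retrospective_design <- function(n_cases, n_controls, sn_successes,
                                 sp_successes, prevalence) {
  check_prevalence(prevalence)
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 anticipated_sn = binomial_outcome(sn_successes, n_cases),
                 anticipated_sp = binomial_outcome(sp_successes, n_controls),
                 prevalence = prevalence),
            class = "retrospective_design")
}

#' Monte-Carlo Bayes predictive intervals for NNT from a retrospective design
#'
#' Draws sensitivity and specificity independently from their Jeffreys
#' posteriors, `SN ~ Beta(x_sn + 1/2, n_sn - x_sn + 1/2)` and
#' `SP ~ Beta(x_sp + 1/2, n_sp - x_sp + 1/2)`, applies forward Bayes at the
#' design prevalence, maps each draw to `NNT_Pos = 1/PPV` and
#' `NNT_Neg = 1/(1 - NPV)`, and returns equal-tailed quantile intervals.
#' Results are reproducible for a fixed `seed` and `n_draws`; the caller's
#' RNG state is left untouched.
#'
#' @param d A [retrospective_design()].
#' @param level Interval level, default 0.95 (equal-tailed).
#' @param n_draws Number of posterior draws, default 1e5.  A warning is
#'   issued below 10,000 draws.
#' @param seed Integer seed for the draws; default 1.
#' @return A list with [interval_estimate()] elements `nnt_pos` and
#'   `nnt_neg` (method `"bayes-predictive"`, point estimates at the
#'   anticipated proportions), plus the `level`, `n_draws` and `seed` used.
#' @examples
#' d <- retrospective_design(22, 40, 18, 34, 0.15)
#' bayes_predictive_nnt_intervals(d, n_draws = 10000, seed = 1)
#' @export
bayes_predictive_nnt_intervals <- function(d, level = 0.95, n_draws = 1e5,
                                           seed = 1L) {
  stopifnot(inherits(d, "retrospective_design"))
  check_level(level)
  check_number(n_draws, "n_draws")
  if (n_draws < 1) stop("n_draws must be at least 1", call. = FALSE)
  if (n_draws < 1e4)
    warning("fewer than 10,000 draws: interval endpoints will be noisy",
            call. = FALSE)
  check_number(seed, "seed")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  sn <- stats::rbeta(n_draws, d$anticipated_sn$successes + 0.5,
                     d$anticipated_sn$trials - d$anticipated_sn$successes + 0.5)
  sp <- stats::rbeta(n_draws, d$anticipated_sp$successes + 0.5,
                     d$anticipated_sp$trials - d$anticipated_sp$successes + 0.5)
  ppv <- bayes_ppv_(sn, sp, d$prevalence)
  npv <- bayes_npv_(sn, sp, d$prevalence)
  alpha <- 1 - level
  q_pos <- stats::quantile(1 / ppv, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  q_neg <- stats::quantile(1 / (1 - npv), c(alpha / 2, 1 - alpha / 2),
                           names = FALSE)
  est <- bayes_forward(d$anticipated_sn$estimate, d$anticipated_sp$estimate,
                       d$prevalence)
  list(nnt_pos = interval_estimate(q_pos[1L], q_pos[2L], level,
                                   "bayes-predictive",
                                   estimate = 1 / est$ppv),
       nnt_neg = interval_estimate(q_neg[1L], q_neg[2L], level,
                                   "bayes-predictive",
                                   estimate = 1 / (1 - est$npv)),
       level = level, n_draws = n_draws, seed = as.integer(seed))
}

#' Retrospective design summary
#'
#' Composes exact confidence intervals for the anticipated sensitivity and
#' specificity, the required sensitivity/specificity from the contra-Bayes
#' inversion of the discomfort-range thresholds (when a discomfort range is
#' supplied), and the Monte-Carlo Bayes predictive intervals for NNT.
#'
#' @param d A [retrospective_design()].
#' @param dr Optional [discomfort_range()]; when given, required SN/SP are
#'   computed via [required_predictive_values()] and [contra_bayes()] at the
#'   design prevalence, and the anticipated estimates are flagged against
#'   them.
#' @inheritParams bayes_predictive_nnt_intervals
#' @return An object of class `retrospective_summary`.
#' @examples
#' retrospective_summary(retrospective_design(22, 40, 18, 34, 0.15),
#'                       discomfort_range(2, 30), n_draws = 10000)
#' @export
retrospective_summary <- function(d, dr = NULL, level = 0.95, n_draws = 1e5,
                                  seed = 1L) {
  stopifnot(inherits(d, "retrospective_design"))
  if (!is.null(dr)) stopifnot(inherits(dr, "discomfort_range"))
  sn_ci <- exact_binomial_ci(d$anticipated_sn, level = level)
  sp_ci <- exact_binomial_ci(d$anticipated_sp, level = level)
  required <- NULL
  meets_required <- NULL
  if (!is.null(dr)) {
    required <- contra_bayes(required_predictive_values(dr),
                             prevalence = d$prevalence)
    meets_required <- list(
      sensitivity = d$anticipated_sn$estimate >= required$sensitivity,
      specificity = d$anticipated_sp$estimate >= required$specificity)
  }
  predictive <- bayes_predictive_nnt_intervals(d, level = level,
                                               n_draws = n_draws, seed = seed)
  structure(list(design = d, sn_ci = sn_ci, sp_ci = sp_ci,
                 required = required, meets_required = meets_required,
                 predictive = predictive, discomfort_range = dr,
                 level = level),
            class = "retrospective_summary")
}

#' @export
print.retrospective_summary <- function(x, ...) {
  d <- x$design
  cat("Retrospective design:", d$n_cases, "cases,", d$n_controls,
      "controls, prevalence", fmt_percent(d$prevalence), "\n")
  cat("  anticipated SN ", d$anticipated_sn$successes, "/", d$n_cases, ": ",
      fmt_percent(x$sn_ci$lower), "-", fmt_percent(x$sn_ci$upper), " CI\n",
      sep = "")
  cat("  anticipated SP ", d$anticipated_sp$successes, "/", d$n_controls,
      ": ", fmt_percent(x$sp_ci$lower), "-", fmt_percent(x$sp_ci$upper),
      " CI\n", sep = "")
  if (!is.null(x$required))
    cat("  required SN ", fmt_percent1(x$required$sensitivity), ", SP ",
        fmt_percent1(x$required$specificity), " (contra-Bayes)\n", sep = "")
  cat("  Bayes predictive NNT_Pos (", fmt_nnt(x$predictive$nnt_pos$lower),
      ", ", fmt_nnt(x$predictive$nnt_pos$upper), "), NNT_Neg (",
      fmt_nnt(x$predictive$nnt_neg$lower), ", ",
      fmt_nnt(x$predictive$nnt_neg$upper), ")  [", x$predictive$n_draws,
      " draws, seed ", x$predictive$seed, "]\n", sep = "")
  invisible(x)
}

#' Smallest prospective cohort whose anticipated intervals clear the range
#'
#' Searches over total sample size for the smallest prospective cohort such
#' that, if the observed NNT values match the targets, the exact confidence
#' intervals transformed to the NNT scale clear the discomfort range on both
#' sides (NNT_Pos interval entirely below `nnt_lower`, NNT_Neg interval
#' entirely above `nnt_upper`).  The search brackets by doubling and then
#' scans linearly; because anticipated counts are integer-rounded the
#' clearance indicator is not exactly monotone in `n`, so the scan checks
#' every size inside the bracket.
#'
#' @param target An [nnt_pair()] of hoped-for NNT values; must already clear
#'   the discomfort range, otherwise no sample size can.
#' @param dr A [discomfort_range()].
#' @param positive_fraction Anticipated positive fraction of the cohort.
#' @param level Two-sided confidence level, default 0.95.
#' @param n_max Largest total size considered before declaring the target
#'   unattainable, default 1e6.
#' @return A list with the smallest `n_total`, the group sizes and the
#'   clearing [prospective_summary()].
#' @examples
#' minimum_n_search(nnt_pair(1.1, 1000), discomfort_range(8, 16), 0.25)
#' @export
minimum_n_search <- function(target, dr, positive_fraction, level = 0.95,
                             n_max = 1e6) {
  stopifnot(inherits(target, "nnt_pair"), inherits(dr, "discomfort_range"))
  usefulness <- is_clinically_useful(target, dr)
  if (!usefulness$useful)
    stop("target NNT pair does not clear the discomfort range (",
         usefulness$message, "); no sample size can demonstrate clearance",
         call. = FALSE)
  clears_at <- function(n) {
    s <- tryCatch(
      prospective_summary(prospective_design(n, positive_fraction, target),
                          dr = dr, level = level),
      error = function(e) NULL)
    !is.null(s) && isTRUE(s$clears$positive) && isTRUE(s$clears$negative)
  }
  lo <- 4L
  hi <- lo
  while (hi <= n_max && !clears_at(hi)) {
    lo <- hi
    hi <- hi * 2L
  }
  if (hi > n_max)
    stop("no cohort of size up to ", n_max, " clears the discomfort range; ",
         "the target NNT pair (", fmt_nnt(target$nnt_pos), ", ",
         fmt_nnt(target$nnt_neg), ") sits too close to the boundary (",
         fmt_nnt(dr$nnt_lower), ", ", fmt_nnt(dr$nnt_upper), ")",
         call. = FALSE)
  # rounding of anticipated counts makes clearance non-monotone in n, so
  # scan every size up to the successful bracket endpoint
  n_best <- hi
  for (n in seq(4L, hi)) {
    if (clears_at(n)) {
      n_best <- n
      break
    }
  }
  s <- prospective_summary(prospective_design(n_best, positive_fraction,
                                              target),
                           dr = dr, level = level)
  list(n_total = n_best,
       n_positive = s$counts$positives$trials,
       n_negative = s$counts$negatives$trials,
       summary = s)
}
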