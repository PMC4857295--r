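# Forward Bayes (SN, SP, prevalence -> PPV, NPV) and its closed-form
# inversion ("contra-Bayes"): given the predictive values a test must
# achieve and the prevalence of BestToAct patients, recover the sensitivity
# and specificity a retrospective case-control study must demonstrate.
#
# With Odds = p/(1-p), PPO = PPV/(1-PPV) and NPO = NPV/(1-NPV):
#
#   SP = (PPO - Odds) / (PPO - NPO^-1)
#   SN = (NPO - Odds^-1) / (NPO - PPO^-1)
#
# which has a solution in [0,1]^2 exactly when the test moves the prior odds
# in the expected directions: PPO > Odds > NPO^-1 (strictly).  Internally the
# ratios are rearranged so that PPV = 1 or NPV = 1 are handled as algebraic
# limits rather than floating-point infinities.

# Vectorised numeric kernels ------------------------------------------------

bayes_ppv_ <- function(sn, sp, prevalence) {
  sn * prevalence / (sn * prevalence + (1 - sp) * (1 - prevalence))
}

bayes_npv_ <- function(sn, sp, prevalence) {
  sp * (1 - prevalence) / (sp * (1 - prevalence) + (1 - sn) * prevalence)
}

# Multiply numerator and denominator of Eq-3's ratios by (1-PPV) resp. (1-NPV)
# so that predictive values of exactly 1 stay finite.
contra_sp_ <- function(ppv, npv, prevalence) {
  odds <- prevalence / (1 - prevalence)
  (ppv - odds * (1 - ppv)) / (ppv - (1 - ppv) * (1 - npv) / npv)
}

contra_sn_ <- function(ppv, npv, prevalence) {
  odds <- prevalence / (1 - prevalence)
  (npv - (1 - npv) / odds) / (npv - (1 - npv) * (1 - ppv) / ppv)
}

# ---------------------------------------------------------------------------

#' Construct a sensitivity/specificity pair
#'
#' @param sensitivity Probability(ies) in \[0, 1\] that a `BestToAct` patient
#'   tests positive.
#' @param specificity Probability(ies) in \[0, 1\] that a `BestToWait` patient
#'   tests negative.
#' @return An object of class `test_characteristics`.
#' @export
test_characteristics <- function(sensitivity, specificity) {
  check_numeric(sensitivity, "sensitivity")
  check_numeric(specificity, "specificity")
  stopifnot(length(sensitivity) == length(specificity))
  if (any(sensitivity < 0 | sensitivity > 1))
    stop("sensitivity must lie in [0, 1]", call. = FALSE)
  if (any(specificity < 0 | specificity > 1))
    stop("specificity must lie in [0, 1]", call. = FALSE)
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "test_characteristics")
}

#' @export
print.test_characteristics <- function(x, ...) {
  cat("Test characteristics: sensitivity ", fmt_percent1(x$sensitivity[1L]),
      ", specificity ", fmt_percent1(x$specificity[1L]), "\n", sep = "")
  if (length(x$sensitivity) > 1L)
    cat("  (", length(x$sensitivity), " pairs in total)\n", sep = "")
  invisible(x)
}

#' Forward Bayes: predictive values from sensitivity, specificity, prevalence
#'
#' Computes
#' `PPV = SN p / (SN p + (1 - SP)(1 - p))` and
#' `NPV = SP (1 - p) / (SP (1 - p) + (1 - SN) p)` where `p` is the
#' prevalence of `BestToAct` status.  Vectorised over `sensitivity` and
#' `specificity`.
#'
#' @param sensitivity,specificity Test characteristics in \[0, 1\]; equal
#'   length vectors (or a [test_characteristics()] object passed as
#'   `sensitivity`).
#' @param prevalence Prior probability of `BestToAct`, strictly inside (0, 1).
#' @return A [predictive_values()] object.
#' @examples
#' bayes_forward(0.8, 0.8, 0.05)  # PPV about 0.17, NPV about 0.99
#' @export
bayes_forward <- function(sensitivity, specificity = NULL, prevalence) {
  if (inherits(sensitivity, "test_characteristics")) {
    tc <- sensitivity
  } else {
    tc <- test_characteristics(sensitivity, specificity)
  }
  check_prevalence(prevalence)
  den_pos <- tc$sensitivity * prevalence +
    (1 - tc$specificity) * (1 - prevalence)
  den_neg <- tc$specificity * (1 - prevalence) +
    (1 - tc$sensitivity) * prevalence
  if (any(den_pos == 0) || any(den_neg == 0))
    stop("degenerate test: a predictive value is undefined (0/0) for ",
         "sensitivity ", tc$sensitivity[which(den_pos == 0 | den_neg == 0)[1L]],
         ", specificity ",
         tc$specificity[which(den_pos == 0 | den_neg == 0)[1L]],
         " at prevalence ", prevalence, call. = FALSE)
  predictive_values(bayes_ppv_(tc$sensitivity, tc$specificity, prevalence),
                    bayes_npv_(tc$sensitivity, tc$specificity, prevalence))
}

#' Check feasibility of the contra-Bayes inversion
#'
#' The inversion has a meaningful solution exactly when positive and negative
#' test results move the prior odds in the expected directions:
#' `PPO > Odds > NPO^-1` (both strict).  Equality on either side means that
#' test arm conveys no information and is treated as infeasible.
#'
#' @param ppv,npv Target predictive values in (0, 1]; equal-length vectors.
#' @param prevalence Prior probability of `BestToAct`, inside (0, 1).
#' @return An object of class `feasibility_check`: list with logical
#'   `feasible`, numeric margins `margin_pos = PPO - Odds` and
#'   `margin_neg = Odds - NPO^-1` (positive when the corresponding
#'   inequality holds; `margin_pos` is `Inf` when `ppv = 1`), and a
#'   character `failed` naming the violated side(s), `""` when feasible.
#' @examples
#' check_feasible(0.5, 29/30, 0.15)   # feasible
#' check_feasible(0.1, 0.95, 0.5)     # positive side fails
#' @export
check_feasible <- function(ppv, npv, prevalence) {
  pv <- if (inherits(ppv, "predictive_values")) ppv else predictive_values(ppv, npv)
  check_prevalence(prevalence)
  odds <- prevalence / (1 - prevalence)
  margin_pos <- ifelse(pv$ppv == 1, Inf, pv$ppv / (1 - pv$ppv) - odds)
  margin_neg <- odds - (1 - pv$npv) / pv$npv
  failed <- mapply(function(mp, mn) {
    paste(c(if (mp <= 0) "positive (PPO <= Odds: a positive result does not raise the odds)",
            if (mn <= 0) "negative (Odds <= 1/NPO: a negative result does not lower the odds)"),
          collapse = "; ")
  }, margin_pos, margin_neg)
  structure(list(feasible = margin_pos > 0 & margin_neg > 0,
                 margin_pos = margin_pos,
                 margin_neg = margin_neg,
                 failed = unname(failed)),
            class = "feasibility_check")
}

#' @export
print.feasibility_check <- function(x, ...) {
  if (all(x$feasible)) {
    cat("Feasible: PPO - Odds = ", signif(x$margin_pos[1L], 4),
        ", Odds - 1/NPO = ", signif(x$margin_neg[1L], 4), "\n", sep = "")
  } else {
    cat("Infeasible on side(s): ", x$failed[which(!x$feasible)[1L]], "\n",
        sep = "")
  }
  invisible(x)
}

#' Contra-Bayes: sensitivity and specificity from predictive values
#'
#' Closed-form inversion of Bayes theorem.  Given target predictive values
#' and the prevalence of `BestToAct` patients, returns the sensitivity and
#' specificity that reproduce them, i.e.
#' `bayes_forward(contra_bayes(pv, p), p) == pv`.
#'
#' Predictive values of exactly 1 are handled as algebraic limits (a perfect
#' positive arm forces `SP = 1`; a perfect negative arm forces `SN = 1`).
#' Infeasible inputs (see [check_feasible()]) raise an error naming the
#' violated inequality.
#'
#' @inheritParams check_feasible
#' @return A [test_characteristics()] object.
#' @examples
#' contra_bayes(0.5, 29/30, 0.15)  # SN 83.3%, SP 85.3%
#' @export
contra_bayes <- function(ppv, npv = NULL, prevalence) {
  pv <- if (inherits(ppv, "predictive_values")) ppv else predictive_values(ppv, npv)
  check_prevalence(prevalence)
  feas <- check_feasible(pv, prevalence = prevalence)
  if (any(!feas$feasible)) {
    i <- which(!feas$feasible)[1L]
    stop("contra-Bayes inversion infeasible for PPV = ", pv$ppv[i],
         ", NPV = ", pv$npv[i], " at prevalence ", prevalence,
         "; failed side(s): ", feas$failed[i], call. = FALSE)
  }
  test_characteristics(contra_sn_(pv$ppv, pv$npv, prevalence),
                       contra_sp_(pv$ppv, pv$npv, prevalence))
}
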