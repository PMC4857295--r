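# The step-by-step study-design scaffold: a config-driven workflow walking
# from the clinical scenario (free text), through the elicited NNT
# discomfort range, to prospective and retrospective design summaries.
#
# Config schema (YAML or JSON), versioned with schema_version = 1:
#   step1_clinical_scenario: free text
#   step2_principal_goal:    free text
#   step3_clinical_benefit:  free text
#   step4_discomfort_range:  {nnt_lower, nnt_upper}          (required)
#   step5_prospective:       {n_total, positive_fraction,
#                             nnt_pos, nnt_neg [, followup_note]}  (optional)
#   step6_retrospective:     {n_cases, n_controls, sn_successes,
#                             sp_successes, prevalence}            (optional)

SCAFFOLD_SCHEMA_VERSION <- 1L

need_field <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop("scaffold config: missing field '", field, "' in ", where,
         call. = FALSE)
  x[[field]]
}

#' Load and validate a study-design scaffold configuration
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) scaffold file, validates
#' every numeric field through the package's constructors, and returns a
#' `scaffold_record`.  Steps 1-3 are free text; step 4 (the discomfort
#' range) is required before steps 5-6 can be computed; step 6 requires a
#' prevalence.
#'
#' @param path Path to the configuration file.
#' @return An object of class `scaffold_record` with fields `step1`,
#'   `step2`, `step3` (character), `step4` ([discomfort_range()]),
#'   `step5` ([prospective_design()] or `NULL`) and `step6`
#'   ([retrospective_design()] or `NULL`).
#' @examples
#' cfg <- system.file("extdata", "ctcl_scaffold.yaml", package = "nntdesign")
#' load_scaffold(cfg)
#' @export
load_scaffold <- function(path) {
  if (!file.exists(path))
    stop("scaffold config not found: '", path, "'", call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ver <- raw$schema_version
  if (is.null(ver) || as.integer(ver) != SCAFFOLD_SCHEMA_VERSION)
    stop("scaffold config: schema_version must be ", SCAFFOLD_SCHEMA_VERSION,
         ", got ", if (is.null(ver)) "none" else ver, call. = FALSE)

  s4 <- need_field(raw, "step4_discomfort_range", "config")
  dr <- discomfort_range(need_field(s4, "nnt_lower", "step4_discomfort_range"),
                         need_field(s4, "nnt_upper", "step4_discomfort_range"))

  step5 <- NULL
  if (!is.null(raw$step5_prospective)) {
    s5 <- raw$step5_prospective
    step5 <- prospective_design(
      need_field(s5, "n_total", "step5_prospective"),
      need_field(s5, "positive_fraction", "step5_prospective"),
      nnt_pair(need_field(s5, "nnt_pos", "step5_prospective"),
               need_field(s5, "nnt_neg", "step5_prospective")),
      followup_note = if (is.null(s5$followup_note)) "" else s5$followup_note)
  }

  step6 <- NULL
  if (!is.null(raw$step6_retrospective)) {
    s6 <- raw$step6_retrospective
    step6 <- retrospective_design(
      need_field(s6, "n_cases", "step6_retrospective"),
      need_field(s6, "n_controls", "step6_retrospective"),
      need_field(s6, "sn_successes", "step6_retrospective"),
      need_field(s6, "sp_successes", "step6_retrospective"),
      need_field(s6, "prevalence", "step6_retrospective"))
  }

  text_or_empty <- function(x) if (is.null(x)) "" else as.character(x)
  structure(list(step1 = text_or_empty(raw$step1_clinical_scenario),
                 step2 = text_or_empty(raw$step2_principal_goal),
                 step3 = text_or_empty(raw$step3_clinical_benefit),
                 step4 = dr, step5 = step5, step6 = step6),
            class = "scaffold_record")
}

#' Run the study-design scaffold
#'
#' Computes, from a validated `scaffold_record`: the required predictive
#' values implied by the discomfort range (step 4 to 5), the prospective
#' design summary with exact confidence intervals on both scales (step 5),
#' and the required sensitivity/specificity via contra-Bayes plus the
#' retrospective summary with Bayes predictive NNT intervals (step 6).
#'
#' @param record A `scaffold_record` from [load_scaffold()].
#' @param level Confidence/predictive-interval level, default 0.95.
#' @param n_draws Monte-Carlo draws for the predictive intervals,
#'   default 1e5.
#' @param seed Seed for the predictive-interval draws; default 20160504,
#'   fixed so reports are reproducible.
#' @return An object of class `nnt_report`: a plain nested list (so it
#'   serializes losslessly) with elements `scenario`, `discomfort_range`,
#'   `required_predictive_values`, `prospective`, `retrospective` and
#'   `settings`.
#' @examples
#' cfg <- system.file("extdata", "ctcl_scaffold.yaml", package = "nntdesign")
#' rep <- run_scaffold(load_scaffold(cfg), n_draws = 10000)
#' cat(render_report(rep))
#' @export
run_scaffold <- function(record, level = 0.95, n_draws = 1e5,
                         seed = 20160504L) {
  stopifnot(inherits(record, "scaffold_record"))
  check_level(level)
  dr <- record$step4
  req_pv <- required_predictive_values(dr)

  prospective <- NULL
  if (!is.null(record$step5)) {
    ps <- prospective_summary(record$step5, dr = dr, level = level)
    prospective <- list(
      n_total = ps$design$n_total,
      positive_fraction = ps$design$positive_fraction,
      target_nnt_pos = ps$design$target$nnt_pos,
      target_nnt_neg = ps$design$target$nnt_neg,
      followup_note = ps$design$followup_note,
      anticipated_ppv = unclass(ps$counts$positives),
      anticipated_npv = unclass(ps$counts$negatives),
      ppv_ci = c(ps$ppv_ci$lower, ps$ppv_ci$upper),
      npv_ci = c(ps$npv_ci$lower, ps$npv_ci$upper),
      nnt_pos_ci = c(ps$nnt_pos_ci$lower, ps$nnt_pos_ci$upper),
      nnt_neg_ci = c(ps$nnt_neg_ci$lower, ps$nnt_neg_ci$upper),
      clears_positive = ps$clears$positive,
      clears_negative = ps$clears$negative)
  }

  retrospective <- NULL
  if (!is.null(record$step6)) {
    rs <- retrospective_summary(record$step6, dr = dr, level = level,
                                n_draws = n_draws, seed = seed)
    retrospective <- list(
      n_cases = rs$design$n_cases,
      n_controls = rs$design$n_controls,
      prevalence = rs$design$prevalence,
      anticipated_sn = unclass(rs$design$anticipated_sn),
      anticipated_sp = unclass(rs$design$anticipated_sp),
      sn_ci = c(rs$sn_ci$lower, rs$sn_ci$upper),
      sp_ci = c(rs$sp_ci$lower, rs$sp_ci$upper),
      required_sensitivity = rs$required$sensitivity,
      required_specificity = rs$required$specificity,
      meets_required_sn = rs$meets_required$sensitivity,
      meets_required_sp = rs$meets_required$specificity,
      predictive_nnt_pos = c(rs$predictive$nnt_pos$lower,
                             rs$predictive$nnt_pos$upper),
      predictive_nnt_neg = c(rs$predictive$nnt_neg$lower,
                             rs$predictive$nnt_neg$upper))
  }

  out <- list(
    scenario = list(clinical_scenario = record$step1,
                    principal_goal = record$step2,
                    clinical_benefit = record$step3),
    discomfort_range = list(nnt_lower = dr$nnt_lower,
                            nnt_upper = dr$nnt_upper),
    required_predictive_values = list(ppv = req_pv$ppv, npv = req_pv$npv),
    prospective = prospective,
    retrospective = retrospective,
    settings = list(level = level, n_draws = n_draws,
                    seed = as.integer(seed),
                    schema_version = SCAFFOLD_SCHEMA_VERSION))
  structure(strip_classes(out), class = "nnt_report")
}

#' Render a scaffold report as markdown
#'
#' The report quotes the design team's step 1-3 free text verbatim, so that
#' the intended clinical use travels with the numbers, then walks through
#' the computed requirements and anticipated-precision summaries.
#'
#' @param report An `nnt_report` from [run_scaffold()].
#' @return A single markdown string.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "nnt_report"))
  dr <- report$discomfort_range
  req <- report$required_predictive_values
  lines <- c(
    "# Biomarker validation study design scaffold",
    "",
    "## Step 1 - Clinical scenario",
    report$scenario$clinical_scenario,
    "",
    "## Step 2 - Principal goal",
    report$scenario$principal_goal,
    "",
    "## Step 3 - Clinical benefit",
    report$scenario$clinical_benefit,
    "",
    "## Step 4 - Classification performance needed",
    paste0("NNT discomfort range: (", fmt_nnt(dr$nnt_lower), ", ",
           fmt_nnt(dr$nnt_upper), ")."),
    paste0("Required predictive values: PPV > ", fmt_percent(req$ppv),
           " = 1/NNT_Lower, NPV > ", fmt_percent(req$npv),
           " = 1 - 1/NNT_Upper."))

  if (!is.null(report$prospective)) {
    p <- report$prospective
    lines <- c(lines, "",
      "## Step 5 - Prospective study requirements",
      paste0("Cohort of ", p$n_total, " patients, anticipated ",
             fmt_percent(p$positive_fraction), " test-positive; target ",
             "NNT_Pos ", fmt_nnt(p$target_nnt_pos), ", NNT_Neg ",
             fmt_nnt(p$target_nnt_neg), ".",
             if (nzchar(p$followup_note)) paste0(" ", p$followup_note)),
      paste0("Anticipated PPV ", p$anticipated_ppv$successes, "/",
             p$anticipated_ppv$trials, ": CI ", fmt_percent(p$ppv_ci[1]),
             "-", fmt_percent(p$ppv_ci[2]), "; NNT_Pos CI (",
             fmt_nnt(p$nnt_pos_ci[1]), ", ", fmt_nnt(p$nnt_pos_ci[2]), ")."),
      paste0("Anticipated NPV ", p$anticipated_npv$successes, "/",
             p$anticipated_npv$trials, ": CI ", fmt_percent(p$npv_ci[1]),
             "-", fmt_percent(p$npv_ci[2]), "; NNT_Neg CI (",
             fmt_nnt(p$nnt_neg_ci[1]), ", ", fmt_nnt(p$nnt_neg_ci[2]), ")."),
      paste0("Interval endpoints clear the discomfort range: positive side ",
             p$clears_positive, ", negative side ", p$clears_negative, "."))
  }

  if (!is.null(report$retrospective)) {
    r <- report$retrospective
    lines <- c(lines, "",
      "## Step 6 - Retrospective study requirements",
      paste0("Required sensitivity ", fmt_percent1(r$required_sensitivity),
             " and specificity ", fmt_percent1(r$required_specificity),
             " (contra-Bayes at prevalence ", fmt_percent(r$prevalence),
             ")."),
      paste0("Anticipated SN ", r$anticipated_sn$successes, "/",
             r$anticipated_sn$trials, ": CI ", fmt_percent(r$sn_ci[1]), "-",
             fmt_percent(r$sn_ci[2]), "."),
      paste0("Anticipated SP ", r$anticipated_sp$successes, "/",
             r$anticipated_sp$trials, ": CI ", fmt_percent(r$sp_ci[1]), "-",
             fmt_percent(r$sp_ci[2]), "."),
      paste0("Bayes predictive intervals: NNT_Pos (",
             fmt_nnt(r$predictive_nnt_pos[1]), ", ",
             fmt_nnt(r$predictive_nnt_pos[2]), "), NNT_Neg (",
             fmt_nnt(r$predictive_nnt_neg[1]), ", ",
             fmt_nnt(r$predictive_nnt_neg[2]), ")."))
  }

  s <- report$settings
  lines <- c(lines, "",
    paste0("_Settings: level ", s$level, ", ", s$n_draws,
           " Monte-Carlo draws, seed ", s$seed, "._"), "")
  paste(lines, collapse = "\n")
}

#' @export
print.nnt_report <- function(x, ...) {
  cat(render_report(x))
  invisible(x)
}

# JSON serialization ---------------------------------------------------------

inf_to_string <- function(x) {
  if (is.list(x)) return(lapply(x, inf_to_string))
  if (is.numeric(x) && any(is.infinite(x))) {
    x <- as.list(x)
    x[vapply(x, is.infinite, logical(1L))] <- "Inf"
  }
  x
}

string_to_inf <- function(x) {
  if (is.list(x)) return(lapply(x, string_to_inf))
  if (is.character(x)) {
    # a mixed array like [5.81, "Inf"] parses as character; restore numerics
    conv <- suppressWarnings(as.numeric(x))
    if (!anyNA(conv)) return(conv)
  }
  x
}

#' Serialize a scaffold report to JSON
#'
#' Infinite NNT values (a perfect negative arm) are written as the string
#' `"Inf"`; [report_from_json()] restores them.
#'
#' @param report An `nnt_report`.
#' @return A JSON string.
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "nnt_report"))
  as.character(jsonlite::toJSON(inf_to_string(unclass(report)),
                                auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' Parse a scaffold report from JSON
#'
#' @param json A JSON string written by [report_to_json()].
#' @return An `nnt_report`.
#' @export
report_from_json <- function(json) {
  parsed <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE)
  structure(string_to_inf(parsed), class = "nnt_report")
}
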