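test_that("Clopper-Pearson CIs match binom.test and the worked intervals", {
  # worked intervals at whole-percent rounding
  cases <- list(list(5, 10, "19%", "81%"),
                list(29, 30, "83%", "100%"),
                list(18, 22, "60%", "95%"),
                list(34, 40, "70%", "94%"))
  for (cs in cases) {
    ci <- exact_binomial_ci(cs[[1]], cs[[2]])
    expect_identical(fmt_percent(ci$lower), cs[[3]])
    expect_identical(fmt_percent(ci$upper), cs[[4]])
  }

  # independent oracle: stats::binom.test on a grid incl. boundary outcomes
  for (n in c(1, 7, 10, 22, 40)) {
    for (x in unique(c(0, 1, floor(n / 2), n - 1, n))) {
      if (x < 0) next
      for (level in c(0.9, 0.95, 0.99)) {
        ci <- exact_binomial_ci(x, n, level)
        oracle <- stats::binom.test(x, n, conf.level = level)$conf.int
        expect_equal(c(ci$lower, ci$upper), as.numeric(oracle),
                     tolerance = 1e-10)
      }
    }
  }
  expect_identical(exact_binomial_ci(0, 7)$lower, 0)
  expect_identical(exact_binomial_ci(7, 7)$upper, 1)
  expect_error(exact_binomial_ci(5, 10, level = 1), "level")
})

test_that("exact CIs are conservative: exhaustive coverage for small n", {
  p_grid <- seq(0.01, 0.99, length.out = 99)
  for (n in 1:25) {
    ci <- vapply(0:n, function(x) {
      e <- exact_binomial_ci(x, n, 0.95)
      c(e$lower, e$upper)
    }, numeric(2))
    for (p in p_grid) {
      covered <- ci[1, ] <= p & p <= ci[2, ]
      coverage <- sum(stats::dbinom(0:n, n, p)[covered])
      expect_gte(coverage, 0.95)
    }
  }
})

test_that("NNT-scale transforms reverse order and preserve containment", {
  ppv_ci <- exact_binomial_ci(5, 10)
  nnt_pos <- nnt_interval_from_pv_interval(ppv_ci, "pos")
  expect_equal(round(nnt_pos$lower, 2), 1.23)
  expect_equal(round(nnt_pos$upper, 2), 5.35)

  npv_ci <- exact_binomial_ci(29, 30)
  nnt_neg <- nnt_interval_from_pv_interval(npv_ci, "neg")
  expect_equal(round(nnt_neg$lower, 2), 5.81)
  expect_true(nnt_neg$upper > 1000)

  # degenerate interval maps to a degenerate interval
  unit <- interval_estimate(1, 1, 0.95, "exact-binomial", estimate = 1)
  expect_equal(unlist(nnt_interval_from_pv_interval(unit, "pos")[
    c("lower", "upper")]), c(lower = 1, upper = 1))
  expect_identical(nnt_interval_from_pv_interval(unit, "neg")$upper, Inf)

  zero_low <- interval_estimate(0, 0.3, 0.95, "exact-binomial")
  expect_error(nnt_interval_from_pv_interval(zero_low, "pos"), "lower bound 0")

  # containment: the point-estimate NNT sits inside the transformed interval
  withr::local_seed(8)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    x <- sample(1:(n - 1), 1)
    ci <- exact_binomial_ci(x, n)
    pos <- nnt_interval_from_pv_interval(ci, "pos")
    expect_true(pos$lower <= n / x && n / x <= pos$upper)
    neg <- nnt_interval_from_pv_interval(ci, "neg")
    nnt_hat <- 1 / (1 - x / n)
    expect_true(neg$lower <= nnt_hat && nnt_hat <= neg$upper)
  }
})

test_that("anticipated prospective counts follow the target NNTs", {
  counts <- anticipated_prospective_counts(
    prospective_design(40, 0.25, nnt_pair(2, 30)))
  expect_identical(unclass(counts$positives)[c("successes", "trials")],
                   list(successes = 5, trials = 10))
  expect_identical(unclass(counts$negatives)[c("successes", "trials")],
                   list(successes = 29, trials = 30))

  # perfect test: every positive benefits, no negative does
  counts <- anticipated_prospective_counts(
    prospective_design(40, 0.25, nnt_pair(1, Inf)))
  expect_equal(counts$positives$successes, 10)
  expect_equal(counts$negatives$successes, 30)

  counts <- anticipated_prospective_counts(
    prospective_design(100, 0.2, nnt_pair(4, 50)))
  expect_equal(counts$positives$successes, 5)   # round(20/4)
  expect_equal(counts$negatives$successes, 78)  # 80 - round(80/50)
  expect_equal(counts$negatives$trials, 80)
})

test_that("prospective summary composes counts, CIs and NNT transforms", {
  s <- prospective_summary(prospective_design(40, 0.25, nnt_pair(2, 30)),
                           dr = discomfort_range(2, 30))
  expect_identical(fmt_percent(s$ppv_ci$lower), "19%")
  expect_identical(fmt_percent(s$ppv_ci$upper), "81%")
  expect_identical(fmt_percent(s$npv_ci$lower), "83%")
  expect_identical(fmt_percent(s$npv_ci$upper), "100%")
  expect_equal(round(s$nnt_pos_ci$lower, 2), 1.23)
  expect_equal(round(s$nnt_pos_ci$upper, 2), 5.35)
  expect_equal(round(s$nnt_neg_ci$lower, 2), 5.81)
  # with the target sitting on the range boundary the CIs cannot clear it
  expect_false(s$clears$positive)
  expect_false(s$clears$negative)

  # oracle: manual composition of the three component operations
  d <- prospective_design(100, 0.2, nnt_pair(4, 50))
  s <- prospective_summary(d, level = 0.9)
  ppv_ci <- exact_binomial_ci(5, 20, 0.9)
  npv_ci <- exact_binomial_ci(78, 80, 0.9)
  expect_equal(c(s$nnt_pos_ci$lower, s$nnt_pos_ci$upper),
               c(1 / ppv_ci$upper, 1 / ppv_ci$lower))
  expect_equal(c(s$nnt_neg_ci$lower, s$nnt_neg_ci$upper),
               c(1 / (1 - npv_ci$lower), 1 / (1 - npv_ci$upper)))
})

test_that("Bayes predictive NNT intervals are reproducible and calibrated", {
  d <- retrospective_design(22, 40, 18, 34, 0.15)
  a <- bayes_predictive_nnt_intervals(d, n_draws = 2e4, seed = 5)
  b <- bayes_predictive_nnt_intervals(d, n_draws = 2e4, seed = 5)
  expect_identical(a$nnt_pos$lower, b$nnt_pos$lower)
  expect_identical(a$nnt_neg$upper, b$nnt_neg$upper)

  # point estimates come from forward Bayes at the observed proportions
  expect_equal(a$nnt_pos$estimate,
               1 / bayes_forward(18 / 22, 34 / 40, 0.15)$ppv)

  # scaling the counts 1000x concentrates the intervals at the plug-in NNTs
  big <- retrospective_design(22000, 40000, 18000, 34000, 0.15)
  bi <- bayes_predictive_nnt_intervals(big, n_draws = 2e4, seed = 5)
  expect_equal(bi$nnt_pos$lower, a$nnt_pos$estimate, tolerance = 0.02)
  expect_equal(bi$nnt_pos$upper, a$nnt_pos$estimate, tolerance = 0.02)
  expect_equal(bi$nnt_neg$lower, a$nnt_neg$estimate, tolerance = 0.05)
  expect_equal(bi$nnt_neg$upper, a$nnt_neg$estimate, tolerance = 0.05)
  # and the widths shrink
  expect_lt(bi$nnt_pos$upper - bi$nnt_pos$lower,
            a$nnt_pos$upper - a$nnt_pos$lower)
  expect_lt(bi$nnt_neg$upper - bi$nnt_neg$lower,
            a$nnt_neg$upper - a$nnt_neg$lower)

  expect_warning(bayes_predictive_nnt_intervals(d, n_draws = 100, seed = 1),
                 "noisy")
})

test_that("two independent seeds agree within Monte-Carlo tolerance", {
  d <- retrospective_design(22, 40, 18, 34, 0.15)
  a <- bayes_predictive_nnt_intervals(d, n_draws = 1e5, seed = 101)
  b <- bayes_predictive_nnt_intervals(d, n_draws = 1e5, seed = 202)
  for (side in c("nnt_pos", "nnt_neg")) {
    expect_equal(a[[side]]$lower, b[[side]]$lower, tolerance = 0.02)
    expect_equal(a[[side]]$upper, b[[side]]$upper, tolerance = 0.02)
  }
})

test_that("the sampler leaves the caller's RNG state untouched", {
  set.seed(314)
  before <- .Random.seed
  invisible(bayes_predictive_nnt_intervals(
    retrospective_design(22, 40, 18, 34, 0.15), n_draws = 1e4, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("retrospective summary combines CIs, requirements and predictions", {
  s <- retrospective_summary(retrospective_design(22, 40, 18, 34, 0.15),
                             dr = discomfort_range(2, 30),
                             n_draws = 2e4, seed = 3)
  expect_identical(fmt_percent(s$sn_ci$lower), "60%")
  expect_identical(fmt_percent(s$sn_ci$upper), "95%")
  expect_identical(fmt_percent(s$sp_ci$lower), "70%")
  expect_identical(fmt_percent(s$sp_ci$upper), "94%")
  expect_identical(fmt_percent1(s$required$sensitivity), "83.3%")
  expect_identical(fmt_percent1(s$required$specificity), "85.3%")
  # anticipated SN 81.8% sits below the required 83.3%, SP 85% just below 85.3%
  expect_false(s$meets_required$sensitivity)
  expect_false(s$meets_required$specificity)

  # all-correct counts give CIs with upper bound 1
  s2 <- retrospective_summary(retrospective_design(22, 40, 22, 40, 0.15),
                              n_draws = 2e4, seed = 3)
  expect_identical(s2$sn_ci$upper, 1)
  expect_identical(s2$sp_ci$upper, 1)
  expect_null(s2$required)

  # composition oracle on an arbitrary design
  d <- retrospective_design(30, 50, 24, 45, 0.2)
  s3 <- retrospective_summary(d, dr = discomfort_range(3, 20),
                              n_draws = 2e4, seed = 17)
  expect_equal(c(s3$sn_ci$lower, s3$sn_ci$upper),
               as.numeric(stats::binom.test(24, 30)$conf.int),
               tolerance = 1e-10)
  req <- contra_bayes(required_predictive_values(discomfort_range(3, 20)),
                      prevalence = 0.2)
  expect_equal(s3$required$sensitivity, req$sensitivity)
  pred <- bayes_predictive_nnt_intervals(d, n_draws = 2e4, seed = 17)
  expect_identical(s3$predictive$nnt_pos$upper, pred$nnt_pos$upper)
})

test_that("minimum_n_search finds the smallest clearing cohort", {
  # an easily-cleared target needs a small cohort
  res <- minimum_n_search(nnt_pair(1.1, 1000), discomfort_range(8, 16), 0.25)
  expect_true(res$n_total < 150)
  expect_true(res$summary$clears$positive && res$summary$clears$negative)

  # independent check: recompose the clearance condition at n and below
  clears <- function(n) {
    s <- tryCatch(prospective_summary(
      prospective_design(n, 0.25, nnt_pair(1.1, 1000)),
      dr = discomfort_range(8, 16)), error = function(e) NULL)
    !is.null(s) && s$clears$positive && s$clears$negative
  }
  expect_true(clears(res$n_total))
  expect_false(any(vapply(seq(4, res$n_total - 1), clears, logical(1))))

  # a target on the discomfort boundary can never be demonstrated
  expect_error(minimum_n_search(nnt_pair(2.5, 30), discomfort_range(2.5, 25),
                                0.25),
               "does not clear")

  # a finite answer exists for the moderately separated target
  res2 <- minimum_n_search(nnt_pair(2, 30), discomfort_range(2.5, 25), 0.25)
  expect_true(is.finite(res2$n_total))
  expect_true(res2$summary$clears$positive && res2$summary$clears$negative)
})

test_that("design constructors validate their inputs", {
  expect_error(binomial_outcome(5, 0), "positive integer")
  expect_error(binomial_outcome(11, 10), "\\[0, trials]")
  expect_error(prospective_design(1, 0.5, nnt_pair(2, 30)), ">= 2")
  expect_error(prospective_design(40, 0, nnt_pair(2, 30)), "strictly inside")
  expect_error(retrospective_design(22, 40, 18, 34, 1.5), "prevalence")
})
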