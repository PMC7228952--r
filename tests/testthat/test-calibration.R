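mk_records <- function(mc, ac, counters = 4, sd_mc = 0) {
  lapply(seq_along(mc), function(i) {
    counts <- if (sd_mc == 0) rep(mc[i], counters) else
      rnorm(counters, mc[i], sd_mc)
    count_record(paste0("img", i), counts, ac[i])
  })
}

test_that("a noiseless linear bias is recovered and inverted exactly", {
  mc <- seq(10, 100, by = 5)
  recs <- mk_records(mc, 0.8 * mc + 5)
  fit <- fit_correction(recs)
  expect_equal(fit$a, 0.8, tolerance = 1e-12)
  expect_equal(fit$b, 5, tolerance = 1e-10)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-12)
  expect_equal(apply_correction(fit, 0.8 * mc + 5), mc, tolerance = 1e-9)
  # identity tool needs no correction
  fit_id <- fit_correction(mk_records(mc, mc))
  expect_equal(fit_id$a, 1, tolerance = 1e-12)
  expect_equal(fit_id$b, 0, tolerance = 1e-10)
})

test_that("the published rat validation coefficients invert as expected", {
  rat <- list(a = 0.801, b = 4.8)
  expect_equal(apply_correction(rat, 52.9), (52.9 - 4.8) / 0.801)
  expect_equal(apply_correction(rat, 52.9), 60.05, tolerance = 1e-4)
})

test_that("the OLS slope lands within sampling error of the truth", {
  set.seed(11)
  mc <- runif(300, 20, 120)
  ac <- 0.8 * mc + 5 + rnorm(300)
  fit <- fit_correction(mk_records(mc, ac))
  se_a <- 1 / sqrt(sum((mc - mean(mc))^2))  # sigma = 1 by construction
  expect_lt(abs(fit$a - 0.8), 3 * se_a)
  expect_gt(fit$fit_r2, 0.99)
})

test_that("degenerate correction fits are refused", {
  expect_error(fit_correction(mk_records(c(10, 20), c(10, 20))), "3")
  expect_error(fit_correction(mk_records(rep(10, 5), 1:5)), "identical")
  expect_error(apply_correction(list(a = 0, b = 1), 10), "zero slope")
})

test_that("Bland-Altman limits converge to +/- 1.96 sigma on normal errors", {
  recs <- mk_records(rep(50, 2), c(50, 50))
  ba0 <- bland_altman(recs)
  expect_equal(ba0$bias_mean, 0)
  expect_equal(unname(ba0$loa), c(0, 0))
  set.seed(12)
  n <- 1000; sigma <- 4
  mc <- runif(n, 30, 80)
  recs <- mk_records(mc, mc + rnorm(n, 0, sigma))
  ba <- bland_altman(recs)
  # sampling error of the LoA estimate ~ sigma * sqrt(3/n)
  tol <- 3 * sigma * sqrt(3 / n)
  expect_lt(abs(ba$loa[["lower"]] - (-1.96 * sigma)), tol)
  expect_lt(abs(ba$loa[["upper"]] - 1.96 * sigma), tol)
  # order invariance
  ba_rev <- bland_altman(rev(recs))
  expect_equal(ba_rev$loa, ba$loa)
})

test_that("success rate matches the t-interval's new-observation coverage", {
  set.seed(13)
  recs <- mk_records(runif(50, 20, 60), rep(0, 50), sd_mc = 3)
  hit_all <- lapply(recs, function(r) {
    r$ac_corrected <- mean(r$manual_counts); r
  })
  expect_equal(success_rate(hit_all), 1)
  miss_all <- lapply(recs, function(r) { r$ac_corrected <- 1e6; r })
  expect_equal(success_rate(miss_all), 0)
  # an AC drawn like a fifth counter falls in the 4-counter t-CI of the mean
  # with probability P(|t_3| <= t_{.975,3} / sqrt(5)) — the closed form the
  # Monte-Carlo estimate must match
  n <- 4000; sigma <- 5
  recs5 <- lapply(seq_len(n), function(i) {
    mu <- runif(1, 30, 70)
    count_record(i, rnorm(4, mu, sigma), ac = 1,
                 ac_corrected = rnorm(1, mu, sigma))
  })
  coverage <- 2 * pt(qt(0.975, 3) / sqrt(5), 3) - 1
  expect_equal(success_rate(recs5), coverage,
               tolerance = 4 * sqrt(coverage * (1 - coverage) / n) /
                 coverage)
  # records without exactly 4 counters are excluded with a warning
  mixed <- c(hit_all, mk_records(50, 50, counters = 2))
  expect_warning(sr <- success_rate(mixed), "excluded")
  expect_equal(sr, 1)
})

test_that("coefficients of variation summarize inter-counter spread", {
  ident <- mk_records(c(30, 40), c(0, 0))
  expect_equal(cov_stats(ident)$median_cov, 0)
  one <- list(count_record("a", c(48, 52), 0))
  expect_equal(cov_stats(one)$median_cov, sd(c(48, 52)) / 50)
  expect_equal(cov_stats(one)$median_cov, 0.0565685, tolerance = 1e-6)
})

test_that("correction reduces the error of genuinely biased counts", {
  set.seed(14)
  mc <- runif(200, 20, 100)
  ac <- 0.85 * mc + 8 + rnorm(200, 0, 2)   # >10% systematic bias
  recs <- mk_records(mc, ac)
  fit <- fit_correction(recs[1:100])
  test_recs <- correct_records(fit, recs[101:200])
  mae_raw <- mean(abs(sapply(test_recs, `[[`, "ac") -
                        sapply(test_recs, function(r) mean(r$manual_counts))))
  rep <- agreement_report(test_recs)
  expect_lt(rep$mae, mae_raw)
  expect_gt(rep$r2, 0.9)
})
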