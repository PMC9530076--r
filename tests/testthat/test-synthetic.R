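test_that("the lognormal cost calibration inverts mean and median in closed form", {
  cal <- calibrate_cost_distribution(1013.03, 850)
  expect_equal(round(cal$meanlog, 4), 6.7452)
  expect_equal(round(cal$sdlog, 4), 0.5924)
  # oracle: the calibrated distribution returns the targets
  expect_equal(exp(cal$meanlog), 850)
  expect_equal(exp(cal$meanlog + cal$sdlog^2 / 2), 1013.03)

  degen <- calibrate_cost_distribution(500, 500)
  expect_equal(degen$sdlog, 0)
  expect_error(calibrate_cost_distribution(800, 850),
               class = "odysseycost_skew_violation")
  expect_error(calibrate_cost_distribution(100, 0))
})

test_that("the truncated negative binomial matches the count moments", {
  cal <- calibrate_testcount_distribution(2.32, 2.08, 16L)
  # oracle: exhaustive mass summation over the support {1..16}
  k <- 1:16
  p <- stats::dnbinom(k, size = cal$size, mu = cal$mu)
  p <- p / sum(p)
  m <- sum(k * p)
  s <- sqrt(sum(k^2 * p) - m^2)
  expect_true(m >= 2.319 && m <= 2.321)
  expect_equal(s, 2.08, tolerance = 1e-3)
  expect_equal(cal$mean, m)
  expect_equal(cal$sd, s)

  # Monte-Carlo cross-check of the same calibration
  set.seed(11)
  draws <- sample(k, 2e5, replace = TRUE, prob = p)
  expect_equal(mean(draws), 2.32, tolerance = 0.02)
  expect_equal(stats::sd(draws), 2.08, tolerance = 0.02)

  expect_error(calibrate_testcount_distribution(0.9, 1, 16L), "exceed 1")
  expect_error(calibrate_testcount_distribution(2.32, 0, 16L), "positive")
  expect_error(calibrate_testcount_distribution(2, 20, 16L),
               class = "odysseycost_infeasible_moments")
})

test_that("the same seed reproduces the cohort byte for byte", {
  cfg <- cohort_config(n_probands = 40L, n_submitted = 50L, seed = 99L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$histories, b$histories)
  expect_identical(tibble::as_tibble(a$costbook), tibble::as_tibble(b$costbook))
  expect_identical(a$ground_truth, b$ground_truth)
  c2 <- simulate_cohort(cohort_config(n_probands = 40L, n_submitted = 50L, seed = 100L))
  expect_false(identical(a$ground_truth$true_cost, c2$ground_truth$true_cost))
})

test_that("per-proband costs respect the truncation bounds for every seed", {
  for (seed in 1:100) {
    coh <- simulate_cohort(cohort_config(n_probands = 50L, n_submitted = 50L,
                                         seed = seed))
    expect_true(all(coh$ground_truth$true_cost >= 90))
    expect_true(all(coh$ground_truth$true_cost <= 6784.39))
    expect_true(all(coh$ground_truth$n_tests >= 1 & coh$ground_truth$n_tests <= 16))
  }
})

test_that("costing a generated cohort recovers the generator's ground truth", {
  coh <- simulate_cohort(cohort_config(n_probands = 60L, n_submitted = 80L,
                                       seed = 7L))
  split <- filter_costable(coh$histories, coh$costbook)
  expect_equal(length(unique(split$included$proband_id)), 60)
  expect_equal(nrow(split$excluded), 20)
  expect_true(all(grepl("ILLEGIBLE", split$excluded$reason)))

  pc <- cost_pathways(split$included, coh$costbook)
  joined <- dplyr::inner_join(pc, coh$ground_truth, by = "proband_id")
  expect_equal(nrow(joined), 60)
  expect_equal(joined$test_total, joined$true_cost, tolerance = 1e-9)
  expect_equal(joined$n_tests.x, joined$n_tests.y)
  expect_equal(joined$grand_total, joined$true_cost + 828, tolerance = 1e-9)
})

test_that("category draws converge to the configured weights", {
  coh <- simulate_cohort(cohort_config(n_probands = 10000L, n_submitted = 10000L,
                                       seed = 13L))
  w <- default_category_weights()
  obs <- table(factor(coh$ground_truth$category, levels = names(w)))
  gof <- suppressWarnings(stats::chisq.test(obs, p = w))
  expect_gt(gof$p.value, 0.001)
  # the two headline categories dominate the mix
  props <- prop.table(obs)
  expect_equal(unname(props[["intellectual disability"]]), 0.37, tolerance = 0.05)
})

test_that("Monte-Carlo moments approach the calibrated analytic ones as n grows", {
  cal <- calibrate_cost_distribution(1013.03, 850)
  errs <- purrr::map_dbl(c(100L, 400L, 1600L), function(n) {
    reps <- purrr::map_dbl(1:8, function(s) {
      coh <- simulate_cohort(cohort_config(n_probands = n, n_submitted = n,
                                           seed = 1000L + s * 17L + n))
      mean(coh$ground_truth$true_cost) - 1013.03
    })
    sqrt(mean(reps^2))
  })
  # RMS error shrinks roughly as 1/sqrt(n): a 16-fold n gives ~4-fold shrink
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 60)
})

test_that("written cohorts reload into the same pipeline inputs", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(cohort_config(n_probands = 25L, n_submitted = 30L,
                                       seed = 3L))
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  cb2 <- read_costbook(file.path(dir, "costbook.csv"))
  h2 <- read_histories(file.path(dir, "histories.csv"))
  pc <- cost_pathways(filter_costable(h2, cb2)$included, cb2)
  expect_equal(sort(pc$test_total), sort(coh$ground_truth$true_cost),
               tolerance = 1e-6)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$seed, 3)
})

test_that("cohort configuration guards its invariants", {
  expect_error(cohort_config(n_probands = 10, n_submitted = 5))
  bad_w <- default_category_weights(); bad_w[1] <- bad_w[1] + 0.1
  expect_error(cohort_config(category_weights = bad_w), "sum to 1")
  expect_error(cohort_config(cost_range = c(100, 90)))
})
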