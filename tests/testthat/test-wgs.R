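ctx0 <- economic_context(inflation_index = c("2016" = 263.1, "2018" = 278.1))

test_that("annual equivalent cost follows the annuity closed form", {
  r0 <- economic_context(discount_rate = 0)
  expect_equal(annual_equivalent_cost(1000, 5, r0), 200)                 # K/L limit
  expect_equal(annual_equivalent_cost(1000, 1, ctx0), 1035)              # K(1+r)
  expect_equal(annual_equivalent_cost(1000, 5, ctx0),
               1000 * 0.035 / (1 - 1.035^-5))
  expect_equal(round(annual_equivalent_cost(1000, 5, ctx0), 2), 221.48)

  # r -> 0+ continuity: tiny positive rate approaches straight-line K/L
  eps <- economic_context(discount_rate = 1e-8)
  expect_equal(annual_equivalent_cost(1000, 5, eps) / 200, 1, tolerance = 1e-4)

  # increasing in the discount rate
  rates <- c(0.005, 0.02, 0.035, 0.06, 0.1)
  aecs <- vapply(rates, function(r)
    annual_equivalent_cost(1000, 5, economic_context(discount_rate = r)),
    numeric(1))
  expect_true(all(diff(aecs) > 0))

  # historical purchase prices are inflated before annuitization
  expect_equal(
    annual_equivalent_cost(1000, 5, ctx0, price_year = 2016),
    1000 * 278.1 / 263.1 * 0.035 / (1 - 1.035^-5)
  )
})

test_that("capital is allocated by utilisation and trio throughput", {
  got <- capital_cost_per_trio(1000, 5, annual_maintenance = 50,
                               utilization_fraction = 0.01,
                               annual_trio_throughput = 33, ctx = ctx0)
  expect_equal(got, (1000 * 0.035 / (1 - 1.035^-5) + 50) * 0.01 / 33)
  expect_equal(round(got, 4), 0.0823)
  expect_equal(capital_cost_per_trio(1000, 5, 50, 0, 33, ctx0), 0)
  expect_equal(capital_cost_per_trio(1000, 5, 50, 1, 1, ctx0),
               annual_equivalent_cost(1000, 5, ctx0) + 50)
  expect_error(capital_cost_per_trio(1000, 5, 50, 0.5, 0, ctx0),
               class = "odysseycost_zero_throughput")
  # doubling throughput halves the per-trio charge
  expect_equal(capital_cost_per_trio(1000, 5, 50, 0.4, 66, ctx0),
               got / 0.01 * 0.4 / 2)
  # 100 samples a year is 33 whole trios
  expect_equal(trios_per_year(100, ctx0), 33)
})

test_that("staff tasks are costed at the chosen point of the time range", {
  expect_equal(staff_task_cost(15, 60, 45000, 1.2, 108000),
               37.5 * 45000 * 1.2 / 108000)
  expect_equal(staff_task_cost(0, 0, 45000, 1.5, 108000), 0)
  # a 5-20 min task is costed at 12.5 min by default
  mid <- staff_task_cost(5, 20, 40000, 1, 100000)
  expect_equal(mid, 12.5 * 0.4)
  expect_equal(staff_task_cost(5, 20, 40000, 1, 100000, time_point = "low"), 5 * 0.4)
  expect_equal(staff_task_cost(5, 20, 40000, 1, 100000, time_point = "high"), 20 * 0.4)
  expect_error(staff_task_cost(30, 10, 40000, 1, 100000))
})

test_that("batch runs amortise per sample and scale up to the trio", {
  expect_equal(batch_amortized_cost(240, 24, ctx0), 30)
  expect_equal(batch_amortized_cost(100, 3, ctx0), 100)   # one trio per batch
  expect_equal(batch_amortized_cost(100, 1, ctx0), 300)
})

test_that("stage costs weight branches by probability and isolate methods", {
  micro <- function(p_stage = 1, p_mdt = 1, salary = 40000) wgs_stage(
    "mdt", method = "micro", branch_probability = p_stage,
    components = list(staff = list(list(
      minutes_low = 5, minutes_high = 20, annual_salary_midpoint = salary,
      overhead_multiplier = 1, annual_working_minutes = 100000,
      probability = p_mdt
    )))
  )
  full <- expected_stage_cost(micro(), ctx0)
  expect_equal(expected_stage_cost(micro(p_mdt = 0.5), ctx0), 0.5 * full)
  expect_equal(expected_stage_cost(micro(p_stage = 0), ctx0), 0)
  # monotone non-decreasing in each probability
  ps <- seq(0, 1, by = 0.25)
  expect_true(all(diff(vapply(ps, function(p)
    expected_stage_cost(micro(p_mdt = p), ctx0), numeric(1))) >= 0))

  # charge stages ignore staff/capital parameters entirely
  ch <- wgs_stage("seq", method = "charge", charge_per_trio = 2550,
                  vat_applies = TRUE)
  expect_equal(expected_stage_cost(ch, ctx0), 3060)
  expect_equal(expected_stage_cost(ch, ctx0, time_point = "high"), 3060)
  cal <- wgs_stage("fixed", method = "calibrated", cost_per_trio = 132.63)
  expect_equal(expected_stage_cost(cal, ctx0), 132.63)
})

test_that("micro stages sum staff, consumable and capital components", {
  st <- wgs_stage("extraction", method = "micro", components = list(
    staff = list(list(minutes_low = 10, minutes_high = 30,
                      annual_salary_midpoint = 30000,
                      overhead_multiplier = 1.25,
                      annual_working_minutes = 100000)),
    consumables = list(list(batch_run_cost = 240, batch_size_samples = 24)),
    capital = list(list(purchase_price = 1000, lifetime_years = 5,
                        annual_maintenance = 50, utilization_fraction = 0.01,
                        annual_trio_throughput = 33))
  ))
  expect_equal(
    expected_stage_cost(st, ctx0),
    staff_task_cost(10, 30, 30000, 1.25, 100000) +
      batch_amortized_cost(240, 24, ctx0) +
      capital_cost_per_trio(1000, 5, 50, 0.01, 33, ctx0)
  )
  expect_error(wgs_stage("bad", method = "micro", charge_per_trio = 5))
  expect_error(wgs_stage("bad", method = "charge", cost_per_trio = 5))
})

test_that("the ledger conserves costs and its shares sum to about 100", {
  stages <- read_wgs_stages(odysseycost_example("wgs_stages_sgp_2018.yaml"))
  led <- cost_wgs_pipeline(stages, ctx0)
  td <- tidy(led)
  expect_equal(sum(td$cost_per_trio), led$total_per_trio)
  expect_equal(sum(td$share_pct), 100, tolerance = 1e-12)
  expect_true(abs(sum(round(td$share_pct, 2)) - 100) <= 0.1)
  expect_equal(nrow(td), 13)
  g <- glance(led)
  expect_equal(g$total_gbp, round(g$total_per_trio))
  expect_s3_class(autoplot(led), "ggplot")

  expect_error(cost_wgs_pipeline(list(), ctx0), class = "odysseycost_empty_stages")
  zero <- list(wgs_stage("z", method = "calibrated", cost_per_trio = 0))
  expect_warning(led0 <- cost_wgs_pipeline(zero, ctx0),
                 class = "odysseycost_zero_total")
  expect_equal(led0$total_per_trio, 0)
  expect_true(is.na(tidy(led0)$share_pct))
})

test_that("random synthetic pipelines conserve the ledger identity", {
  set.seed(505)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    stages <- purrr::map(seq_len(n), function(j) {
      method <- sample(c("charge", "calibrated"), 1)
      value <- round(stats::runif(1, 1, 2000), 2)
      args <- list(paste0("s", j), method = method,
                   branch_probability = stats::runif(1),
                   vat_applies = FALSE)
      args[[if (method == "charge") "charge_per_trio" else "cost_per_trio"]] <- value
      do.call(wgs_stage, args)
    })
    led <- cost_wgs_pipeline(stages, ctx0)
    td <- tidy(led)
    expect_equal(sum(td$cost_per_trio), led$total_per_trio, tolerance = 1e-12)
    expect_equal(sum(td$share_pct), 100, tolerance = 1e-9)
  }
})
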