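#' The 19 rare-disease categories used for cohort grouping
#'
#' Top-level rare-disease categories following the Genomics England
#' classification. The vector is also shipped as the editable vocabulary
#' file `odysseycost_example("rd_categories.txt")`.
#'
#' @return Character vector of 19 category labels.
#' @export
rd_categories <- function() {
  c(
    "intellectual disability",
    "neurodevelopmental and neurological disorders without intellectual disability",
    "cardiovascular disorders",
    "ciliopathies",
    "dermatological disorders",
    "dysmorphic and congenital abnormality syndromes",
    "endocrine disorders",
    "gastroenterological disorders",
    "genomic medicine service indications",
    "growth disorders",
    "haematological and immunological disorders",
    "hearing and ear disorders",
    "metabolic disorders",
    "neuromuscular disorders",
    "ophthalmological disorders",
    "renal and urinary tract disorders",
    "respiratory disorders",
    "skeletal disorders",
    "tumour syndromes"
  )
}

#' Default category mixing weights for the synthetic cohort
#'
#' Intellectual disability 37%, neurodevelopmental/neurological disorders
#' 21%; the remaining 17 categories share the residual 42% uniformly.
#'
#' @return Named numeric vector over [rd_categories()], summing to 1.
#' @export
default_category_weights <- function() {
  cats <- rd_categories()
  w <- setNames(rep((1 - 0.37 - 0.21) / 17, length(cats)), cats)
  w["intellectual disability"] <- 0.37
  w["neurodevelopmental and neurological disorders without intellectual disability"] <- 0.21
  w
}

#' Calibrate the per-proband cost distribution by closed form
#'
#' A right-skewed per-proband cost distribution is modelled as lognormal.
#' Matching the cohort mean \eqn{m} and median \eqn{q} inverts in closed
#' form: \eqn{\mu = \ln q} (the lognormal median is \eqn{e^\mu}) and, from
#' \eqn{m = e^{\mu + \sigma^2/2}}, \eqn{\sigma = \sqrt{2 \ln(m/q)}}. A
#' two-parameter lognormal cannot also match a separately reported SD;
#' mean and median are prioritised.
#'
#' @param target_mean Target mean cost, GBP; must exceed the median
#'   (right skew).
#' @param target_median Target median cost, GBP, positive.
#' @return List with `meanlog` and `sdlog`.
#' @examples
#' calibrate_cost_distribution(1013.03, 850)   # meanlog 6.7452, sdlog 0.5924
#' @export
calibrate_cost_distribution <- function(target_mean, target_median) {
  if (target_median <= 0) abort("`target_median` must be positive.")
  if (target_mean < target_median) {
    abort("`target_mean` below `target_median` contradicts the right-skew assumption.",
          class = "odysseycost_skew_violation")
  }
  list(
    meanlog = log(target_median),
    sdlog = sqrt(2 * log(target_mean / target_median))
  )
}

ztnb_pmf <- function(size, mu, ceiling) {
  k <- seq_len(ceiling)
  p <- dnbinom(k, size = size, mu = mu)
  s <- sum(p)
  if (s <= 0 || !is.finite(s)) return(rep(NA_real_, ceiling))
  p / s
}

ztnb_moments <- function(size, mu, ceiling) {
  k <- seq_len(ceiling)
  p <- ztnb_pmf(size, mu, ceiling)
  m <- sum(k * p)
  c(mean = m, sd = sqrt(sum(k^2 * p) - m^2))
}

#' Calibrate the per-proband test-count distribution
#'
#' Test counts are modelled as a negative binomial truncated to the support
#' `{1, ..., ceiling}` (zero-truncated, with draws above the ceiling
#' resampled; equivalently, the probability mass renormalised over the
#' support). The two free parameters are solved numerically so the
#' truncated mean and SD match the targets to within `tol`.
#'
#' @param target_mean Target mean tests per proband, > 1.
#' @param target_sd Target SD of tests per proband, > 0.
#' @param ceiling Maximum tests per proband (default 16).
#' @param tol Moment-matching tolerance (default 1e-3).
#' @return List with `size`, `mu`, `ceiling`, and the achieved
#'   `mean`/`sd` on the truncated support.
#' @export
calibrate_testcount_distribution <- function(target_mean, target_sd,
                                             ceiling = 16L, tol = 1e-3) {
  if (target_mean <= 1) abort("`target_mean` must exceed 1 on the zero-truncated support.")
  if (target_sd <= 0) abort("`target_sd` must be positive; a degenerate count has no dispersion to match.")
  if (target_mean >= ceiling) abort("`target_mean` must lie below `ceiling`.")
  obj <- function(par) {
    ms <- ztnb_moments(exp(par[1]), exp(par[2]), ceiling)
    if (anyNA(ms)) return(1e6)
    (ms[["mean"]] - target_mean)^2 + (ms[["sd"]] - target_sd)^2
  }
  fit <- optim(c(0, log(target_mean)), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  size <- exp(fit$par[1]); mu <- exp(fit$par[2])
  ms <- ztnb_moments(size, mu, ceiling)
  if (abs(ms[["mean"]] - target_mean) > tol || abs(ms[["sd"]] - target_sd) > tol) {
    abort(sprintf(
      "moments (mean %.3f, sd %.3f) not attainable on {1..%d} within %.0e.",
      target_mean, target_sd, ceiling, tol
    ), class = "odysseycost_infeasible_moments")
  }
  list(size = size, mu = mu, ceiling = as.integer(ceiling),
       mean = unname(ms[["mean"]]), sd = unname(ms[["sd"]]))
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: 393
#' screening forms of which 259 are costable; category mix 37% intellectual
#' disability, 21% neurodevelopmental/neurological, remainder uniform;
#' per-proband costs lognormal calibrated to mean 1013.03 / median 850 and
#' truncated to `[90, 6784.39]`; test counts mean 2.32 / SD 2.08 on
#' `{1..16}`.
#'
#' @param n_probands Costable probands (default 259).
#' @param n_submitted Submitted records including uncostable ones
#'   (default 393; must be >= `n_probands`).
#' @param category_weights Named weights over [rd_categories()], summing
#'   to 1.
#' @param cost_mean,cost_median Cost calibration targets, GBP.
#' @param cost_range Truncation bounds for per-proband costs, GBP.
#' @param count_mean,count_sd Test-count calibration targets.
#' @param count_ceiling Maximum tests per proband.
#' @param seed Integer seed governing all randomness in
#'   [simulate_cohort()].
#' @return A `cohort_config` list, with the calibrated `cost_dist` and
#'   `count_dist` parameters attached.
#' @export
cohort_config <- function(n_probands = 259L, n_submitted = 393L,
                          category_weights = default_category_weights(),
                          cost_mean = 1013.03, cost_median = 850,
                          cost_range = c(90, 6784.39),
                          count_mean = 2.32, count_sd = 2.08,
                          count_ceiling = 16L, seed = 1L) {
  stopifnot(
    n_probands >= 1, n_submitted >= n_probands,
    length(cost_range) == 2L, cost_range[1] < cost_range[2]
  )
  if (abs(sum(category_weights) - 1) > 1e-9) {
    abort("`category_weights` must sum to 1.")
  }
  if (is.null(names(category_weights))) abort("`category_weights` must be named.")
  structure(
    list(
      n_probands = as.integer(n_probands),
      n_submitted = as.integer(n_submitted),
      category_weights = category_weights,
      cost_dist = calibrate_cost_distribution(cost_mean, cost_median),
      cost_range = cost_range,
      count_dist = calibrate_testcount_distribution(count_mean, count_sd, count_ceiling),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

rlnorm_truncated <- function(n, meanlog, sdlog, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(max(n, 100L), meanlog, sdlog)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic proband cohort with a matching costbook
#'
#' Draws a rare-disease category, a test count and a total testing cost for
#' every proband, apportions each cost across the proband's tests with
#' uniform Dirichlet weights, and emits a costbook pricing every synthetic
#' test so that running [cost_pathways()] on the histories reproduces the
#' drawn totals exactly. The `n_submitted - n_probands` extra records each
#' carry one unidentifiable test name absent from the costbook (emulating
#' illegible screening forms) and are excluded by [filter_costable()].
#' All randomness flows from `config$seed`; the same seed yields identical
#' output.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` list: `histories` (one row per test),
#'   `costbook`, `ground_truth` (per-proband `category`, `n_tests`,
#'   `true_cost` for the costable probands), and `config`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_probands = 40, n_submitted = 50, seed = 7))
#' mean(coh$ground_truth$true_cost)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_all <- config$n_submitted
  n_cost <- config$n_probands
  n_excl <- n_all - n_cost

  ids <- sprintf("SP%04d", seq_len(n_all))
  categories <- sample(names(config$category_weights), n_all, replace = TRUE,
                       prob = config$category_weights)
  cd <- config$count_dist
  counts <- sample(seq_len(cd$ceiling), n_all, replace = TRUE,
                   prob = ztnb_pmf(cd$size, cd$mu, cd$ceiling))
  costable <- c(rep(TRUE, n_cost), rep(FALSE, n_excl))

  true_cost <- rlnorm_truncated(n_all, config$cost_dist$meanlog,
                                config$cost_dist$sdlog,
                                config$cost_range[1], config$cost_range[2])

  # one row per test; Dirichlet(1) split of each proband's total via
  # normalised exponentials
  idx <- rep(seq_len(n_all), counts)
  test_no <- sequence(counts)
  w <- rexp(length(idx))
  test_cost <- true_cost[idx] * w / stats::ave(w, idx, FUN = sum)
  name <- sprintf("SYN-%04d-T%02d", idx, test_no)
  illegible <- !costable[idx] & test_no == 1L
  name[illegible] <- sprintf("ILLEGIBLE-%04d", idx[illegible])
  per_proband <- tibble(
    proband_id = ids[idx], category = categories[idx], test_name = name,
    unit_cost = test_cost, priced = !illegible
  )

  histories <- per_proband[c("proband_id", "category", "test_name")]
  priced <- per_proband[per_proband$priced, , drop = FALSE]
  n_e <- nrow(priced)
  cb <- costbook(tibble(
    test_name = priced$test_name,
    test_class = sample(c("single_gene", "gene_panel", "epigenetic"), n_e,
                        replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    amplicon_count = ifelse(stats::runif(n_e) < 0.3,
                            sample(1:60, n_e, replace = TRUE), NA_integer_),
    cost_gbp = priced$unit_cost,
    price_year = 2018L,
    tier = sample(c("scotland_lab", "uk_lab"), n_e, replace = TRUE,
                  prob = c(0.8, 0.2))
  ))

  ground_truth <- tibble(
    proband_id = ids[costable], category = categories[costable],
    n_tests = counts[costable], true_cost = true_cost[costable]
  )

  structure(
    list(histories = histories, costbook = cb, ground_truth = ground_truth,
         config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d submitted records (%d costable, %d with unidentifiable tests); seed %d\n",
    x$config$n_submitted, x$config$n_probands,
    x$config$n_submitted - x$config$n_probands, x$config$seed
  ))
  invisible(x)
}

#' Write a synthetic cohort to disk in the dialects the pipeline consumes
#'
#' Emits `histories.csv`, `costbook.csv`, `ground_truth.csv` and
#' `metadata.json` (seed and calibration parameters) under `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("histories.csv", "costbook.csv",
                            "ground_truth.csv", "metadata.json"))
  readr::write_csv(cohort$histories, paths[1])
  cb <- as_tibble(cohort$costbook)
  readr::write_csv(cb[c("test_name", "test_class", "amplicon_count",
                        "cost_gbp", "price_year", "tier")], paths[2])
  readr::write_csv(cohort$ground_truth, paths[3])
  cfg <- cohort$config
  jsonlite::write_json(
    list(seed = cfg$seed, n_probands = cfg$n_probands,
         n_submitted = cfg$n_submitted, cost_dist = cfg$cost_dist,
         cost_range = cfg$cost_range,
         count_dist = cfg$count_dist[c("size", "mu", "ceiling")]),
    paths[4], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
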