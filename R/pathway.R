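#' Hospital-attendance costing policy
#'
#' The standard testing pathway is assumed to involve a fixed number of
#' general outpatient and clinical-genetics outpatient attendances per
#' proband, each at a unit cost from national reference costs. Defaults are
#' two general attendances at \eqn{\pounds}295.61 and one genetics
#' attendance at \eqn{\pounds}236.78, giving \eqn{\pounds}828.00 per
#' proband; all four numbers are editable.
#'
#' @param n_general Number of general outpatient attendances (default 2).
#' @param n_genetics Number of clinical-genetics attendances (default 1).
#' @param unit_cost_general Unit cost of a general attendance, GBP.
#' @param unit_cost_genetics Unit cost of a genetics attendance, GBP.
#' @return An `attendance_policy` object.
#' @examples
#' attendance_cost(attendance_policy())                 # 828.00
#' attendance_cost(attendance_policy(n_genetics = 2))   # 1064.78
#' @export
attendance_policy <- function(n_general = 2L, n_genetics = 1L,
                              unit_cost_general = 295.61,
                              unit_cost_genetics = 236.78) {
  stopifnot(
    n_general >= 0, n_genetics >= 0,
    unit_cost_general >= 0, unit_cost_genetics >= 0
  )
  structure(
    list(
      n_general = n_general, n_genetics = n_genetics,
      unit_cost_general = unit_cost_general,
      unit_cost_genetics = unit_cost_genetics
    ),
    class = "attendance_policy"
  )
}

#' @rdname attendance_policy
#' @param policy An `attendance_policy`.
#' @export
attendance_cost <- function(policy) {
  stopifnot(inherits(policy, "attendance_policy"))
  policy$n_general * policy$unit_cost_general +
    policy$n_genetics * policy$unit_cost_genetics
}

#' Read per-proband testing histories
#'
#' One row per test: columns `proband_id`, `category` (rare-disease
#' category), `test_name`, and optionally `amplicon_count` for the bin
#' fallback. Date or timestamp columns, if present, are ignored with a
#' warning: testing dates were not modelled, so costs are never annualised.
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @export
read_histories <- function(path) {
  if (!file.exists(path)) abort(sprintf("histories file not found: %s", path))
  h <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_guess()))
  required <- c("proband_id", "category", "test_name")
  missing_cols <- setdiff(required, names(h))
  if (length(missing_cols)) {
    abort(sprintf("histories file is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  datelike <- grep("date|time", names(h), ignore.case = TRUE, value = TRUE)
  if (length(datelike)) {
    warn(sprintf(
      "ignoring date/time column(s) %s: costs are not annualised.",
      paste(datelike, collapse = ", ")
    ))
  }
  h$proband_id <- as.character(h$proband_id)
  if (!"amplicon_count" %in% names(h)) h$amplicon_count <- NA_integer_
  as_tibble(h)
}

#' Resolve per-test costs for a testing-history table
#'
#' @param histories Tibble with one row per test (`proband_id`, `category`,
#'   `test_name`, optional `amplicon_count`).
#' @param costbook A [costbook()].
#' @return `histories` with `cost`, `tier` and `costable` columns appended.
#' @export
cost_tests <- function(histories, costbook) {
  histories <- as_tibble(histories)
  if (!"amplicon_count" %in% names(histories)) histories$amplicon_count <- NA_integer_
  resolved <- lookup_unit_cost(costbook, histories$test_name, histories$amplicon_count)
  dplyr::bind_cols(histories, resolved[c("cost", "tier", "costable")])
}

#' Split probands into costable and excluded
#'
#' A proband is excluded if any of their tests cannot be costed (no
#' authoritative costbook entry and no amplicon/exon count for the bin
#' fallback). This mirrors the exclusion of screening forms with missing or
#' unidentifiable test names: no partial costing is attempted, since a
#' partial total would understate the pathway cost.
#'
#' @inheritParams cost_tests
#' @return A list with `included` (per-test tibble with resolved costs for
#'   costable probands) and `excluded` (one row per excluded proband:
#'   `proband_id`, `category`, `n_tests`, `n_uncostable`, `reason`).
#' @export
filter_costable <- function(histories, costbook) {
  resolved <- cost_tests(histories, costbook)
  by_proband <- resolved |>
    group_by(.data$proband_id) |>
    summarise(all_costable = all(.data$costable | is.na(.data$test_name)), .groups = "drop")
  bad_ids <- by_proband$proband_id[!by_proband$all_costable]

  excluded <- resolved |>
    filter(.data$proband_id %in% bad_ids) |>
    group_by(.data$proband_id, .data$category) |>
    summarise(
      n_tests = sum(!is.na(.data$test_name)),
      n_uncostable = sum(!.data$costable),
      uncostable_tests = paste(.data$test_name[!.data$costable], collapse = "; "),
      .groups = "drop"
    ) |>
    mutate(reason = sprintf(
      "%d of %d test(s) uncostable: %s", .data$n_uncostable, .data$n_tests,
      .data$uncostable_tests
    )) |>
    select(-"uncostable_tests")

  list(
    included = filter(resolved, !.data$proband_id %in% bad_ids),
    excluded = excluded
  )
}

#' Cost each proband's genetic-testing sub-odyssey
#'
#' Sums resolved per-test unit costs for each proband and adds the fixed
#' attendance cost from `policy`. All probands must be costable: run
#' [filter_costable()] first (or set `uncostable = "drop"` to exclude them
#' with a warning). Probands whose only history row has a missing
#' `test_name` are treated as having zero recorded tests: they are retained
#' with a zero test total and flagged with a warning.
#'
#' @inheritParams cost_tests
#' @param policy An [attendance_policy()].
#' @param uncostable `"error"` (default) or `"drop"`.
#' @return A tibble, one row per proband: `proband_id`, `category`,
#'   `n_tests`, `test_total`, `attendance_total`, `grand_total`.
#' @examples
#' cb <- costbook(tibble::tibble(
#'   test_name = c("t1", "t2"), test_class = "single_gene",
#'   amplicon_count = NA_integer_, cost_gbp = c(100, 200),
#'   price_year = 2018L, tier = "scotland_lab"
#' ))
#' h <- tibble::tibble(
#'   proband_id = "p1", category = "intellectual disability",
#'   test_name = c("t1", "t2")
#' )
#' cost_pathways(h, cb)   # test_total 300, grand_total 1128
#' @export
cost_pathways <- function(histories, costbook, policy = attendance_policy(),
                          uncostable = c("error", "drop")) {
  uncostable <- match.arg(uncostable)
  resolved <- if ("costable" %in% names(histories)) as_tibble(histories) else cost_tests(histories, costbook)

  bad <- resolved$proband_id[!resolved$costable & !is.na(resolved$test_name)]
  if (length(bad)) {
    if (uncostable == "error") {
      abort(sprintf(
        "%d proband(s) have uncostable tests (e.g. %s); run filter_costable() or use uncostable = \"drop\".",
        length(unique(bad)), paste(head(unique(bad), 3), collapse = ", ")
      ), class = "odysseycost_uncostable")
    }
    warn(sprintf("dropping %d proband(s) with uncostable tests.", length(unique(bad))))
    resolved <- filter(resolved, !.data$proband_id %in% bad)
  }

  att <- attendance_cost(policy)
  out <- resolved |>
    group_by(.data$proband_id, .data$category) |>
    summarise(
      n_tests = sum(!is.na(.data$test_name)),
      test_total = sum(.data$cost[!is.na(.data$test_name)]),
      .groups = "drop"
    ) |>
    mutate(
      attendance_total = att,
      grand_total = .data$test_total + .data$attendance_total
    )
  if (any(out$n_tests == 0L)) {
    warn(sprintf("%d proband(s) have zero recorded tests (test total 0).", sum(out$n_tests == 0L)))
  }
  out
}

#' Flag box-plot outliers with Tukey fences
#'
#' Standard box-plot rule: points strictly outside
#' \eqn{[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]} are outliers,
#' with quartiles by linear interpolation between order statistics
#' ([stats::quantile()] type 7). On-fence values are not outliers. Requires
#' at least 4 points.
#'
#' @param x Numeric vector of costs.
#' @param k Fence multiplier (default 1.5).
#' @return Integer indices of outlying elements (possibly empty).
#' @export
flag_outliers <- function(x, k = 1.5) {
  x <- as.numeric(x)
  if (length(x) < 4L) {
    abort("at least 4 observations are needed for Tukey fences.",
          class = "odysseycost_too_few_points")
  }
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  which(x < q[1] - k * iqr | x > q[2] + k * iqr)
}

#' Summarise pathway costs over the cohort or by category
#'
#' Computes n, mean, SD, median, min, max and IQR of a chosen cost column,
#' overall and/or per rare-disease category, with Tukey-fence outlier
#' identification for groups of at least 4. Outliers are identified but
#' never removed from the statistics. Groups with a single member report
#' SD 0 and are flagged degenerate; groups with n of 2 or less are flagged
#' `small_group` (box plots are conventionally drawn only for n > 2).
#'
#' @param costs Per-proband cost tibble from [cost_pathways()].
#' @param by `"overall"`, `"category"`, or both.
#' @param value Name of the cost column to summarise (default
#'   `"grand_total"`).
#' @return A tibble with one row per group: `grouping`, `group`, `n`,
#'   `mean`, `sd`, `median`, `min`, `max`, `iqr`, `n_outliers`,
#'   `outlier_ids` (list-column), `degenerate`, `small_group`.
#' @export
summarize_cohort <- function(costs, by = c("overall", "category"),
                             value = "grand_total") {
  by <- match.arg(by, several.ok = TRUE)
  costs <- as_tibble(costs)
  if (!nrow(costs)) abort("empty cohort.", class = "odysseycost_empty_cohort")
  if (!value %in% names(costs)) abort(sprintf("no column '%s' in `costs`.", value))

  one_group <- function(v, ids, grouping, group) {
    out_idx <- if (length(v) >= 4L) flag_outliers(v) else integer(0)
    tibble(
      grouping = grouping, group = group, n = length(v),
      mean = mean(v), sd = if (length(v) > 1L) sd(v) else 0,
      median = median(v), min = min(v), max = max(v),
      iqr = unname(diff(quantile(v, c(0.25, 0.75), type = 7))),
      n_outliers = length(out_idx), outlier_ids = list(ids[out_idx]),
      degenerate = length(v) == 1L, small_group = length(v) <= 2L
    )
  }

  res <- list()
  if ("overall" %in% by) {
    res <- c(res, list(one_group(costs[[value]], costs$proband_id, "overall", "all")))
  }
  if ("category" %in% by) {
    res <- c(res, unname(map(
      split(costs, costs$category),
      function(g) one_group(g[[value]], g$proband_id, "category", g$category[1])
    )))
  }
  bind_rows(res)
}

#' Box-plot of pathway costs by rare-disease category
#'
#' Draws a Tukey box plot of per-proband costs for each category with at
#' least `min_n` probands; outliers appear as points beyond the whiskers.
#'
#' @param costs Per-proband cost tibble from [cost_pathways()].
#' @param value Cost column to plot (default `"grand_total"`).
#' @param min_n Minimum category size to draw (default 3).
#' @return A ggplot object.
#' @export
plot_category_costs <- function(costs, value = "grand_total", min_n = 3L) {
  keepers <- costs |>
    dplyr::count(.data$category) |>
    filter(n >= min_n) |>
    pull("category")
  plot_dat <- filter(costs, .data$category %in% keepers)
  if (!nrow(plot_dat)) abort("no category reaches `min_n` probands.")
  ggplot2::ggplot(plot_dat, ggplot2::aes(
    x = stats::reorder(.data$category, .data[[value]], FUN = stats::median),
    y = .data[[value]]
  )) +
    ggplot2::geom_boxplot(outlier.shape = 16, fill = "grey85") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Cost per proband (GBP)",
      title = "Standard genetic-testing pathway cost by rare-disease category"
    ) +
    ggplot2::theme_minimal()
}
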