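#' Annual equivalent cost of a capital purchase
#'
#' Converts a capital purchase price to a constant annual charge over the
#' equipment lifetime, discounted at the context's rate: the annuity
#' \deqn{AEC = K \cdot r / (1 - (1+r)^{-L})}
#' where `K` is the price inflated to the base year, `r` the discount rate
#' and `L` the lifetime in years. At `r = 0` this reduces to straight-line
#' `K / L`.
#'
#' @param purchase_price Purchase price in GBP at `price_year` prices.
#' @param lifetime_years Equipment lifetime, whole years, at least 1.
#' @param ctx An [economic_context()] supplying the discount rate and base
#'   year.
#' @param price_year Year the price is expressed in (default: the context's
#'   base year, i.e. no inflation adjustment).
#' @return Annual equivalent cost, GBP per year.
#' @examples
#' ctx <- economic_context()
#' annual_equivalent_cost(1000, 5, ctx)   # 221.48/year at 3.5%
#' @export
annual_equivalent_cost <- function(purchase_price, lifetime_years, ctx,
                                   price_year = ctx$base_year) {
  stopifnot(purchase_price >= 0, lifetime_years >= 1)
  k <- inflate_to_base_year(purchase_price, price_year, ctx)
  r <- ctx$discount_rate
  if (r == 0) k / lifetime_years else k * r / (1 - (1 + r)^(-lifetime_years))
}

#' Per-trio share of an item of capital equipment
#'
#' Annualises the purchase with [annual_equivalent_cost()], adds annual
#' maintenance, scales by the fraction of equipment time used for
#' whole-genome sequencing, and divides by the laboratory's annual trio
#' throughput.
#'
#' @inheritParams annual_equivalent_cost
#' @param annual_maintenance Maintenance cost, GBP per year (base-year
#'   prices).
#' @param utilization_fraction Fraction of equipment time attributable to
#'   WGS, in `[0, 1]`.
#' @param annual_trio_throughput Trios processed per year (> 0). A
#'   laboratory running 100 samples a year processes
#'   `floor(100 / 3) = 33` trios.
#' @return Capital cost in GBP per trio.
#' @export
capital_cost_per_trio <- function(purchase_price, lifetime_years,
                                  annual_maintenance, utilization_fraction,
                                  annual_trio_throughput, ctx,
                                  price_year = ctx$base_year) {
  stopifnot(
    annual_maintenance >= 0,
    utilization_fraction >= 0, utilization_fraction <= 1
  )
  if (annual_trio_throughput <= 0) {
    abort("`annual_trio_throughput` must be positive.",
          class = "odysseycost_zero_throughput")
  }
  aec <- annual_equivalent_cost(purchase_price, lifetime_years, ctx, price_year)
  (aec + annual_maintenance) * utilization_fraction / annual_trio_throughput
}

#' Annual trio throughput implied by a sample throughput
#'
#' Integer-division convention: `floor(samples / samples_per_trio)`.
#'
#' @param annual_samples Samples per year.
#' @param ctx An [economic_context()].
#' @return Whole trios per year.
#' @export
trios_per_year <- function(annual_samples, ctx = economic_context()) {
  floor(annual_samples / ctx$samples_per_trio)
}

#' Cost of a staff task from its time range and salary
#'
#' Staff time is valued at the salary-grade midpoint with an overhead
#' multiplier for clinic and laboratory overheads. Task durations are
#' recorded as a low-high range; the costed duration is the midpoint by
#' default, switchable to the low or high bound for sensitivity scenarios.
#'
#' @param minutes_low,minutes_high Task duration range in minutes,
#'   `0 <= low <= high`.
#' @param annual_salary_midpoint Salary-grade midpoint, GBP per year.
#' @param overhead_multiplier Multiplier of at least 1 covering overheads.
#' @param annual_working_minutes Productive minutes per working year.
#' @param time_point Which point of the duration range to cost:
#'   `"mid"` (default), `"low"` or `"high"`.
#' @return Task cost in GBP.
#' @examples
#' # a 15-60 min task is costed at 37.5 min
#' staff_task_cost(15, 60, 45000, 1.2, 108000)
#' @export
staff_task_cost <- function(minutes_low, minutes_high, annual_salary_midpoint,
                            overhead_multiplier = 1,
                            annual_working_minutes = 108000,
                            time_point = c("mid", "low", "high")) {
  time_point <- match.arg(time_point)
  stopifnot(
    minutes_low >= 0, minutes_high >= minutes_low,
    annual_salary_midpoint >= 0, overhead_multiplier >= 1,
    annual_working_minutes > 0
  )
  minutes <- switch(time_point,
    low = minutes_low,
    high = minutes_high,
    mid = (minutes_low + minutes_high) / 2
  )
  minutes * annual_salary_midpoint * overhead_multiplier / annual_working_minutes
}

#' Per-trio cost of a batch-run consumable step
#'
#' Laboratory steps run in batches of samples (e.g. DNA extraction in
#' batches of 24); the run cost is split per sample and multiplied up to
#' the trio.
#'
#' @param batch_run_cost Cost of one batch run, GBP.
#' @param batch_size_samples Samples per batch, at least 1.
#' @param ctx An [economic_context()] supplying `samples_per_trio`.
#' @return Cost in GBP per trio.
#' @export
batch_amortized_cost <- function(batch_run_cost, batch_size_samples,
                                 ctx = economic_context()) {
  stopifnot(batch_run_cost >= 0, batch_size_samples >= 1)
  batch_run_cost / batch_size_samples * ctx$samples_per_trio
}

#' Define one stage of the WGS costing pipeline
#'
#' A stage is costed by exactly one of three methods: `micro` (built up
#' from staff tasks, batch consumables and capital items, each optionally
#' probability-weighted), `charge` (a price invoiced by an external
#' provider), or `calibrated` (a per-trio cost taken as given, used when a
#' stage's total is known but its internal composition is not). The whole
#' stage may additionally carry a branch probability (e.g. an MDT review
#' needed for 50% of cases), and external charges may attract VAT.
#'
#' @param name Stage name.
#' @param method `"micro"`, `"charge"` or `"calibrated"`.
#' @param charge_per_trio Net per-trio charge, GBP (method `"charge"`).
#' @param cost_per_trio Per-trio cost, GBP (method `"calibrated"`).
#' @param components For method `"micro"`: a list with any of `staff`,
#'   `consumables`, `capital`, each a list of parameter lists matching
#'   [staff_task_cost()], [batch_amortized_cost()] and
#'   [capital_cost_per_trio()] arguments, plus an optional `probability`.
#' @param branch_probability Probability the stage occurs at all, in
#'   `[0, 1]` (default 1).
#' @param vat_applies Should VAT be added to the stage cost?
#' @param assumptions Free-text assumptions note carried into reports.
#' @return A `wgs_stage` object.
#' @export
wgs_stage <- function(name, method = c("micro", "charge", "calibrated"),
                      charge_per_trio = NULL, cost_per_trio = NULL,
                      components = NULL, branch_probability = 1,
                      vat_applies = FALSE, assumptions = "") {
  method <- match.arg(method)
  stopifnot(
    is.character(name), nzchar(name),
    branch_probability >= 0, branch_probability <= 1
  )
  given <- c(
    charge = !is.null(charge_per_trio),
    calibrated = !is.null(cost_per_trio),
    micro = !is.null(components)
  )
  if (!given[[method]] || sum(given) != 1L) {
    abort(sprintf(
      "stage '%s': method '%s' requires exactly its own cost input (%s).",
      name, method,
      switch(method, charge = "charge_per_trio", calibrated = "cost_per_trio",
             micro = "components")
    ))
  }
  structure(
    list(
      name = name, method = method, charge_per_trio = charge_per_trio,
      cost_per_trio = cost_per_trio, components = components,
      branch_probability = branch_probability, vat_applies = vat_applies,
      assumptions = assumptions
    ),
    class = "wgs_stage"
  )
}

component_cost <- function(kind, params, ctx, time_point) {
  p <- params$probability %||% 1
  stopifnot(p >= 0, p <= 1)
  params$probability <- NULL
  base <- switch(kind,
    staff = do.call(staff_task_cost, c(params, list(time_point = time_point))),
    consumables = do.call(batch_amortized_cost, c(params, list(ctx = ctx))),
    capital = do.call(capital_cost_per_trio, c(params, list(ctx = ctx)))
  )
  p * base
}

#' Probability-weighted per-trio cost of one stage
#'
#' Micro stages sum their component costs (each component weighted by its
#' own probability); charge and calibrated stages pass their per-trio value
#' through. VAT is added when the stage is flagged, and the whole stage is
#' then weighted by its branch probability.
#'
#' @param stage A [wgs_stage()].
#' @param ctx An [economic_context()].
#' @param time_point Duration scenario passed to [staff_task_cost()].
#' @return Expected cost in GBP per trio.
#' @export
expected_stage_cost <- function(stage, ctx, time_point = "mid") {
  stopifnot(inherits(stage, "wgs_stage"))
  base <- switch(stage$method,
    charge = stage$charge_per_trio,
    calibrated = stage$cost_per_trio,
    micro = sum(map_dbl(
      names(stage$components),
      function(kind) sum(map_dbl(
        stage$components[[kind]],
        function(params) component_cost(kind, params, ctx, time_point)
      ))
    ))
  )
  if (isTRUE(stage$vat_applies)) base <- apply_vat(base, ctx)
  stage$branch_probability * base
}

#' Read a WGS stage configuration from YAML or JSON
#'
#' The file holds a top-level `stages` list; each entry maps directly onto
#' the [wgs_stage()] arguments. The configuration shipped at
#' `odysseycost_example("wgs_stages_sgp_2018.yaml")` encodes the 13-stage
#' 2018 trio pathway of a Scottish regional genetics centre.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` stage configuration.
#' @return A list of `wgs_stage` objects.
#' @export
read_wgs_stages <- function(path) {
  if (!file.exists(path)) abort(sprintf("stage configuration not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$stages) || !length(cfg$stages)) {
    abort("stage configuration has no `stages` entries.")
  }
  map(cfg$stages, function(s) do.call(wgs_stage, s))
}

#' Cost the whole WGS pipeline and build the stage ledger
#'
#' Evaluates [expected_stage_cost()] for every stage and assembles a
#' per-trio ledger: stage costs, each stage's percentage share of the
#' full-precision total, and the total itself. Presentation rounding (2 dp
#' money and shares, nearest-pound headline total) happens only in
#' [render_reports()], [print()][print.wgs_ledger] and [tidy()] output; the
#' ledger keeps full precision so the shares sum to 100 exactly.
#'
#' @param stages A list of [wgs_stage()] objects, e.g. from
#'   [read_wgs_stages()].
#' @param ctx An [economic_context()].
#' @param time_point Duration scenario for staff tasks (`"mid"`, `"low"`,
#'   `"high"`).
#' @return A `wgs_ledger` object; see [tidy.wgs_ledger()] and
#'   [glance.wgs_ledger()].
#' @examples
#' ctx <- economic_context()
#' stages <- read_wgs_stages(odysseycost_example("wgs_stages_sgp_2018.yaml"))
#' ledger <- cost_wgs_pipeline(stages, ctx)
#' glance(ledger)   # total 6625 GBP per trio
#' @export
cost_wgs_pipeline <- function(stages, ctx, time_point = "mid") {
  if (!length(stages)) abort("empty stage list.", class = "odysseycost_empty_stages")
  stopifnot(all(map_lgl(stages, inherits, "wgs_stage")))
  costs <- map_dbl(stages, expected_stage_cost, ctx = ctx, time_point = time_point)
  total <- sum(costs)
  if (total == 0) {
    warn("all stage costs are zero; percentage shares are undefined.",
         class = "odysseycost_zero_total")
    shares <- rep(NA_real_, length(costs))
  } else {
    shares <- costs / total * 100
  }
  structure(
    list(
      stages = tibble(
        stage = map_chr(stages, "name"),
        method = map_chr(stages, "method"),
        assumptions = map_chr(stages, function(s) s$assumptions %||% ""),
        cost_per_trio = costs,
        share_pct = shares
      ),
      total_per_trio = total,
      context = ctx,
      time_point = time_point
    ),
    class = "wgs_ledger"
  )
}

#' @describeIn cost_wgs_pipeline Tidy the ledger into one row per stage
#'   (`stage`, `method`, `cost_per_trio`, `share_pct`, full precision).
#' @param x A `wgs_ledger`.
#' @param ... Unused.
#' @export
tidy.wgs_ledger <- function(x, ...) x$stages

#' @describeIn cost_wgs_pipeline One-row summary: stage count,
#'   full-precision total, the nearest-pound headline total, and the
#'   largest stage with its share.
#' @export
glance.wgs_ledger <- function(x, ...) {
  i <- which.max(x$stages$cost_per_trio)
  tibble(
    n_stages = nrow(x$stages),
    total_per_trio = x$total_per_trio,
    total_gbp = round(x$total_per_trio),
    largest_stage = x$stages$stage[i],
    largest_share_pct = x$stages$share_pct[i]
  )
}

#' @export
print.wgs_ledger <- function(x, ...) {
  cat(sprintf("<wgs_ledger> %d stages, GBP %.2f per trio (headline GBP %d)\n",
              nrow(x$stages), x$total_per_trio, round(x$total_per_trio)))
  df <- x$stages
  df$cost_per_trio <- sprintf("%.2f", df$cost_per_trio)
  df$share_pct <- sprintf("%.2f%%", df$share_pct)
  print(as.data.frame(df[c("stage", "method", "cost_per_trio", "share_pct")]),
        row.names = FALSE, right = FALSE)
  invisible(x)
}

#' @describeIn cost_wgs_pipeline Bar chart of each stage's share of the
#'   per-trio total.
#' @param object A `wgs_ledger`.
#' @export
autoplot.wgs_ledger <- function(object, ...) {
  ggplot2::ggplot(object$stages, ggplot2::aes(
    x = stats::reorder(.data$stage, .data$cost_per_trio),
    y = .data$cost_per_trio, fill = .data$method
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Cost per trio (GBP)", fill = "Costing method",
      title = sprintf("Trio WGS cost ledger (total GBP %d per trio)",
                      round(object$total_per_trio))
    ) +
    ggplot2::theme_minimal()
}

#' Path to a packaged example or fixture file
#'
#' @param file File name under the package's `extdata/`; with no argument,
#'   lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
odysseycost_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "odysseycost"))
  } else {
    path <- system.file("extdata", file, package = "odysseycost")
    if (!nzchar(path)) abort(sprintf("no packaged file '%s'.", file))
    path
  }
}
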