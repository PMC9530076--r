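#' Economic context for a costing run
#'
#' Bundles the price year, discount rate, VAT rate, number of samples per
#' family trio and an annual inflation-index series (RPI-style) into a single
#' object passed to every costing function. Historical prices are re-expressed
#' in base-year pounds with the index ratio, capital is annuitized at
#' `discount_rate`, and VAT is applied to external charges flagged as
#' VAT-bearing.
#'
#' @param base_year Calendar year all money is expressed in (default 2018).
#' @param discount_rate Annual discount rate used for capital annuitization,
#'   as a fraction (default 0.035, the standard UK health-technology-assessment
#'   rate).
#' @param vat_rate Value-added-tax rate as a fraction (default 0.20, the UK
#'   standard rate).
#' @param samples_per_trio Samples sequenced per family trio (default 3:
#'   proband plus both parents).
#' @param inflation_index Named numeric vector or single-level list mapping
#'   calendar years (names) to index values, e.g. UK RPI annual averages. Must
#'   cover `base_year` and every price year encountered.
#' @return An object of class `economic_context` (a named list).
#' @examples
#' ctx <- economic_context(inflation_index = c("2016" = 263.1, "2018" = 278.1))
#' inflate_to_base_year(100, 2016, ctx)
#' apply_vat(2550, ctx)
#' @export
economic_context <- function(base_year = 2018,
                             discount_rate = 0.035,
                             vat_rate = 0.20,
                             samples_per_trio = 3L,
                             inflation_index = default_inflation_index()) {
  inflation_index <- unlist(inflation_index)
  if (is.null(names(inflation_index)) || anyNA(suppressWarnings(as.integer(names(inflation_index))))) {
    abort("`inflation_index` must be named by calendar year.")
  }
  stopifnot(
    is.numeric(base_year), length(base_year) == 1L,
    is.numeric(discount_rate), discount_rate >= 0,
    is.numeric(vat_rate), vat_rate >= 0,
    samples_per_trio >= 1
  )
  if (!as.character(base_year) %in% names(inflation_index)) {
    abort(sprintf("inflation index has no entry for base year %d", as.integer(base_year)))
  }
  structure(
    list(
      base_year = as.integer(base_year),
      discount_rate = discount_rate,
      vat_rate = vat_rate,
      samples_per_trio = as.integer(samples_per_trio),
      inflation_index = inflation_index
    ),
    class = "economic_context"
  )
}

#' @export
print.economic_context <- function(x, ...) {
  cat(sprintf(
    "<economic_context> base year %d | discount %.1f%% | VAT %.0f%% | %d samples/trio | index %s-%s\n",
    x$base_year, 100 * x$discount_rate, 100 * x$vat_rate, x$samples_per_trio,
    min(names(x$inflation_index)), max(names(x$inflation_index))
  ))
  invisible(x)
}

#' Default UK RPI annual-average index series
#'
#' ONS Retail Prices Index annual averages (1987 = 100) for 2013-2018, the
#' window relevant to 2018-base costings. Editable: pass your own series to
#' [economic_context()] for other windows or indices.
#'
#' @return Named numeric vector, year -> index value.
#' @export
default_inflation_index <- function() {
  c("2013" = 250.1, "2014" = 255.7, "2015" = 257.0,
    "2016" = 263.1, "2017" = 272.5, "2018" = 278.1)
}

#' Read an economic context from a YAML or JSON config file
#'
#' Expected keys: `base_year`, `discount_rate`, `vat_rate`,
#' `samples_per_trio`, `inflation_index` (a year -> value mapping). Missing
#' keys fall back to the [economic_context()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `economic_context`.
#' @export
read_economic_context <- function(path) {
  if (!file.exists(path)) abort(sprintf("context file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- cfg[intersect(
    names(cfg),
    c("base_year", "discount_rate", "vat_rate", "samples_per_trio", "inflation_index")
  )]
  do.call(economic_context, args)
}

index_at <- function(ctx, year) {
  key <- as.character(as.integer(year))
  idx <- ctx$inflation_index[key]
  if (anyNA(idx)) {
    abort(sprintf(
      "inflation index missing for year(s): %s",
      paste(unique(key[is.na(idx)]), collapse = ", ")
    ), class = "odysseycost_missing_index")
  }
  unname(idx)
}

#' Re-express a historical cost in base-year pounds
#'
#' Multiplies by the ratio of the inflation index at the context's base year
#' to the index at `price_year`. Identity when `price_year` equals the base
#' year. Vectorised over `cost` and `price_year`.
#'
#' @param cost Non-negative cost(s) in GBP at `price_year` prices.
#' @param price_year Calendar year(s) the cost is expressed in.
#' @param ctx An [economic_context()].
#' @return Cost(s) at base-year prices (full precision; round only for display).
#' @export
inflate_to_base_year <- function(cost, price_year, ctx) {
  stopifnot(is.numeric(cost))
  if (any(cost < 0, na.rm = TRUE)) abort("`cost` must be non-negative.")
  cost * index_at(ctx, ctx$base_year) / index_at(ctx, price_year)
}

#' Add value-added tax to a net cost
#'
#' @param net Non-negative net cost(s) in GBP.
#' @param ctx An [economic_context()]; its `vat_rate` is used.
#' @return `net * (1 + vat_rate)`.
#' @export
apply_vat <- function(net, ctx) {
  stopifnot(is.numeric(net))
  if (any(net < 0, na.rm = TRUE)) abort("`net` must be non-negative.")
  net * (1 + ctx$vat_rate)
}
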