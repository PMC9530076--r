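#' Build a unit-cost registry for genetic tests
#'
#' A costbook maps test names to unit costs with a provenance tier and
#' supports the amplicon/exon-bin fallback price: tests without an
#' authoritative entry are priced at the mean cost of authoritative entries
#' whose amplicon (or exon) count falls in the same bin, with the five bins
#' 1-10, 11-20, 21-30, 31-40 and 41+. Authoritative tiers are
#' `scotland_lab` (preferred) and `uk_lab`; bin-estimated prices are derived
#' at lookup time, never stored.
#'
#' Test names are matched exactly after case folding and whitespace
#' normalisation; there is no fuzzy matching. When a `context` is supplied,
#' entry costs are re-expressed in base-year pounds before bin means are
#' computed, so bins never mix price years.
#'
#' @param entries Data frame with columns `test_name` (character),
#'   `test_class` (one of `single_gene`, `gene_panel`, `epigenetic`,
#'   `first_line`, `other`), `amplicon_count` (positive integer or NA),
#'   `cost_gbp` (non-negative), `price_year` (integer), `tier`
#'   (`scotland_lab` or `uk_lab`).
#' @param context Optional [economic_context()]. If `NULL`, all entries must
#'   share one price year and costs are used as given.
#' @return A `costbook`: a tibble of entries with a normalised `name_key` and
#'   base-year `cost_base` column, and an `amplicon_bins` attribute.
#' @examples
#' cb <- costbook(tibble::tibble(
#'   test_name = c("MECP2 sequencing", "FBN1 panel"),
#'   test_class = c("single_gene", "gene_panel"),
#'   amplicon_count = c(4L, 66L),
#'   cost_gbp = c(420, 900),
#'   price_year = 2018L,
#'   tier = c("scotland_lab", "uk_lab")
#' ))
#' amplicon_bins(cb)
#' @export
costbook <- function(entries, context = NULL) {
  entries <- as_tibble(entries)
  required <- c("test_name", "test_class", "amplicon_count", "cost_gbp", "price_year", "tier")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols)) {
    abort(sprintf("costbook is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  valid_classes <- c("single_gene", "gene_panel", "epigenetic", "first_line", "other")
  valid_tiers <- c("scotland_lab", "uk_lab")
  if (any(!entries$test_class %in% valid_classes)) {
    abort(sprintf("test_class must be one of: %s", paste(valid_classes, collapse = ", ")))
  }
  if (any(!entries$tier %in% valid_tiers)) {
    abort("stored costbook tiers must be 'scotland_lab' or 'uk_lab'; bin-estimated prices are derived, not stored.")
  }
  if (any(entries$cost_gbp < 0, na.rm = TRUE)) abort("costs must be non-negative.")
  if (any(!is.na(entries$amplicon_count) & entries$amplicon_count < 1)) {
    abort("amplicon_count, when present, must be >= 1.")
  }
  if (any(!nzchar(trimws(entries$test_name)))) abort("test names must be non-empty.")

  entries$amplicon_count <- as.integer(entries$amplicon_count)
  entries$name_key <- normalize_test_name(entries$test_name)

  if (is.null(context)) {
    if (length(unique(entries$price_year)) > 1L) {
      warn("costbook mixes price years but no economic context was supplied; costs used as given.")
    }
    entries$cost_base <- entries$cost_gbp
  } else {
    entries$cost_base <- inflate_to_base_year(entries$cost_gbp, entries$price_year, context)
  }

  dup <- entries |>
    dplyr::count(.data$name_key, .data$tier) |>
    filter(n > 1L)
  if (nrow(dup)) {
    warn(sprintf(
      "duplicate costbook entries for %d test/tier pair(s); the first occurrence wins.",
      nrow(dup)
    ))
  }

  structure(entries, class = c("costbook", class(entries)),
            amplicon_bins = compute_amplicon_bins(entries))
}

normalize_test_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

amplicon_bin_breaks <- function() c(1, 11, 21, 31, 41, Inf)

amplicon_bin_labels <- function() c("1-10", "11-20", "21-30", "31-40", "41+")

bin_of <- function(count) {
  lab <- amplicon_bin_labels()
  lab[pmin((as.integer(count) - 1L) %/% 10L + 1L, 5L)]
}

compute_amplicon_bins <- function(entries) {
  lab <- amplicon_bin_labels()
  with_counts <- entries[!is.na(entries$amplicon_count), , drop = FALSE]
  members <- split(with_counts$cost_base, factor(bin_of(with_counts$amplicon_count), levels = lab))
  tibble(
    bin = lab,
    lower = c(1L, 11L, 21L, 31L, 41L),
    upper = c(10L, 20L, 30L, 40L, NA_integer_),
    n_members = unname(map_dbl(members, length)),
    mean_cost = unname(map_dbl(members, function(v) if (length(v)) mean(v) else NA_real_))
  )
}

#' @rdname costbook
#' @param x A `costbook`.
#' @export
amplicon_bins <- function(x) {
  stopifnot(inherits(x, "costbook"))
  attr(x, "amplicon_bins")
}

#' Read a costbook from a delimited text file
#'
#' Expects a UTF-8 CSV with a header row and columns
#' `test_name,test_class,amplicon_count,cost_gbp,price_year,tier`.
#'
#' @param path Path to the CSV file.
#' @inheritParams costbook
#' @return A `costbook`.
#' @export
read_costbook <- function(path, context = NULL) {
  if (!file.exists(path)) abort(sprintf("costbook file not found: %s", path))
  entries <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_guess()))
  required <- c("test_name", "test_class", "amplicon_count", "cost_gbp", "price_year", "tier")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols)) {
    abort(sprintf("costbook file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  entries$test_name <- as.character(entries$test_name)
  entries$cost_gbp <- as.numeric(entries$cost_gbp)
  entries$price_year <- as.integer(entries$price_year)
  costbook(entries, context = context)
}

#' Mean bin price for a given amplicon or exon count
#'
#' Returns the mean base-year cost of authoritative costbook entries in the
#' amplicon bin containing `amplicon_count` (bins 1-10, 11-20, 21-30, 31-40,
#' 41+). Errors with class `odysseycost_empty_bin` when the bin has no
#' authoritative members; the neighbouring bin is never borrowed.
#'
#' @param amplicon_count Positive integer count(s) of amplicons or exons.
#' @param costbook A [costbook()].
#' @return Mean cost(s) in GBP.
#' @export
bin_average_cost <- function(amplicon_count, costbook) {
  stopifnot(inherits(costbook, "costbook"))
  if (any(is.na(amplicon_count)) || any(amplicon_count < 1)) {
    abort("`amplicon_count` must be a positive integer.")
  }
  bins <- amplicon_bins(costbook)
  hit <- match(bin_of(amplicon_count), bins$bin)
  out <- bins$mean_cost[hit]
  if (anyNA(out)) {
    abort(sprintf(
      "no authoritative costbook entries in amplicon bin(s): %s",
      paste(unique(bins$bin[hit][is.na(out)]), collapse = ", ")
    ), class = "odysseycost_empty_bin")
  }
  out
}

#' Resolve the unit cost of each test against a costbook
#'
#' For each test, returns the authoritative entry if one exists (tier
#' `scotland_lab` preferred over `uk_lab`); otherwise, when an amplicon/exon
#' count is supplied, a `bin_estimated` price via [bin_average_cost()];
#' otherwise the test is uncostable (`NA` cost, tier `uncostable`) and the
#' caller decides whether to exclude the proband.
#'
#' @param costbook A [costbook()].
#' @param test_name Character vector of test names (matched after case and
#'   whitespace normalisation).
#' @param amplicon_count Optional integer vector (same length, NA allowed) of
#'   amplicon or exon counts used for the bin fallback.
#' @return A tibble with one row per test: `test_name`, `cost` (base-year
#'   GBP, NA if uncostable), `tier` (`scotland_lab`, `uk_lab`,
#'   `bin_estimated`, `uncostable`) and `costable`.
#' @export
lookup_unit_cost <- function(costbook, test_name, amplicon_count = NULL) {
  stopifnot(inherits(costbook, "costbook"))
  n <- length(test_name)
  if (is.null(amplicon_count)) amplicon_count <- rep(NA_integer_, n)
  stopifnot(length(amplicon_count) == n)

  key <- normalize_test_name(test_name)
  scot <- costbook[costbook$tier == "scotland_lab", , drop = FALSE]
  uk <- costbook[costbook$tier == "uk_lab", , drop = FALSE]
  cost <- scot$cost_base[match(key, scot$name_key)]
  tier <- ifelse(is.na(cost), NA_character_, "scotland_lab")
  uk_hit <- is.na(cost) & key %in% uk$name_key
  cost[uk_hit] <- uk$cost_base[match(key[uk_hit], uk$name_key)]
  tier[uk_hit] <- "uk_lab"

  need_bin <- is.na(cost) & !is.na(amplicon_count)
  if (any(need_bin)) {
    # empty-bin lookups fall through to uncostable rather than aborting the batch
    bins <- amplicon_bins(costbook)
    est <- bins$mean_cost[match(bin_of(amplicon_count[need_bin]), bins$bin)]
    cost[need_bin] <- est
    tier[need_bin][!is.na(est)] <- "bin_estimated"
  }
  tier[is.na(tier)] <- "uncostable"

  tibble(
    test_name = test_name,
    cost = cost,
    tier = tier,
    costable = !is.na(cost)
  )
}

#' @export
print.costbook <- function(x, ...) {
  bins <- amplicon_bins(x)
  cat(sprintf(
    "<costbook> %d entries (%d scotland_lab, %d uk_lab); %d/5 amplicon bins populated\n",
    nrow(x), sum(x$tier == "scotland_lab"), sum(x$tier == "uk_lab"),
    sum(bins$n_members > 0)
  ))
  NextMethod()
}
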