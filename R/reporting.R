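#' Validate a set of pipeline input files
#'
#' Schema-checks every supplied input and returns a tidy issue log.
#' Malformed delimited files (missing required columns, invalid values)
#' are a hard failure naming the problem; recoverable oddities — unknown
#' rare-disease categories (retained under `other` downstream), duplicate
#' proband/test rows — are returned as warnings in the report.
#'
#' @param costbook,histories,stages,context,wtp,ratings Optional file
#'   paths; only supplied inputs are checked.
#' @param categories Known category vocabulary (default [rd_categories()]).
#' @return A tibble with columns `input`, `severity` (`ok`/`warning`) and
#'   `message`; zero warning rows means a clean bill.
#' @export
validate_inputs <- function(costbook = NULL, histories = NULL, stages = NULL,
                            context = NULL, wtp = NULL, ratings = NULL,
                            categories = rd_categories()) {
  issues <- list()
  note <- function(input, severity, message) {
    issues[[length(issues) + 1L]] <<- tibble(
      input = input, severity = severity, message = message
    )
  }

  ctx <- if (!is.null(context)) read_economic_context(context)
  if (!is.null(costbook)) {
    cb <- withCallingHandlers(
      read_costbook(costbook, context = ctx),
      warning = function(w) {
        note("costbook", "warning", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    note("costbook", "ok", sprintf("%d entries parsed", nrow(cb)))
  }
  if (!is.null(histories)) {
    h <- suppressWarnings(read_histories(histories))
    unknown <- setdiff(unique(h$category), categories)
    if (length(unknown)) {
      note("histories", "warning", sprintf(
        "unknown categor%s retained under 'other': %s",
        if (length(unknown) > 1) "ies" else "y",
        paste(unknown, collapse = "; ")
      ))
    }
    dup <- h[duplicated(h[c("proband_id", "test_name")]) & !is.na(h$test_name), ]
    if (nrow(dup)) {
      note("histories", "warning",
           sprintf("%d duplicate proband/test row(s)", nrow(dup)))
    }
    note("histories", "ok", sprintf("%d test rows for %d probands",
                                    nrow(h), length(unique(h$proband_id))))
  }
  if (!is.null(stages)) {
    st <- read_wgs_stages(stages)
    note("stages", "ok", sprintf("%d stages parsed", length(st)))
  }
  if (!is.null(context)) {
    note("context", "ok", sprintf("base year %d", ctx$base_year))
  }
  if (!is.null(wtp)) {
    w <- read_wtp(wtp)
    note("wtp", "ok", sprintf("%d responses", nrow(w)))
  }
  if (!is.null(ratings)) {
    r <- read_ratings(ratings)
    note("ratings", "ok", sprintf("%d rating rows", nrow(r)))
  }
  if (!length(issues)) {
    return(tibble(input = character(), severity = character(), message = character()))
  }
  bind_rows(issues)
}

#' Remap unknown rare-disease categories to `other`
#'
#' @param histories Testing-history tibble.
#' @param categories Known vocabulary (default [rd_categories()]).
#' @return `histories` with unknown categories replaced by `"other"`.
#' @export
coerce_categories <- function(histories, categories = rd_categories()) {
  unknown <- !histories$category %in% categories
  if (any(unknown)) {
    warn(sprintf("%d row(s) with unknown category retained under 'other'.", sum(unknown)))
    histories$category[unknown] <- "other"
  }
  histories
}

#' Bundle module outputs for report rendering
#'
#' @param pathway_summary Tibble from [summarize_cohort()] (optional).
#' @param wgs_ledger A `wgs_ledger` from [cost_wgs_pipeline()] (optional).
#' @param wtp_summary Tibble from [summarize_wtp()] (optional).
#' @param rating_summary A `rating_summary` (optional).
#' @param exclusions Exclusion tibble from [filter_costable()] (optional).
#' @param metadata Named list recorded verbatim (seed, scenario label, ...).
#' @return A `report_bundle`.
#' @export
report_bundle <- function(pathway_summary = NULL, wgs_ledger = NULL,
                          wtp_summary = NULL, rating_summary = NULL,
                          exclusions = NULL, metadata = list()) {
  if (!is.null(wgs_ledger)) stopifnot(inherits(wgs_ledger, "wgs_ledger"))
  if (!is.null(rating_summary)) stopifnot(inherits(rating_summary, "rating_summary"))
  metadata$tool_version <- as.character(utils::packageVersion("odysseycost"))
  metadata$currency <- "GBP"
  structure(
    list(
      pathway_summary = pathway_summary, wgs_ledger = wgs_ledger,
      wtp_summary = wtp_summary, rating_summary = rating_summary,
      exclusions = exclusions, metadata = metadata
    ),
    class = "report_bundle"
  )
}

round2 <- function(x) round(x, 2)

#' Render a report bundle to disk
#'
#' Writes whichever sections the bundle holds: a pathway summary CSV, the
#' WGS ledger as CSV (`stage,assumptions,cost_per_trio_gbp,share_pct`) and
#' JSON, preference summaries, the exclusion log, run metadata, and a
#' human-readable markdown report. Machine outputs carry plain decimals
#' (currency stated in the metadata); money and shares are rounded to 2 dp
#' and headline totals to the nearest pound. Output is deterministic:
#' identical bundles render byte-identical files.
#'
#' @param bundle A [report_bundle()].
#' @param out_dir Output directory, created if needed.
#' @param formats Any of `"csv"`, `"json"`, `"md"`.
#' @return Invisibly, the paths written.
#' @export
render_reports <- function(bundle, out_dir, formats = c("csv", "json", "md")) {
  stopifnot(inherits(bundle, "report_bundle"))
  formats <- match.arg(formats, several.ok = TRUE)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    abort(sprintf("output directory not writable: %s", out_dir),
          class = "odysseycost_unwritable")
  }
  paths <- character(0)
  emit <- function(name) {
    p <- file.path(out_dir, name)
    paths <<- c(paths, p)
    p
  }

  if ("csv" %in% formats) {
    if (!is.null(bundle$pathway_summary)) {
      ps <- bundle$pathway_summary |>
        mutate(
          across(c("mean", "sd", "median", "min", "max", "iqr"), round2),
          outlier_ids = map_chr(.data$outlier_ids, paste, collapse = "; ")
        )
      readr::write_csv(ps, emit("pathway_summary.csv"))
    }
    if (!is.null(bundle$wgs_ledger)) {
      led <- tidy(bundle$wgs_ledger) |>
        mutate(
          cost_per_trio_gbp = round2(.data$cost_per_trio),
          share_pct = round2(.data$share_pct)
        ) |>
        select("stage", "assumptions", "cost_per_trio_gbp", "share_pct")
      readr::write_csv(led, emit("wgs_ledger.csv"))
    }
    if (!is.null(bundle$wtp_summary)) {
      ws <- bundle$wtp_summary |>
        mutate(non_quantified_codes = map_chr(.data$non_quantified_codes,
                                              paste, collapse = "; "))
      readr::write_csv(ws, emit("wtp_summary.csv"))
    }
    if (!is.null(bundle$rating_summary)) {
      readr::write_csv(tidy(bundle$rating_summary), emit("rating_distribution.csv"))
    }
    if (!is.null(bundle$exclusions)) {
      readr::write_csv(bundle$exclusions, emit("exclusions.csv"))
    }
  }

  if ("json" %in% formats) {
    payload <- list(metadata = bundle$metadata)
    if (!is.null(bundle$wgs_ledger)) {
      payload$wgs_ledger <- list(
        stages = tidy(bundle$wgs_ledger),
        total_per_trio = bundle$wgs_ledger$total_per_trio,
        total_gbp = round(bundle$wgs_ledger$total_per_trio)
      )
    }
    if (!is.null(bundle$pathway_summary)) {
      payload$pathway_summary <- bundle$pathway_summary |>
        mutate(outlier_ids = map_chr(.data$outlier_ids, paste, collapse = "; "))
    }
    if (!is.null(bundle$wtp_summary)) {
      payload$wtp_summary <- bundle$wtp_summary |>
        mutate(non_quantified_codes = map_chr(.data$non_quantified_codes,
                                              paste, collapse = "; "))
    }
    if (!is.null(bundle$rating_summary)) {
      payload$ratings <- glance(bundle$rating_summary)
    }
    jsonlite::write_json(payload, emit("report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  if ("md" %in% formats) {
    lines <- c("# Costing report", "")
    meta <- bundle$metadata
    lines <- c(lines, sprintf("- %s: %s", names(meta), map_chr(meta, as.character)), "")
    if (!is.null(bundle$pathway_summary)) {
      ov <- filter(bundle$pathway_summary, .data$grouping == "overall")
      if (nrow(ov)) {
        lines <- c(lines, "## Standard testing pathway", sprintf(
          "n = %d probands; mean cost £%.2f (SD £%.2f); median £%.2f; range £%.2f-£%.2f; headline total £%d.",
          ov$n[1], ov$mean[1], ov$sd[1], ov$median[1], ov$min[1], ov$max[1],
          round(ov$mean[1])
        ), "")
      }
    }
    if (!is.null(bundle$exclusions)) {
      lines <- c(lines, sprintf("Excluded probands (uncostable tests): %d.",
                                nrow(bundle$exclusions)), "")
    }
    if (!is.null(bundle$wgs_ledger)) {
      g <- glance(bundle$wgs_ledger)
      lines <- c(lines, "## Trio WGS", sprintf(
        "Total %d per trio across %d stages; largest stage '%s' at %.2f%%.",
        g$total_gbp, g$n_stages, g$largest_stage, g$largest_share_pct
      ), "")
    }
    if (is.null(bundle$wtp_summary) && is.null(bundle$rating_summary)) {
      lines <- c(lines, "## Preferences", "No preference data supplied.", "")
    } else if (!is.null(bundle$wtp_summary)) {
      ws <- bundle$wtp_summary
      lines <- c(lines, "## Preferences", sprintf(
        "%d of %d participants quantified a willingness to pay (range £%.0f-£%.0f, median £%.0f).",
        ws$n_quantified, ws$n_total, ws$min, ws$max, ws$median
      ), "")
    }
    writeLines(lines, emit("report.md"))
  }
  invisible(paths)
}
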