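#' Read willingness-to-pay interview responses
#'
#' One row per participant: `participant_id`, `role` (`adult` or `parent`),
#' `wtp_gbp` (the stated amount, empty when the participant would pay but
#' could not quantify) and `qualitative_code` (the narrative response for
#' non-quantified answers). Exactly one of `wtp_gbp` / `qualitative_code`
#' must be present per row. The packaged file
#' `odysseycost_example("wtp_interviews.csv")` holds the nine-interview
#' study data.
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @export
read_wtp <- function(path) {
  if (!file.exists(path)) abort(sprintf("WTP file not found: %s", path))
  w <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    role = readr::col_character(),
    wtp_gbp = readr::col_double(),
    qualitative_code = readr::col_character()
  ))
  validate_wtp(w)
}

validate_wtp <- function(w) {
  w <- as_tibble(w)
  required <- c("participant_id", "role", "wtp_gbp", "qualitative_code")
  missing_cols <- setdiff(required, names(w))
  if (length(missing_cols)) {
    abort(sprintf("WTP data missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  has_val <- !is.na(w$wtp_gbp)
  has_code <- !is.na(w$qualitative_code) & nzchar(w$qualitative_code)
  if (any(has_val == has_code)) {
    abort("each WTP row must carry exactly one of a value or a qualitative code.")
  }
  if (any(!w$role %in% c("adult", "parent"))) abort("role must be 'adult' or 'parent'.")
  w
}

#' Summarise willingness-to-pay responses
#'
#' Statistics are computed over quantified values only; participants who
#' would pay but could not quantify are counted and their narrative codes
#' listed. The median of an even number of values is the mean of the
#' central pair.
#'
#' @param wtp Tibble as returned by [read_wtp()].
#' @return One-row tibble: `n_total`, `n_quantified`, `n_non_quantified`,
#'   `min`, `median`, `mean`, `max` (NA when nothing is quantified, with a
#'   warning) and `non_quantified_codes` (list-column).
#' @examples
#' wtp <- read_wtp(odysseycost_example("wtp_interviews.csv"))
#' summarize_wtp(wtp)   # 7 of 9 quantified, GBP 200-5000
#' @export
summarize_wtp <- function(wtp) {
  wtp <- validate_wtp(wtp)
  if (!nrow(wtp)) abort("no WTP responses.", class = "odysseycost_empty_input")
  vals <- wtp$wtp_gbp[!is.na(wtp$wtp_gbp)]
  if (!length(vals)) {
    warn("no quantified WTP responses; statistics undefined.")
  }
  tibble(
    n_total = nrow(wtp),
    n_quantified = length(vals),
    n_non_quantified = nrow(wtp) - length(vals),
    min = if (length(vals)) min(vals) else NA_real_,
    median = if (length(vals)) median(vals) else NA_real_,
    mean = if (length(vals)) mean(vals) else NA_real_,
    max = if (length(vals)) max(vals) else NA_real_,
    non_quantified_codes = list(wtp$qualitative_code[is.na(wtp$wtp_gbp)])
  )
}

wgs_rating_attributes <- function() {
  c("chance_of_diagnosis", "waiting_time", "family_information",
    "other_conditions_information", "research_contribution")
}

#' Read attribute-importance ratings
#'
#' One row per (participant, attribute): `participant_id`, `attribute` (one
#' of the five WGS attributes: chance of diagnosis, waiting time for
#' results, information for family members, information about other
#' conditions, contribution to research) and `score` on a 1-5 importance
#' scale (5 = extremely important).
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) abort(sprintf("ratings file not found: %s", path))
  r <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    attribute = readr::col_character(),
    score = readr::col_integer()
  ))
  r
}

#' Summarise the attribute-importance rating exercise
#'
#' Tabulates scores per attribute and counts the participants who rated
#' every one of the five attributes at the maximum score. Only participants
#' with a complete five-attribute response enter that count; incomplete
#' responders are flagged. Duplicate (participant, attribute) pairs are
#' rejected.
#'
#' @param ratings Tibble as returned by [read_ratings()].
#' @return A `rating_summary`: a list with `distribution` (tibble
#'   `attribute` x `score` counts), `n_participants`, `n_complete`,
#'   `n_all_max`, and `incomplete_ids`.
#' @export
summarize_ratings <- function(ratings) {
  ratings <- as_tibble(ratings)
  required <- c("participant_id", "attribute", "score")
  missing_cols <- setdiff(required, names(ratings))
  if (length(missing_cols)) {
    abort(sprintf("ratings data missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  attrs <- wgs_rating_attributes()
  if (any(!ratings$attribute %in% attrs)) {
    abort(sprintf("unknown attribute(s): %s",
                  paste(setdiff(unique(ratings$attribute), attrs), collapse = ", ")))
  }
  if (any(!ratings$score %in% 1:5)) abort("scores must be integers in 1..5.")
  if (anyDuplicated(ratings[c("participant_id", "attribute")])) {
    abort("duplicate (participant, attribute) rating pairs.")
  }

  per_part <- ratings |>
    group_by(.data$participant_id) |>
    summarise(
      complete = length(unique(.data$attribute)) == length(attrs),
      all_max = .data$complete[1] && all(.data$score == 5L),
      .groups = "drop"
    )
  incomplete <- per_part$participant_id[!per_part$complete]
  if (length(incomplete)) {
    warn(sprintf("%d participant(s) with incomplete ratings excluded from the all-max count: %s",
                 length(incomplete), paste(incomplete, collapse = ", ")))
  }

  distribution <- ratings |>
    dplyr::count(.data$attribute, .data$score) |>
    tidyr::complete(
      attribute = attrs, score = 1:5, fill = list(n = 0L)
    )

  structure(
    list(
      distribution = distribution,
      n_participants = nrow(per_part),
      n_complete = sum(per_part$complete),
      n_all_max = sum(per_part$all_max),
      incomplete_ids = incomplete
    ),
    class = "rating_summary"
  )
}

#' @export
print.rating_summary <- function(x, ...) {
  cat(sprintf(
    "<rating_summary> %d participants (%d complete); %d rated every attribute 5/5\n",
    x$n_participants, x$n_complete, x$n_all_max
  ))
  print(tidyr::pivot_wider(x$distribution, names_from = "score",
                           values_from = "n", names_prefix = "score_"))
  invisible(x)
}

#' @export
tidy.rating_summary <- function(x, ...) x$distribution

#' @export
glance.rating_summary <- function(x, ...) {
  tibble(
    n_participants = x$n_participants,
    n_complete = x$n_complete,
    n_all_max = x$n_all_max
  )
}
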