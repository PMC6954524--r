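# Scoring of the 8-item youth sedentary-behaviour questionnaire: four
# activities, each reported separately for weekdays and weekend days
# (min/day). Children are parent-reported and include passive play;
# adolescents are self-reported and include studying. Both groups share
# television, computer and console-game items.

#' Questionnaire item sets by age group
#'
#' @param group `"children"` or `"adolescents"`.
#' @return Character vector of the four activity item names.
#' @export
sb_items <- function(group = c("children", "adolescents")) {
  group <- match.arg(group)
  c("tv", "computer", "games", if (group == "children") "play" else "study")
}

expected_respondent <- function(group) {
  # proxy report for children, self-report for adolescents
  ifelse(group == "children", "parent_proxy", "self")
}

#' Validate a long-format questionnaire response table
#'
#' The canonical layout is long: one row per participant, administration
#' and activity item, with columns `participant_id`, `group`,
#' `respondent`, `administration`, `item`, `weekday_min`, `weekend_min`.
#' Missing item responses are `NA`. Each participant x administration must
#' hold exactly the four items of its group; children must be
#' parent-proxy reported and adolescents self-reported.
#'
#' @param responses The response tibble.
#' @return `responses`, invisibly, after validation.
#' @export
validate_responses <- function(responses) {
  needed <- c(
    "participant_id", "group", "respondent", "administration",
    "item", "weekday_min", "weekend_min"
  )
  miss <- setdiff(needed, names(responses))
  if (length(miss)) {
    stop("response table lacks columns: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(responses$group %in% c("children", "adolescents"))) {
    stop("`group` must be 'children' or 'adolescents'", call. = FALSE)
  }
  if (!all(responses$administration %in% c("Q1", "Q2"))) {
    stop("`administration` must be 'Q1' or 'Q2'", call. = FALSE)
  }
  bad_resp <- responses$respondent != expected_respondent(responses$group)
  if (any(bad_resp)) {
    stop("children must be parent_proxy reported and adolescents self reported",
      call. = FALSE
    )
  }
  if (any(responses$weekday_min < 0, na.rm = TRUE) ||
    any(responses$weekend_min < 0, na.rm = TRUE)) {
    stop("reported minutes cannot be negative", call. = FALSE)
  }
  key <- interaction(responses$participant_id, responses$administration, drop = TRUE)
  for (k in levels(key)) {
    rows <- responses[key == k, , drop = FALSE]
    want <- sb_items(rows$group[1])
    if (nrow(rows) != 4L || !setequal(rows$item, want)) {
      stop(
        sprintf(
          "participant %s / %s must have exactly the items: %s",
          rows$participant_id[1], rows$administration[1],
          paste(want, collapse = ", ")
        ),
        call. = FALSE
      )
    }
  }
  invisible(responses)
}

#' Map banded duration responses to minutes per day
#'
#' Some questionnaire deployments collect duration bands (e.g.
#' "30-60 min") rather than open minutes. This maps band labels to
#' configured midpoints so banded data can enter the same scoring path.
#'
#' @param responses Long response table whose `weekday_min` and
#'   `weekend_min` columns hold band labels (character).
#' @param band_table A data frame with columns `band` and `midpoint_min`.
#' @return The response table with numeric minute columns.
#' @export
map_duration_bands <- function(responses, band_table) {
  lookup <- stats::setNames(band_table$midpoint_min, band_table$band)
  to_min <- function(x) {
    out <- unname(lookup[as.character(x)])
    if (any(is.na(out) & !is.na(x))) {
      stop("unknown duration band: ",
        paste(unique(x[is.na(out) & !is.na(x)]), collapse = ", "),
        call. = FALSE
      )
    }
    out
  }
  responses$weekday_min <- to_min(responses$weekday_min)
  responses$weekend_min <- to_min(responses$weekend_min)
  responses
}

#' Score questionnaire responses into sedentary-behaviour time
#'
#' Weekday (weekend) sedentary behaviour is the sum of the four weekday
#' (weekend) item reports in min/day; the weekly total applies the 5/2
#' weighting. Handling of missing items is complete-case and
#' segment-wise: a segment score is emitted only when all four of its
#' items are present, and the weekly total only when both segments are
#' complete (`complete = FALSE` otherwise). No imputation is performed.
#'
#' @param responses Long response table (see [validate_responses()]).
#' @param guideline_limit Guideline cut-off passed to
#'   [classify_guideline()].
#' @return A tibble with one row per participant x administration:
#'   `participant_id`, `group`, `respondent`, `administration`,
#'   `weekday_min`, `weekend_min`, `total_min`, `complete`,
#'   `meets_guideline`.
#' @export
score_responses <- function(responses, guideline_limit = 120) {
  validate_responses(responses)
  sum_or_na <- function(x) if (anyNA(x)) NA_real_ else sum(x)
  out <- dplyr::summarise(
    dplyr::group_by(responses, participant_id, group, respondent, administration),
    weekday_min = sum_or_na(weekday_min),
    weekend_min = sum_or_na(weekend_min),
    .groups = "drop"
  )
  out$complete <- !is.na(out$weekday_min) & !is.na(out$weekend_min)
  out$total_min <- ifelse(
    out$complete, weekly_total(out$weekday_min, out$weekend_min), NA_real_
  )
  out$meets_guideline <- NA
  has_total <- !is.na(out$total_min)
  out$meets_guideline[has_total] <- classify_guideline(
    out$total_min[has_total],
    limit = guideline_limit
  )
  out[, c(
    "participant_id", "group", "respondent", "administration",
    "weekday_min", "weekend_min", "total_min", "complete", "meets_guideline"
  )]
}

#' Score a single response
#'
#' @param response Long rows for one participant and administration.
#' @inheritParams score_responses
#' @return A one-row score tibble (see [score_responses()]).
#' @export
score_response <- function(response, guideline_limit = 120) {
  if (length(unique(response$participant_id)) != 1L ||
    length(unique(response$administration)) != 1L) {
    stop("`response` must hold one participant and one administration",
      call. = FALSE
    )
  }
  score_responses(response, guideline_limit)
}
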