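STIM_RESPONSE_CATEGORIES <- c("left_contraction", "right_contraction",
                              "continuous_swimming", "no_response")

#' Onset-laterality dominance over a cohort
#'
#' Fraction and rounded percentage of embryos whose right channel began
#' oscillating first. Embryos with an indeterminate onset are excluded
#' and counted.
#'
#' @param onset_table data frame with a `first_onset` column
#'   (`"L"`, `"R"`, or `"indeterminate"`), e.g. from [simulate_cohort()].
#' @return list with `fraction`, `percent` (nearest integer), `n_right`,
#'   `n_total`, `n_indeterminate`.
#' @examples
#' tab <- data.frame(first_onset = rep(c("R", "L"), c(13, 4)))
#' laterality_dominance(tab)$percent  # 76
#' @export
laterality_dominance <- function(onset_table) {
  if (!nrow(onset_table)) stop("empty onset table", call. = FALSE)
  x <- onset_table$first_onset
  n_ind <- sum(x == "indeterminate")
  x <- x[x != "indeterminate"]
  if (!length(x)) stop("no determinate onsets", call. = FALSE)
  frac <- sum(x == "R") / length(x)
  list(fraction = frac, percent = round(100 * frac),
       n_right = sum(x == "R"), n_total = length(x),
       n_indeterminate = n_ind)
}

# reporting precision: integers at or above 10%, one decimal below
report_percent <- function(p) ifelse(p >= 10, round(p), round(p, 1))

#' Photostimulation response percentages for one stimulated side
#'
#' Tabulates the behavioral response categories (left contraction, right
#' contraction, continuous swimming, no response) for the trials in which
#' the given side was stimulated. Reported percentages are rounded to
#' integers at or above 10% and to one decimal below 10%; exact fractions
#' are retained alongside.
#'
#' @param trials data frame with columns `stimulated_side` (`"L"`/`"R"`)
#'   and `response` (one of the four categories); see
#'   [make_stim_trials()].
#' @param side which stimulated side to tabulate.
#' @return list with `side`, `n`, and a data frame `percentages`
#'   (`category`, `count`, `percent_exact`, `percent_reported`).
#' @export
stim_response_percentages <- function(trials, side) {
  side <- match.arg(side, c("L", "R"))
  bad <- setdiff(unique(trials$response), STIM_RESPONSE_CATEGORIES)
  if (length(bad)) {
    stop("unknown response categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  resp <- trials$response[trials$stimulated_side == side]
  if (!length(resp)) stop("no trials for side '", side, "'", call. = FALSE)
  counts <- table(factor(resp, levels = STIM_RESPONSE_CATEGORIES))
  pct <- 100 * as.numeric(counts) / length(resp)
  list(side = side, n = length(resp),
       percentages = data.frame(
         category = STIM_RESPONSE_CATEGORIES,
         count = as.integer(counts),
         percent_exact = pct,
         percent_reported = report_percent(pct)))
}
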