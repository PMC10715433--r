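#' Clean a raw coded recall output
#'
#' Coded recall outputs occasionally contain repeated idea units or codes
#' outside the text's range (intrusions). Cleaning keeps the first
#' occurrence of each unit, drops out-of-range codes, and reports what was
#' removed; scoring operates on the cleaned sequence.
#'
#' @param recalled_raw Integer vector of original idea-unit positions in
#'   output order.
#' @param n_units Number of idea units in the text.
#'
#' @return A list with `recalled_clean` (distinct, in-range, first-occurrence
#'   order), `n_duplicates`, `n_intrusions`, and `removed`, a tibble with
#'   columns `position_in_output`, `value`, `reason`.
#' @export
#' @examples
#' clean_output(c(5, 5, 2, 31), n_units = 30)
clean_output <- function(recalled_raw, n_units) {
  recalled_raw <- as.integer(recalled_raw)
  n <- length(recalled_raw)
  reason <- rep(NA_character_, n)
  in_range <- !is.na(recalled_raw) & recalled_raw >= 1L & recalled_raw <= n_units
  reason[!in_range] <- "intrusion"
  seen <- logical(n_units)
  for (i in seq_len(n)) {
    if (!in_range[i]) next
    u <- recalled_raw[i]
    if (seen[u]) reason[i] <- "duplicate" else seen[u] <- TRUE
  }
  keep <- is.na(reason)
  removed <- tibble::tibble(
    position_in_output = which(!keep),
    value = recalled_raw[!keep],
    reason = reason[!keep]
  )
  list(
    recalled_clean = recalled_raw[keep],
    n_duplicates = sum(reason == "duplicate", na.rm = TRUE),
    n_intrusions = sum(reason == "intrusion", na.rm = TRUE),
    removed = removed
  )
}

#' Proportion of idea units recalled
#'
#' The quantity measure: number of distinct correctly recalled idea units
#' divided by the number of idea units in the text (30 in the standard
#' materials).
#'
#' @param recalled_clean Distinct integer vector of recalled unit positions.
#' @param n_units Number of idea units in the text (default 30).
#'
#' @return A proportion in `[0, 1]`.
#' @export
proportion_recalled <- function(recalled_clean, n_units = 30L) {
  if (length(n_units) != 1L || is.na(n_units) || n_units <= 0) {
    stop_input("`n_units` must be a positive integer.")
  }
  check_distinct(recalled_clean)
  length(recalled_clean) / as.numeric(n_units)
}

check_distinct <- function(x) {
  if (anyDuplicated(x)) {
    stop_input(sprintf(
      "Recalled units must be distinct; unit %s appears more than once (run clean_output() first).",
      x[duplicated(x)][1]
    ))
  }
  if (anyNA(x)) stop_input("Recalled units must not be missing.")
  invisible(x)
}

#' Relative serial positions of recalled units
#'
#' For each recalled idea unit, its rank among the recalled units when they
#' are sorted by original text position (rank 1 = earliest in the text).
#' E.g. a unit preceded in the text by six other recalled units gets
#' relative serial position 7.
#'
#' @param recalled_clean Distinct integer vector of original unit positions,
#'   in output order.
#'
#' @return An integer vector, a permutation of `1..length(recalled_clean)`.
#' @export
#' @examples
#' relative_positions(c(30, 10, 20))  # 3 1 2
relative_positions <- function(recalled_clean) {
  check_distinct(recalled_clean)
  as.integer(rank(recalled_clean))
}

#' Recall-order score of a recall output
#'
#' Measures how consistently a free-recall output follows the order of the
#' original text, independently of how much was recalled. For each recalled
#' unit the absolute difference is taken between its actual serial position
#' (position within the output) and its relative serial position (rank among
#' the recalled units by text order); these displacements are averaged and
#' the average divided by the number of recalled units. A score of 0 means
#' the units were recalled exactly in text order; higher scores mean less
#' text-consistent order. The attainable maximum for n recalled units is
#' `floor(n^2/2)/n^2 <= 0.5` (see [max_order_score()]), reached e.g. by a
#' fully reversed output.
#'
#' @param recalled_clean Distinct integer vector of original unit positions,
#'   in output order.
#'
#' @return A list of class `order_score_result` with `score`, `n_recalled`,
#'   `relative_positions`, `displacements`. An empty input yields
#'   `score = NA` with `n_recalled = 0` (no order to measure).
#' @export
#' @examples
#' order_score(c(30, 10, 20))$score  # 4/9, printed 0.44
#' order_score(c(10, 30, 20))$score  # 2/9, printed 0.22
order_score <- function(recalled_clean) {
  check_distinct(recalled_clean)
  n <- length(recalled_clean)
  if (n == 0L) {
    res <- list(score = NA_real_, n_recalled = 0L,
                relative_positions = integer(0), displacements = integer(0))
    class(res) <- "order_score_result"
    return(res)
  }
  rel <- as.integer(rank(recalled_clean))
  actual <- seq_len(n)
  disp <- abs(actual - rel)
  res <- list(
    score = mean(disp) / n,
    n_recalled = n,
    relative_positions = rel,
    displacements = disp
  )
  class(res) <- "order_score_result"
  res
}

#' @export
print.order_score_result <- function(x, ...) {
  cat(sprintf("Recall-order score: %s (n recalled = %d)\n",
              ifelse(is.na(x$score), "NA", format(round(x$score, 3))),
              x$n_recalled))
  invisible(x)
}

#' Maximum attainable recall-order score
#'
#' Closed form for the maximum of [order_score()] over all permutations of
#' `n` recalled units: `floor(n^2/2) / n^2`. The maximum tends to 0.5 from
#' below and is attained by, among others, the fully reversed output; no
#' output of any length can score 1.
#'
#' @param n Number of recalled units (>= 1).
#'
#' @return The maximum score, a value in `[0, 0.5]`.
#' @export
#' @examples
#' max_order_score(3)  # 4/9
max_order_score <- function(n) {
  if (any(is.na(n)) || any(n < 1)) stop_input("`n` must be >= 1.")
  floor(n^2 / 2) / n^2
}

# Order score of an SR practice output computed per contiguous section and
# averaged across sections with >= 1 recalled unit (NA if none).
sr_sectionwise_order_score <- function(recalled_clean, n_units, n_sections) {
  per <- n_units %/% n_sections
  section <- ceiling(recalled_clean / per)
  scores <- vapply(
    split(recalled_clean, section),
    function(u) order_score(u)$score,
    numeric(1)
  )
  if (all(is.na(scores))) NA_real_ else mean(scores, na.rm = TRUE)
}

#' Score a collection of recall outputs
#'
#' Turns long-format coded recall outputs into the scored trial table the
#' statistical pipeline consumes: one row per (participant, condition,
#' phase) with the number of units recalled, the proportion recalled, and
#' the recall-order score. Raw outputs are cleaned ([clean_output()]) with
#' a warning summarising any duplicates or intrusions.
#'
#' By default the order score is computed for whole-text outputs only
#' (whole-text-recall practice and all criterion outputs); section-recall
#' practice outputs get a missing order score because each section was
#' recalled separately. Set `sr_practice_order = "per_section"` to instead
#' score each section's output and average.
#'
#' Participants with a (participant, condition, phase) cell present in the
#' input but an empty recall get proportion 0 and a missing order score.
#'
#' @param outputs Long-format tibble of coded recall outputs with columns
#'   `participant_id`, `text_id`, `condition`, `phase`,
#'   `position_in_output`, `original_unit` (all serial positions 1-based).
#' @param texts Tibble of texts (see [text_material()], [default_texts()]).
#' @param roster Optional participant roster with `participant_id` and
#'   `group` (and any extra columns to carry along, e.g. `version_id`);
#'   if omitted, `group` is `NA`.
#' @param sr_practice_order `"none"` (default) or `"per_section"`.
#'
#' @return A tibble with columns `participant_id`, `group`, `condition`,
#'   `phase`, `n_recalled`, `proportion`, `order_score`.
#' @export
score_dataset <- function(outputs, texts = default_texts(), roster = NULL,
                          sr_practice_order = c("none", "per_section")) {
  sr_practice_order <- match.arg(sr_practice_order)
  req <- c("participant_id", "text_id", "condition", "phase",
           "position_in_output", "original_unit")
  missing_cols <- setdiff(req, names(outputs))
  if (length(missing_cols) > 0L) {
    stop_input(paste0("`outputs` is missing columns: ",
                      paste(missing_cols, collapse = ", "), "."))
  }
  unknown <- setdiff(unique(outputs$text_id), texts$text_id)
  if (length(unknown) > 0L) {
    stop_input(paste0("Unknown text_id in outputs: ",
                      paste(unknown, collapse = ", "), "."))
  }

  outputs <- dplyr::arrange(outputs, .data$participant_id, .data$condition,
                            .data$phase, .data$position_in_output)
  keys <- dplyr::distinct(outputs, .data$participant_id, .data$condition, .data$phase,
                          .data$text_id)
  grouped <- dplyr::group_by(outputs, .data$participant_id, .data$condition,
                             .data$phase, .data$text_id)
  split_out <- dplyr::group_split(grouped)
  key_tbl <- dplyr::group_keys(grouped)

  n_dup <- 0L
  n_intr <- 0L
  rows <- vector("list", nrow(key_tbl))
  for (i in seq_along(split_out)) {
    g <- split_out[[i]]
    txt <- texts[texts$text_id == g$text_id[1], ]
    raw <- g$original_unit
    # A single row with position_in_output 0 and NA unit encodes an empty output.
    raw <- raw[!is.na(raw)]
    cl <- clean_output(raw, txt$n_units)
    n_dup <- n_dup + cl$n_duplicates
    n_intr <- n_intr + cl$n_intrusions
    x <- cl$recalled_clean
    is_sr_practice <- key_tbl$condition[i] == "SR" && key_tbl$phase[i] == "practice"
    osc <- if (is_sr_practice) {
      if (sr_practice_order == "per_section" && length(x) > 0) {
        sr_sectionwise_order_score(x, txt$n_units, txt$n_sections)
      } else NA_real_
    } else {
      order_score(x)$score
    }
    rows[[i]] <- tibble::tibble(
      participant_id = key_tbl$participant_id[i],
      condition = key_tbl$condition[i],
      phase = key_tbl$phase[i],
      n_recalled = length(x),
      proportion = proportion_recalled(x, txt$n_units),
      order_score = osc
    )
  }
  if (n_dup + n_intr > 0L) {
    warn(sprintf("Cleaned recall outputs: removed %d duplicate(s) and %d intrusion(s).",
                 n_dup, n_intr))
  }
  scored <- dplyr::bind_rows(rows)
  if (!is.null(roster)) {
    scored <- dplyr::left_join(scored,
                               dplyr::select(roster, dplyr::any_of(c("participant_id", "group"))),
                               by = "participant_id")
  } else {
    scored$group <- NA_character_
  }
  scored <- dplyr::select(scored, "participant_id", "group", "condition", "phase",
                          "n_recalled", "proportion", "order_score")
  scored$condition <- factor(scored$condition, levels = condition_levels())
  scored$phase <- factor(scored$phase, levels = phase_levels())
  dplyr::arrange(scored, .data$participant_id, .data$phase, .data$condition)
}
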