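#' Define a study text
#'
#' A text is an ordered list of idea units, implicitly numbered
#' `1..n_units` in text order (the "original serial position"). Texts are
#' read section by section in the section-recall condition, so `n_units`
#' must divide evenly into `n_sections` contiguous blocks.
#'
#' @param text_id Unique identifier for the text.
#' @param title Human-readable title.
#' @param n_units Number of coded idea units (default 30).
#' @param n_sections Number of contiguous sections (default 5).
#'
#' @return A one-row tibble with columns `text_id`, `title`, `n_units`,
#'   `n_sections`.
#' @export
#' @examples
#' text_material("sun", "The Sun")
text_material <- function(text_id, title = text_id, n_units = 30L, n_sections = 5L) {
  n_units <- as.integer(n_units)
  n_sections <- as.integer(n_sections)
  if (length(text_id) != 1L || is.na(text_id) || !nzchar(as.character(text_id))) {
    stop_input("`text_id` must be a single non-empty identifier.")
  }
  if (is.na(n_units) || n_units < 1L) stop_input("`n_units` must be a positive integer.")
  if (is.na(n_sections) || n_sections < 1L) stop_input("`n_sections` must be a positive integer.")
  if (n_units %% n_sections != 0L) {
    stop_input(sprintf(
      "`n_units` (%d) must be divisible by `n_sections` (%d).", n_units, n_sections
    ))
  }
  tibble::tibble(
    text_id = as.character(text_id), title = as.character(title),
    n_units = n_units, n_sections = n_sections
  )
}

#' Default set of three 30-unit texts
#'
#' Three texts of 30 idea units in five sections each, mirroring the usual
#' design of text-learning retrieval-practice experiments.
#'
#' @return A tibble of three texts (see [text_material()]).
#' @export
default_texts <- function() {
  dplyr::bind_rows(
    text_material("text1", "Text 1"),
    text_material("text2", "Text 2"),
    text_material("text3", "Text 3")
  )
}

#' Sum the 18 ASRS item responses
#'
#' The Adult ADHD Self-Report Scale has 18 items; screening uses the plain
#' sum across all items. The per-item scale is configurable (default 0-4,
#' giving a maximum sum of 72).
#'
#' @param items Integer vector of exactly 18 item responses.
#' @param item_range Length-2 integer vector giving the allowed per-item
#'   range (inclusive).
#'
#' @return The integer sum score.
#' @export
#' @examples
#' asrs_sum(rep(3L, 18))  # 54
asrs_sum <- function(items, item_range = c(0L, 4L)) {
  if (length(items) != 18L) {
    stop_input(sprintf("ASRS requires exactly 18 items; got %d.", length(items)))
  }
  items <- as.numeric(items)
  bad <- which(is.na(items) | items != round(items) |
                 items < item_range[1] | items > item_range[2])
  if (length(bad) > 0L) {
    stop_input(sprintf(
      "ASRS item %d is missing, non-integer, or outside [%s, %s].",
      bad[1], item_range[1], item_range[2]
    ))
  }
  as.integer(sum(items))
}

#' Screen an ASRS sum score against the clinical cutoff
#'
#' A sum score at or above the cutoff (51 in the Hebrew adaptation of the
#' instrument) is treated as an indication of ADHD.
#'
#' @param sum_score Non-negative integer sum score.
#' @param cutoff Screening cutoff (default 51).
#'
#' @return `TRUE` if `sum_score >= cutoff`.
#' @export
asrs_screen <- function(sum_score, cutoff = 51L) {
  if (any(is.na(sum_score)) || any(sum_score < 0)) {
    stop_input("`sum_score` must be non-negative.")
  }
  sum_score >= cutoff
}

# All permutations of a vector, in lexicographic order of positions.
permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Generate the fully counterbalanced design
#'
#' Crosses every order of the conditions with every assignment of texts to
#' conditions. With the standard three conditions and three texts this
#' yields the 36 versions used to counterbalance a within-participant
#' retrieval-practice experiment: each condition occupies each serial
#' position in exactly 12 versions and each text serves each condition in
#' exactly 12 versions.
#'
#' Versions are numbered lexicographically by (condition order, text
#' assignment), with conditions in the canonical order
#' restudy < WTR < SR and texts in the order given.
#'
#' @param conditions Character vector of condition labels (default the
#'   standard three).
#' @param texts Character vector of text ids, same length as `conditions`.
#'
#' @return A tibble with one row per version: `version_id`, columns
#'   `position_1..k` (condition presented at each serial position), and
#'   columns `text_for_<condition>` (text assigned to each condition).
#' @export
#' @examples
#' nrow(generate_design())  # 36
generate_design <- function(conditions = condition_levels(),
                            texts = default_texts()$text_id) {
  conditions <- as.character(conditions)
  texts <- as.character(texts)
  k <- length(conditions)
  if (length(texts) != k) stop_input("`texts` and `conditions` must have equal length.")
  if (anyDuplicated(conditions) || anyDuplicated(texts)) {
    stop_input("`conditions` and `texts` must each be distinct.")
  }
  orders <- permutations_of(conditions)
  assigns <- permutations_of(texts)  # assigns[[j]][i] = text for conditions[i]
  rows <- vector("list", length(orders) * length(assigns))
  v <- 0L
  for (ord in orders) {
    for (asg in assigns) {
      v <- v + 1L
      row <- c(
        list(version_id = v),
        setNames(as.list(ord), paste0("position_", seq_len(k))),
        setNames(as.list(asg), paste0("text_for_", conditions))
      )
      rows[[v]] <- tibble::as_tibble(row)
    }
  }
  dplyr::bind_rows(rows)
}

#' Assign counterbalancing versions to participants
#'
#' Each design version is used the same number of times within each group,
#' so group and version are fully crossed. The number of participants per
#' group must therefore be a multiple of the number of versions (36 in the
#' standard design, one participant per version per group).
#'
#' @param participants_per_group Participants in each group (default 36).
#' @param groups Character vector of group labels.
#' @param n_versions Number of design versions (default 36).
#'
#' @return A tibble with `participant_id`, `group`, `version_id`.
#' @export
assign_versions <- function(participants_per_group = 36L,
                            groups = group_levels(),
                            n_versions = 36L) {
  participants_per_group <- as.integer(participants_per_group)
  if (is.na(participants_per_group) || participants_per_group < 1L) {
    stop_input("`participants_per_group` must be a positive integer.")
  }
  if (participants_per_group %% n_versions != 0L) {
    stop_input(sprintf(
      "`participants_per_group` (%d) must be a multiple of the %d versions.",
      participants_per_group, n_versions
    ))
  }
  n_total <- participants_per_group * length(groups)
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n_total)),
    group = factor(rep(groups, each = participants_per_group), levels = groups),
    version_id = rep(rep(seq_len(n_versions),
                         times = participants_per_group / n_versions),
                     times = length(groups))
  )
}

#' Planned-sample constant from the power analysis
#'
#' The study was planned for at least 34 participants per group to detect a
#' medium effect (d = 0.50) with power 0.80 in two-tailed dependent-means
#' comparisons. Recorded as planning metadata, not recomputed.
#'
#' @return A list with `n_per_group_min`, `d`, `power`.
#' @export
planned_power <- function() {
  list(n_per_group_min = 34L, d = 0.50, power = 0.80)
}
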