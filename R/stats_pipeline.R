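# Filter a scored trial table to one phase / set of within levels, apply
# listwise deletion (participants missing any within level are dropped from
# this analysis only), and return a complete long table.
prepare_analysis_table <- function(table, dv, within_levels, phase) {
  if (!dv %in% names(table)) stop_input(sprintf("No `%s` column in the trial table.", dv))
  d <- table[as.character(table$phase) == phase &
               as.character(table$condition) %in% within_levels, ]
  d$value <- d[[dv]]
  dup <- d |>
    dplyr::count(.data$participant_id, .data$condition) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop_analysis(paste0(
      "More than one row per (participant, condition, phase) for: ",
      paste(unique(dup$participant_id), collapse = ", "), "."
    ))
  }
  ok <- d |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::count(.data$participant_id) |>
    dplyr::filter(.data$n == length(within_levels))
  dropped <- setdiff(unique(d$participant_id), ok$participant_id)
  if (length(dropped) > 0L) {
    inform(sprintf("Listwise deletion: dropping %d participant(s) missing a within level (%s).",
                   length(dropped), paste(utils::head(dropped, 5), collapse = ", ")))
  }
  d <- d[d$participant_id %in% ok$participant_id & !is.na(d$value), ]
  d$condition <- factor(as.character(d$condition), levels = within_levels)
  lv <- unique(as.character(d$group))
  d$group <- factor(as.character(d$group),
                    levels = c(intersect(group_levels(), lv), setdiff(lv, group_levels())))
  d$participant_id <- factor(d$participant_id)
  d
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# repeated measures.
gg_epsilon <- function(d, within_levels) {
  wide <- tidyr::pivot_wider(
    dplyr::select(d, "participant_id", "group", "condition", "value"),
    names_from = "condition", values_from = "value"
  )
  mats <- lapply(split(wide[within_levels], wide$group), function(m) {
    m <- as.matrix(m)
    if (nrow(m) < 2L) return(NULL)
    stats::cov(m) * (nrow(m) - 1L)
  })
  mats <- Filter(Negate(is.null), mats)
  S <- Reduce(`+`, mats) / (nrow(wide) - length(mats))
  w <- length(within_levels)
  C <- stats::contr.helmert(w)
  C <- apply(C, 2, function(x) x / sqrt(sum(x^2)))
  M <- t(C) %*% S %*% C
  sum(diag(M))^2 / ((w - 1) * sum(M^2))
}

#' Split-plot (mixed-design) ANOVA
#'
#' Fits the classical two-stratum split-plot decomposition for a design with
#' one between-participants factor (`group`) and one within-participants
#' factor (`condition`): the group effect is tested against the
#' participant-within-group stratum and the condition and condition-by-group
#' effects against the condition-by-participant stratum. Participants
#' missing any analysed within level (or with a missing dependent value) are
#' dropped from this analysis by listwise deletion, so the error degrees of
#' freedom reflect the retained sample: with g groups, w within levels and N
#' retained participants, the between error has N - g df and the within
#' error (N - g)(w - 1) df.
#'
#' @param table Scored trial table from [score_dataset()] (columns
#'   `participant_id`, `group`, `condition`, `phase`, plus the dependent
#'   variable).
#' @param dv Dependent variable: `"proportion"` or `"order_score"`.
#' @param within_levels Conditions to include as the repeated measure.
#' @param phase `"practice"` or `"criterion"`.
#' @param sphericity `"none"` (uncorrected degrees of freedom, the default)
#'   or `"GG"` for Greenhouse-Geisser-corrected p-values on the within
#'   effects.
#'
#' @return A tibble of class `recall_anova` with one row per effect
#'   (`group`, `condition`, `group:condition`): `SS`, `df`, `SS_error`,
#'   `df_error`, `F`, `p`, `partial_eta_sq`. Attributes: `n_participants`,
#'   `dv`, `phase`, and `gg_epsilon` when the correction is requested.
#' @export
mixed_anova <- function(table, dv = c("proportion", "order_score"),
                        within_levels = condition_levels(),
                        phase = "criterion",
                        sphericity = c("none", "GG")) {
  dv <- match.arg(dv)
  sphericity <- match.arg(sphericity)
  if (length(within_levels) < 2L) stop_input("Need at least 2 within levels.")
  d <- prepare_analysis_table(table, dv, within_levels, phase)

  n_by_group <- table(dplyr::distinct(d, .data$participant_id, .data$group)$group)
  if (length(n_by_group) < 2L || any(n_by_group < 2L)) {
    stop_analysis("Each group needs at least 2 complete participants after listwise deletion.")
  }

  fit <- aov(value ~ group * condition + Error(participant_id), data = d)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: participant_id"]][[1]])
  within <- as.data.frame(s[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(between))
  rn_w <- trimws(rownames(within))

  pick <- function(tab, rn, term) {
    i <- match(term, rn)
    c(df = tab$Df[i], SS = tab$`Sum Sq`[i])
  }
  b_err <- pick(between, rn_b, "Residuals")
  w_err <- pick(within, rn_w, "Residuals")
  effects <- list(
    group = c(pick(between, rn_b, "group"), err = b_err),
    condition = c(pick(within, rn_w, "condition"), err = w_err),
    `group:condition` = c(pick(within, rn_w, "group:condition"), err = w_err)
  )

  eps <- if (sphericity == "GG") gg_epsilon(d, within_levels) else NA_real_
  out <- dplyr::bind_rows(lapply(names(effects), function(nm) {
    e <- effects[[nm]]
    Fval <- (e[["SS"]] / e[["df"]]) / (e[["err.SS"]] / e[["err.df"]])
    df1 <- e[["df"]]; df2 <- e[["err.df"]]
    if (sphericity == "GG" && nm != "group") {
      df1 <- df1 * eps
      df2 <- df2 * eps
    }
    tibble::tibble(
      effect = nm,
      SS = e[["SS"]], df = e[["df"]],
      SS_error = e[["err.SS"]], df_error = e[["err.df"]],
      `F` = Fval,
      p = stats::pf(Fval, df1, df2, lower.tail = FALSE),
      partial_eta_sq = e[["SS"]] / (e[["SS"]] + e[["err.SS"]])
    )
  }))
  attr(out, "n_participants") <- length(unique(d$participant_id))
  attr(out, "dv") <- dv
  attr(out, "phase") <- phase
  attr(out, "gg_epsilon") <- eps
  class(out) <- c("recall_anova", class(out))
  out
}

#' Bonferroni-adjusted pairwise comparisons of within levels
#'
#' Paired t-tests between every pair of within levels, pooled across groups,
#' with Bonferroni adjustment (`p_adj = min(1, m * p)` for m pairs; m = 3
#' for three levels) and a Cohen's d per contrast. The default d divides the
#' mean difference by the pooled SD of the two condition distributions
#' (`sqrt((sd1^2 + sd2^2)/2)`, often called d_av); `d_method = "z"` divides
#' by the SD of the paired differences instead.
#'
#' @inheritParams mixed_anova
#' @param d_method `"av"` (default) or `"z"`.
#'
#' @return A tibble with one row per pair: `level_1`, `level_2`, `n_pairs`,
#'   `mean_1`, `mean_2`, `mean_diff`, `t`, `df`, `p_raw`, `p_adj`, `d`.
#' @export
bonferroni_pairwise <- function(table, dv = c("proportion", "order_score"),
                                within_levels = condition_levels(),
                                phase = "criterion",
                                d_method = c("av", "z")) {
  dv <- match.arg(dv)
  d_method <- match.arg(d_method)
  if (length(within_levels) < 2L) stop_input("Need at least 2 within levels.")
  d <- table[as.character(table$phase) == phase &
               as.character(table$condition) %in% within_levels, ]
  d$value <- d[[dv]]
  wide <- tidyr::pivot_wider(
    dplyr::select(d, "participant_id", "condition", "value"),
    names_from = "condition", values_from = "value"
  )
  pairs <- utils::combn(within_levels, 2L, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    x <- wide[[pr[1]]]
    y <- wide[[pr[2]]]
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 2L) {
      stop_analysis(sprintf("Fewer than 2 complete pairs for %s vs %s.", pr[1], pr[2]))
    }
    diffs <- x - y
    if (sd(diffs) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(x) - 1L),
                 p.value = if (mean(diffs) == 0) 1 else 0)
    } else {
      tt <- t.test(x, y, paired = TRUE)
    }
    denom <- switch(d_method,
                    av = sqrt((var(x) + var(y)) / 2),
                    z = sd(diffs))
    tibble::tibble(
      level_1 = pr[1], level_2 = pr[2], n_pairs = length(x),
      mean_1 = mean(x), mean_2 = mean(y), mean_diff = mean(diffs),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value, p_adj = min(1, m * tt$p.value),
      d = if (denom == 0) 0 else mean(diffs) / denom
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "m_comparisons") <- m
  attr(out, "d_method") <- d_method
  out
}

#' Independent-groups Student t-test with Cohen's d
#'
#' Two-sample t-test with pooled variance (df = n1 + n2 - 2). The effect
#' size is derived from the statistic as `d = t * sqrt(1/n1 + 1/n2)`, the
#' standard conversion for independent groups.
#'
#' @param values Numeric vector (missing values dropped with their group
#'   labels).
#' @param group Factor or character vector with exactly two levels.
#'
#' @return A list with `t`, `df`, `p`, `d`, and per-group `n`, `mean`, `sd`.
#' @export
independent_t <- function(values, group) {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- factor(as.character(group[keep]),
                  levels = intersect(c(group_levels(), unique(as.character(group[keep]))),
                                     unique(as.character(group[keep]))))
  lv <- levels(group)
  if (length(lv) != 2L) stop_analysis("`group` must have exactly two levels.")
  n1 <- sum(group == lv[1]); n2 <- sum(group == lv[2])
  if (n1 < 2L || n2 < 2L) stop_analysis("Each group needs at least 2 observations.")
  tt <- t.test(values[group == lv[1]], values[group == lv[2]], var.equal = TRUE)
  t_val <- unname(tt$statistic)
  list(
    t = t_val, df = unname(tt$parameter), p = tt$p.value,
    d = cohens_d_from_t(t_val, n1, n2),
    groups = lv,
    n = c(n1, n2),
    mean = c(mean(values[group == lv[1]]), mean(values[group == lv[2]])),
    sd = c(sd(values[group == lv[1]]), sd(values[group == lv[2]]))
  )
}

#' Convert an independent-groups t statistic to Cohen's d
#'
#' `d = t * sqrt(1/n1 + 1/n2)`; e.g. t(70) = 9.29 with 36 per group gives
#' d = 2.19.
#'
#' @param t t statistic.
#' @param n1,n2 Group sizes.
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, n1, n2) {
  t * sqrt(1 / n1 + 1 / n2)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation over pairwise-complete observations, with the
#' usual t-transform p-value. Used both for proportion-vs-order-score
#' relations and as an inter-coder reliability utility.
#'
#' @param x,y Numeric vectors of equal length.
#'
#' @return A list with `r`, `p`, `n` (pairs used).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_input("`x` and `y` must have equal length.")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_analysis("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) stop_analysis("Zero variance in `x` or `y`.")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# Per-cell descriptive means and SDs for both dependent variables.
cell_means <- function(scored) {
  scored |>
    dplyr::group_by(.data$group, .data$condition, .data$phase) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_proportion = mean(.data$proportion, na.rm = TRUE),
      sd_proportion = sd(.data$proportion, na.rm = TRUE),
      mean_order_score = mean(.data$order_score, na.rm = TRUE),
      sd_order_score = sd(.data$order_score, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Run the full analysis battery on a scored trial table
#'
#' Reproduces the standard inferential sequence for a two-group, three-
#' condition retrieval-practice study: (1) 2 x 2 mixed ANOVA on the
#' proportion recalled at practice (WTR, SR); (2) 3 x 2 mixed ANOVA on the
#' criterion proportion with Bonferroni pairwise comparisons; (3) Pearson
#' correlations between proportion and order score per condition (WTR
#' practice and criterion, restudy and SR criterion); (4) independent-groups
#' t-test on the WTR practice order score; (5) 3 x 2 mixed ANOVA on the
#' criterion order score with Bonferroni pairwise comparisons. Cell means
#' and SDs are included for reference.
#'
#' @param scored Scored trial table from [score_dataset()].
#' @param d_method Cohen's d convention for pairwise contrasts (see
#'   [bonferroni_pairwise()]).
#' @param sphericity Sphericity handling for the 3-level ANOVAs (see
#'   [mixed_anova()]).
#'
#' @return A list of class `recall_report` with elements
#'   `practice_proportion_anova`, `criterion_proportion_anova`,
#'   `criterion_proportion_pairwise`, `correlations`,
#'   `practice_order_ttest`, `criterion_order_anova`,
#'   `criterion_order_pairwise`, `cell_means`.
#' @export
analyze_study <- function(scored, d_method = c("av", "z"),
                          sphericity = c("none", "GG")) {
  d_method <- match.arg(d_method)
  sphericity <- match.arg(sphericity)

  cors <- list(
    WTR_practice = c("WTR", "practice"),
    WTR_criterion = c("WTR", "criterion"),
    restudy_criterion = c("restudy", "criterion"),
    SR_criterion = c("SR", "criterion")
  )
  correlations <- dplyr::bind_rows(lapply(names(cors), function(nm) {
    sel <- scored[as.character(scored$condition) == cors[[nm]][1] &
                    as.character(scored$phase) == cors[[nm]][2], ]
    res <- pearson_r(sel$proportion, sel$order_score)
    tibble::tibble(analysis = nm, condition = cors[[nm]][1], phase = cors[[nm]][2],
                   r = res$r, p = res$p, n = res$n)
  }))

  wtr_prac <- scored[as.character(scored$condition) == "WTR" &
                       as.character(scored$phase) == "practice", ]

  report <- list(
    practice_proportion_anova = mixed_anova(
      scored, dv = "proportion", within_levels = c("WTR", "SR"), phase = "practice",
      sphericity = "none"
    ),
    criterion_proportion_anova = mixed_anova(
      scored, dv = "proportion", within_levels = condition_levels(),
      phase = "criterion", sphericity = sphericity
    ),
    criterion_proportion_pairwise = bonferroni_pairwise(
      scored, dv = "proportion", within_levels = condition_levels(),
      phase = "criterion", d_method = d_method
    ),
    correlations = correlations,
    practice_order_ttest = independent_t(wtr_prac$order_score, wtr_prac$group),
    criterion_order_anova = mixed_anova(
      scored, dv = "order_score", within_levels = condition_levels(),
      phase = "criterion", sphericity = sphericity
    ),
    criterion_order_pairwise = bonferroni_pairwise(
      scored, dv = "order_score", within_levels = condition_levels(),
      phase = "criterion", d_method = d_method
    ),
    cell_means = cell_means(scored)
  )
  class(report) <- "recall_report"
  report
}

format_p <- function(p) ifelse(p < 0.001, "< 0.001", sprintf("= %.3f", p))

#' @export
print.recall_anova <- function(x, ...) {
  cat(sprintf("Mixed-design ANOVA on %s (%s phase), N = %d\n",
              attr(x, "dv"), attr(x, "phase"), attr(x, "n_participants")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-16s F(%g, %g) = %.2f, p %s, partial eta^2 = %.3f\n",
                x$effect[i], x$df[i], x$df_error[i], x$`F`[i],
                format_p(x$p[i]), x$partial_eta_sq[i]))
  }
  invisible(x)
}

#' @export
print.recall_report <- function(x, ...) {
  cat("== Retrieval-practice analysis report ==\n\n")
  cat("-- Practice proportion recalled --\n"); print(x$practice_proportion_anova)
  cat("\n-- Criterion proportion recalled --\n"); print(x$criterion_proportion_anova)
  pw <- x$criterion_proportion_pairwise
  for (i in seq_len(nrow(pw))) {
    cat(sprintf("  %s vs %s: diff = %.3f, p_adj %s, d = %.2f\n",
                pw$level_1[i], pw$level_2[i], pw$mean_diff[i],
                format_p(pw$p_adj[i]), pw$d[i]))
  }
  cat("\n-- Proportion vs order-score correlations --\n")
  co <- x$correlations
  for (i in seq_len(nrow(co))) {
    cat(sprintf("  %s %s: r = %.2f, p %s (n = %d)\n",
                co$condition[i], co$phase[i], co$r[i], format_p(co$p[i]), co$n[i]))
  }
  tt <- x$practice_order_ttest
  cat(sprintf("\n-- WTR practice order score by group --\n  t(%g) = %.2f, p %s, d = %.2f\n",
              tt$df, tt$t, format_p(tt$p), tt$d))
  cat("\n-- Criterion order score --\n"); print(x$criterion_order_anova)
  pw <- x$criterion_order_pairwise
  for (i in seq_len(nrow(pw))) {
    cat(sprintf("  %s vs %s: diff = %.3f, p_adj %s, d = %.2f\n",
                pw$level_1[i], pw$level_2[i], pw$mean_diff[i],
                format_p(pw$p_adj[i]), pw$d[i]))
  }
  invisible(x)
}
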