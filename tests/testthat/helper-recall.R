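# Shared fixtures and independent oracles, built in code.

# Brute-force oracle: maximum order score over all permutations of 1..n.
brute_force_max_order_score <- function(n) {
  perms <- recallorder:::permutations_of(seq_len(n))
  max(vapply(perms, function(p) order_score(p)$score, numeric(1)))
}

# A balanced two-group, two-condition trial table with a participant random
# intercept; all cell means equal (null) unless shifts are supplied.
null_trial_table <- function(n_per_group = 10L,
                             conditions = c("WTR", "SR"),
                             phase = "practice",
                             cond_shift = rep(0, length(conditions)),
                             group_shift = 0,
                             sd_participant = 0.5, sd_noise = 1) {
  n <- 2L * n_per_group
  ids <- sprintf("S%03d", seq_len(n))
  grp <- rep(c("TD", "ADHD"), each = n_per_group)
  u <- rnorm(n, 0, sd_participant)
  rows <- lapply(seq_along(conditions), function(j) {
    tibble::tibble(
      participant_id = ids, group = grp, condition = conditions[j], phase = phase,
      n_recalled = NA_integer_,
      proportion = u + cond_shift[j] + ifelse(grp == "ADHD", group_shift, 0) +
        rnorm(n, 0, sd_noise),
      order_score = NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

# Textbook split-plot sums of squares for a balanced design (one observation
# per participant x condition), computed directly from means -- an
# independent route to mixed_anova's aov-based decomposition.
textbook_split_plot <- function(d) {
  d$group <- as.character(d$group)
  d$condition <- as.character(d$condition)
  gm <- mean(d$proportion)
  w <- length(unique(d$condition))
  g <- length(unique(d$group))
  subj <- dplyr::summarise(dplyr::group_by(d, participant_id, group),
                           m = mean(proportion), .groups = "drop")
  n_per <- nrow(subj) / g
  grp_m <- dplyr::summarise(dplyr::group_by(subj, group), m = mean(m), .groups = "drop")
  ss_group <- w * n_per * sum((grp_m$m - gm)^2)
  ss_subj_within <- w * sum((subj$m - grp_m$m[match(subj$group, grp_m$group)])^2)
  cond_m <- dplyr::summarise(dplyr::group_by(d, condition), m = mean(proportion),
                             .groups = "drop")
  ss_cond <- g * n_per * sum((cond_m$m - gm)^2)
  cell_m <- dplyr::summarise(dplyr::group_by(d, group, condition),
                             m = mean(proportion), .groups = "drop")
  cell_m$exp <- grp_m$m[match(cell_m$group, grp_m$group)] +
    cond_m$m[match(cell_m$condition, cond_m$condition)] - gm
  ss_int <- n_per * sum((cell_m$m - cell_m$exp)^2)
  ss_total <- sum((d$proportion - gm)^2)
  ss_within_err <- ss_total - ss_group - ss_subj_within - ss_cond - ss_int
  list(
    group = list(SS = ss_group, df = g - 1, SS_err = ss_subj_within,
                 df_err = g * (n_per - 1)),
    condition = list(SS = ss_cond, df = w - 1, SS_err = ss_within_err,
                     df_err = g * (n_per - 1) * (w - 1)),
    interaction = list(SS = ss_int, df = (g - 1) * (w - 1), SS_err = ss_within_err,
                       df_err = g * (n_per - 1) * (w - 1))
  )
}

# Small simulated study cached per session (simulate once, reuse in tests).
cached_study <- local({
  env <- new.env()
  function(seed = 42L) {
    key <- paste0("s", seed)
    if (is.null(env[[key]])) env[[key]] <- simulate_study(simulation_config(seed = seed))
    env[[key]]
  }
})
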