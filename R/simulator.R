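# Location mu such that E[plogis(mu + sd * Z)] = target_p for Z ~ N(0,1),
# so participant-level retention draws are mean-calibrated (a plain shift on
# the log-odds scale would bias cell means toward 0.5). Cached per
# (target_p, sd) since simulate_study reuses a handful of cells.
.logit_mu_cache <- new.env(parent = emptyenv())

logit_location_for_mean <- function(target_p, sd_logit) {
  if (sd_logit == 0) return(qlogis(target_p))
  key <- paste(format(target_p, digits = 12), format(sd_logit, digits = 12))
  if (!is.null(.logit_mu_cache[[key]])) return(.logit_mu_cache[[key]])
  mean_at <- function(mu) {
    integrate(function(z) plogis(mu + sd_logit * z) * stats::dnorm(z),
              lower = -8, upper = 8, rel.tol = 1e-10)$value
  }
  mu <- uniroot(function(m) mean_at(m) - target_p,
                lower = qlogis(target_p) - 4 * sd_logit,
                upper = qlogis(target_p) + 4 * sd_logit,
                tol = 1e-10)$root
  .logit_mu_cache[[key]] <- mu
  mu
}

#' Draw a participant-level retention probability
#'
#' Between-participant heterogeneity in retention is modelled on the
#' log-odds scale: a normal perturbation with standard deviation `sd_logit`
#' is applied and back-transformed. The location is calibrated so the mean
#' of the draws equals `base_p` (an uncalibrated logit-normal would shrink
#' cell means toward 0.5).
#'
#' @param base_p Cell-level retention probability, strictly inside (0, 1)
#'   unless `sd_logit = 0`.
#' @param sd_logit Standard deviation of the log-odds perturbation (>= 0).
#' @param n Number of draws.
#'
#' @return Numeric vector of probabilities in (0, 1).
#' @export
simulate_participant_heterogeneity <- function(base_p, sd_logit, n = 1L) {
  if (is.na(base_p) || base_p < 0 || base_p > 1) stop_input("`base_p` must be in [0, 1].")
  if (is.na(sd_logit) || sd_logit < 0) stop_input("`sd_logit` must be >= 0.")
  if (sd_logit == 0) return(rep(base_p, n))
  if (base_p <= 0 || base_p >= 1) {
    stop_input("`base_p` must be strictly inside (0, 1) when `sd_logit` > 0.")
  }
  plogis(rnorm(n, mean = logit_location_for_mean(base_p, sd_logit), sd = sd_logit))
}

#' Simulate one free-recall output
#'
#' Generative stand-in for a coded human recall output. Each of the
#' `n_units` idea units is retained independently with probability
#' `retention_p`; the retained units start in text order; then
#' `K ~ Poisson(disorder_rate * n_retained)` uniformly random adjacent
#' transpositions are applied. At `disorder_rate = 0` the output is in
#' perfect text order (order score 0); increasing the rate makes the output
#' stochastically less ordered.
#'
#' @param n_units Number of idea units in the (section of) text.
#' @param retention_p Per-unit retention probability in `[0, 1]`.
#' @param disorder_rate Expected adjacent transpositions per retained unit
#'   (>= 0).
#'
#' @return Integer vector of recalled original positions in output order
#'   (possibly empty).
#' @export
#' @examples
#' set.seed(1)
#' simulate_recall(30, retention_p = 0.5, disorder_rate = 0.2)
simulate_recall <- function(n_units, retention_p, disorder_rate) {
  if (is.na(retention_p) || retention_p < 0 || retention_p > 1) {
    stop_input("`retention_p` must be in [0, 1].")
  }
  if (is.na(disorder_rate) || disorder_rate < 0) {
    stop_input("`disorder_rate` must be >= 0.")
  }
  retained <- which(runif(n_units) < retention_p)
  n <- length(retained)
  if (n >= 2L && disorder_rate > 0) {
    k <- rpois(1L, disorder_rate * n)
    if (k > 0L) {
      at <- sample.int(n - 1L, k, replace = TRUE)
      for (i in at) retained[c(i, i + 1L)] <- retained[c(i + 1L, i)]
    }
  }
  retained
}

# Default per-cell generative parameters. Retention probabilities are the
# condition-level mean proportions the design is expected to produce;
# disorder rates were calibrated by Monte Carlo (see the methods vignette)
# so that expected order scores per cell land on the condition-by-group
# means the analysis pipeline is meant to detect.
default_cell_params <- function() {
  tibble::tibble(
    group     = rep(c("TD", "ADHD"), each = 5L),
    condition = rep(c("WTR", "SR", "restudy", "WTR", "SR"), times = 2L),
    phase     = rep(c("practice", "practice", "criterion", "criterion", "criterion"),
                    times = 2L),
    retention = rep(c(0.54, 0.81, 0.42, 0.45, 0.37), times = 2L),
    disorder  = c(
      # TD: practice WTR/SR; criterion restudy/WTR/SR
      0.56, 0.56, 0.86, 1.17, 3.66,
      # ADHD
      1.27, 1.27, 1.53, 2.18, 9.62
    )
  )
}

#' Build a simulation configuration
#'
#' Collects the generative parameters for [simulate_study()]: group sizes,
#' text structure, per-cell retention probabilities and order-noise rates,
#' between-participant heterogeneity, and the random seed. The defaults
#' emulate the standard study conditions: 36 participants per group, three
#' 30-unit texts in five sections, practice retention of 0.81 (SR) and 0.54
#' (WTR), criterion retention of 0.42/0.45/0.37 (restudy/WTR/SR), and
#' disorder rates calibrated so expected criterion order scores are about
#' 0.10/0.11/0.21 with ADHD participants less ordered than TD overall
#' (about 0.16 vs 0.12).
#'
#' @param n_per_group Participants per group (multiple of 36; default 36).
#' @param texts Tibble of texts (default [default_texts()]).
#' @param cell_params Tibble with columns `group`, `condition`, `phase`,
#'   `retention`, `disorder` covering the five observed cells per group
#'   (practice WTR/SR; criterion restudy/WTR/SR).
#' @param sd_logit Between-participant SD of retention on the log-odds
#'   scale (default 0.7).
#' @param carryover Item-level practice-to-criterion dependence in `[0, 1]`;
#'   0 (default) simulates criterion retention independently of practice.
#' @param seed Integer root seed.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_per_group = 36L,
                              texts = default_texts(),
                              cell_params = default_cell_params(),
                              sd_logit = 0.7,
                              carryover = 0,
                              seed = 1L) {
  req <- c("group", "condition", "phase", "retention", "disorder")
  if (!all(req %in% names(cell_params))) {
    stop_input("`cell_params` must have columns group, condition, phase, retention, disorder.")
  }
  need <- expand.grid(group = group_levels(),
                      condition = c("WTR", "SR"), phase = "practice",
                      stringsAsFactors = FALSE)
  need <- rbind(need, expand.grid(group = group_levels(),
                                  condition = condition_levels(), phase = "criterion",
                                  stringsAsFactors = FALSE))
  have <- paste(cell_params$group, cell_params$condition, cell_params$phase)
  missing_cells <- setdiff(paste(need$group, need$condition, need$phase), have)
  if (length(missing_cells) > 0L) {
    stop_input(paste0("`cell_params` is missing cells: ",
                      paste(missing_cells, collapse = "; "), "."))
  }
  if (any(cell_params$retention < 0 | cell_params$retention > 1)) {
    stop_input("All retention probabilities must be in [0, 1].")
  }
  if (any(cell_params$disorder < 0)) stop_input("All disorder rates must be >= 0.")
  if (is.na(sd_logit) || sd_logit < 0) stop_input("`sd_logit` must be >= 0.")
  if (is.na(carryover) || carryover < 0 || carryover > 1) {
    stop_input("`carryover` must be in [0, 1].")
  }
  if (n_per_group %% 36L != 0L) {
    stop_input("`n_per_group` must be a multiple of the 36 design versions.")
  }
  structure(
    list(n_per_group = as.integer(n_per_group), texts = texts,
         cell_params = cell_params, sd_logit = sd_logit,
         carryover = carryover, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

cell_param <- function(cfg, group, condition, phase) {
  p <- cfg$cell_params
  row <- p[p$group == group & p$condition == condition & p$phase == phase, ]
  if (nrow(row) != 1L) {
    stop_input(sprintf("No cell parameters for (%s, %s, %s).", group, condition, phase))
  }
  row
}

# Deterministic per-participant substream seed, kept below 2^31.
participant_seed <- function(root_seed, index) {
  (abs(as.numeric(root_seed)) * 9973 + index * 7919) %% 2147483647
}

# Long-format rows for one output; an empty recall is encoded as a single
# row with position_in_output 0 and NA original_unit so the cell survives
# CSV round-trips.
output_rows <- function(participant_id, text_id, condition, phase, units) {
  if (length(units) == 0L) {
    return(tibble::tibble(participant_id = participant_id, text_id = text_id,
                          condition = condition, phase = phase,
                          position_in_output = 0L, original_unit = NA_integer_))
  }
  tibble::tibble(participant_id = participant_id, text_id = text_id,
                 condition = condition, phase = phase,
                 position_in_output = seq_along(units),
                 original_unit = as.integer(units))
}

# ASRS item responses consistent with a participant's group: a per-
# participant symptom propensity theta drawn to put TD and ADHD group sum
# means near 42 and 61 (of a 0-72 range), items ~ Binomial(4, theta).
simulate_asrs_items <- function(group) {
  target <- if (group == "ADHD") rnorm(1, 60.7, 7.5) else rnorm(1, 41.8, 5.5)
  theta <- min(max(target / 72, 0.02), 0.98)
  rbinom(18L, size = 4L, prob = theta)
}

#' Simulate a full retrieval-practice study
#'
#' Generates a participant roster (two groups, counterbalancing versions
#' assigned via [assign_versions()], ASRS responses and ages) and the
#' complete set of coded recall outputs: practice outputs for the WTR and
#' SR conditions (SR generated section by section and concatenated) and
#' criterion outputs for all three conditions. Retention varies between
#' participants via a shared log-odds offset (see
#' [simulate_participant_heterogeneity()]); output order is perturbed by
#' Poisson adjacent-transposition noise (see [simulate_recall()]).
#'
#' Each participant's data are drawn from a substream seeded
#' deterministically by (root seed, participant index), so the dataset is
#' reproducible and stable under partial regeneration.
#'
#' @param config A [simulation_config()].
#'
#' @return A list with `roster` (tibble: `participant_id`, `group`, `age`,
#'   `version_id`, `asrs_sum`, `asrs_positive`) and `outputs` (long-format
#'   tibble as consumed by [score_dataset()]).
#' @export
#' @examples
#' study <- simulate_study(simulation_config(seed = 42))
#' nrow(study$roster)  # 72
simulate_study <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    stop_input("`config` must be created by simulation_config().")
  }
  design <- generate_design(texts = config$texts$text_id)
  roster0 <- assign_versions(config$n_per_group)
  n_total <- nrow(roster0)

  roster_rows <- vector("list", n_total)
  out_rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    set.seed(participant_seed(config$seed, i))
    grp <- as.character(roster0$group[i])
    pid <- roster0$participant_id[i]
    ver <- design[design$version_id == roster0$version_id[i], ]

    items <- simulate_asrs_items(grp)
    roster_rows[[i]] <- tibble::tibble(
      participant_id = pid, group = grp,
      age = round(rnorm(1, mean = if (grp == "ADHD") 25.6 else 24.8, sd = 3), 1),
      version_id = roster0$version_id[i],
      asrs_sum = asrs_sum(items),
      asrs_positive = asrs_screen(asrs_sum(items))
    )

    u_i <- rnorm(1, 0, config$sd_logit)
    draw_p <- function(condition, phase) {
      cp <- cell_param(config, grp, condition, phase)
      if (config$sd_logit == 0) return(cp$retention)
      plogis(logit_location_for_mean(cp$retention, config$sd_logit) + u_i)
    }

    texts <- config$texts
    text_for <- function(cond) ver[[paste0("text_for_", cond)]]
    rows <- list()

    # Practice: WTR whole text; SR per section, concatenated.
    wtr_text <- texts[texts$text_id == text_for("WTR"), ]
    wtr_prac <- simulate_recall(wtr_text$n_units, draw_p("WTR", "practice"),
                                cell_param(config, grp, "WTR", "practice")$disorder)
    rows[[1]] <- output_rows(pid, wtr_text$text_id, "WTR", "practice", wtr_prac)

    sr_text <- texts[texts$text_id == text_for("SR"), ]
    per <- sr_text$n_units %/% sr_text$n_sections
    p_sr <- draw_p("SR", "practice")
    d_sr <- cell_param(config, grp, "SR", "practice")$disorder
    sr_prac <- unlist(lapply(seq_len(sr_text$n_sections), function(s) {
      simulate_recall(per, p_sr, d_sr) + (s - 1L) * per
    }))
    rows[[2]] <- output_rows(pid, sr_text$text_id, "SR", "practice", sr_prac)

    practiced <- list(WTR = wtr_prac, SR = sr_prac)

    # Criterion: all three conditions on their assigned texts.
    for (j in seq_along(condition_levels())) {
      cond <- condition_levels()[j]
      txt <- texts[texts$text_id == text_for(cond), ]
      p_crit <- draw_p(cond, "criterion")
      d_crit <- cell_param(config, grp, cond, "criterion")$disorder
      if (config$carryover > 0 && cond %in% names(practiced)) {
        # Item-level dependence hook: units recalled at practice keep an
        # elevated criterion retention probability.
        p_item <- (1 - config$carryover) * p_crit +
          config$carryover * as.numeric(seq_len(txt$n_units) %in% practiced[[cond]])
        retained <- which(runif(txt$n_units) < p_item)
        n <- length(retained)
        if (n >= 2L && d_crit > 0) {
          k <- rpois(1L, d_crit * n)
          if (k > 0L) {
            at <- sample.int(n - 1L, k, replace = TRUE)
            for (ii in at) retained[c(ii, ii + 1L)] <- retained[c(ii + 1L, ii)]
          }
        }
        crit <- retained
      } else {
        crit <- simulate_recall(txt$n_units, p_crit, d_crit)
      }
      rows[[2L + j]] <- output_rows(pid, txt$text_id, cond, "criterion", crit)
    }
    out_rows[[i]] <- dplyr::bind_rows(rows)
  }

  list(roster = dplyr::bind_rows(roster_rows),
       outputs = dplyr::bind_rows(out_rows))
}
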