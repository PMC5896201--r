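#' Sample donor event counts for a gate
#'
#' Models the flow-cytometry readout: given the true donor chimerism of a
#' lineage, the number of donor-positive events in a gate of `gate_size`
#' events is Binomial(`gate_size`, `true_percent`/100).
#'
#' @param true_percent True chimerism percent in \[0, 100\] (vectorised).
#' @param gate_size Total events in the gate, >= 1 (vectorised).
#' @param seed Optional integer for a reproducible draw.
#' @return Tibble with columns `donor_events` and `total_events`.
#' @examples
#' sample_gate_counts(0.5, 30000, seed = 1)
#' @export
sample_gate_counts <- function(true_percent, gate_size, seed = NULL) {
  if (any(true_percent < 0 | true_percent > 100)) {
    abort("true_percent must lie in [0, 100]")
  }
  if (any(gate_size < 1)) abort("gate_size must be >= 1")
  n <- max(length(true_percent), length(gate_size))
  true_percent <- rep_len(true_percent, n)
  gate_size <- rep_len(gate_size, n)
  draw <- function() rbinom(n, size = gate_size, prob = true_percent / 100)
  donor <- if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
  tibble(donor_events = as.numeric(donor), total_events = as.numeric(gate_size))
}

# uniform integer draw in [range[1], range[2]], vectorised over n
runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

# long parameter table of an archetype library: one row per label x lineage
archetype_param_table <- function(archetypes, stage = "primary") {
  rows <- lapply(archetypes, function(a) {
    if (stage == "primary") {
      tibble(true_label = a$label, lineage = .lineages,
             plateau = unname(a$plateau), onset = unname(a$onset_week),
             rise = unname(a$rise_rate),
             decay_start = unname(a$decay_start_week),
             decay_rate = unname(a$decay_rate))
    } else {
      tibble(true_label = a$label, lineage = .lineages,
             plateau = unname(a$secondary_plateau),
             onset = a$secondary_onset_week, rise = a$secondary_rise_rate,
             decay_start = NA_real_, decay_rate = 0)
    }
  })
  bind_rows(rows)
}

#' Simulate a single-cell transplantation cohort
#'
#' Draws `n_clones` independent clones from a scenario: each clone is
#' assigned a sorting fraction (proportional to fraction shares), an
#' archetype from that fraction's mixture and a log-normal plateau
#' multiplier; its true five-lineage trajectory is evaluated at the primary
#' timepoints and read out through binomially sampled gates. Primary
#' recipients die with the scenario's death probability, censored at a
#' uniformly drawn timepoint. Primaries of archetypes with engrafting marrow
#' found 1-5 secondary recipients, observed on the secondary schedule.
#'
#' @param sc An [scenario()].
#' @param n_clones Number of transplanted single cells (>= 1).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return An object of class `hsclone_cohort`: a list with `chimerism`
#'   (long observation table, one row per recipient x week x lineage),
#'   `clones` (one row per clone with `true_label`, `fraction`, `dead`,
#'   `death_week`, `n_secondaries`) and `scenario`.
#' @export
simulate_cohort <- function(sc, n_clones, seed = 1L) {
  validate_scenario(sc)
  if (n_clones < 1) abort("n_clones must be >= 1")
  withr::with_seed(seed, simulate_cohort_impl(sc, n_clones))
}

simulate_cohort_impl <- function(sc, n_clones) {
  ff <- sc$fraction_frequencies
  id_width <- max(4, nchar(as.character(n_clones)))
  clone_id <- sprintf(paste0("C%0", id_width, "d"), seq_len(n_clones))

  frac_prob <- ff$shares / sum(ff$shares)
  fraction <- sample(.fractions, n_clones, replace = TRUE, prob = frac_prob)
  true_label <- character(n_clones)
  for (f in .fractions) {
    idx <- which(fraction == f)
    mix <- sc$fraction_mixtures[[f]]
    if (length(idx) > 0) {
      true_label[idx] <- sample(names(mix), length(idx), replace = TRUE,
                                prob = mix)
    }
  }
  jitter <- exp(rnorm(n_clones, 0, sc$plateau_jitter_sd))

  dead <- runif(n_clones) < sc$death_probability
  death_week <- rep(NA_real_, n_clones)
  death_week[dead] <- sample(sc$timepoints_primary, sum(dead), replace = TRUE)

  engraft_p <- vapply(sc$archetypes[true_label], `[[`, numeric(1),
                      "engraft_probability")
  engrafts <- !dead & runif(n_clones) < engraft_p
  n_sec <- integer(n_clones)
  n_sec[engrafts] <- runif_int(sum(engrafts), sc$n_secondaries_range)

  clones <- tibble(
    clone_id = clone_id, age_group = sc$age_group, fraction = fraction,
    true_label = true_label, jitter = jitter,
    dead = dead, death_week = death_week, n_secondaries = n_sec
  )

  obs_primary <- simulate_stage_observations(
    clones, sc, stage = "primary",
    recipients = tibble(clone_id = clone_id, recipient_id = clone_id)
  )
  # truncate dead recipients at their (last observed) death week
  obs_primary <- obs_primary %>%
    left_join(select(clones, "clone_id", "dead", "death_week"), by = "clone_id") %>%
    filter(!.data$dead | .data$week <= .data$death_week) %>%
    mutate(censored_week = ifelse(.data$dead, .data$death_week, NA_real_)) %>%
    select(-"dead", -"death_week")

  sec_recipients <- clones %>%
    filter(.data$n_secondaries > 0) %>%
    select("clone_id", "n_secondaries") %>%
    tidyr::uncount(.data$n_secondaries, .id = "sec_idx") %>%
    mutate(recipient_id = paste0(.data$clone_id, "-S", .data$sec_idx)) %>%
    select("clone_id", "recipient_id")
  obs_secondary <- if (nrow(sec_recipients) > 0) {
    simulate_stage_observations(clones, sc, stage = "secondary",
                                recipients = sec_recipients) %>%
      mutate(censored_week = NA_real_)
  } else {
    NULL
  }

  chim <- bind_rows(obs_primary, obs_secondary)
  chim <- chim[chimerism_columns()]
  chim <- arrange(chim, .data$clone_id, .data$recipient_id, .data$week,
                  .data$lineage)
  structure(list(chimerism = chim,
                 clones = select(clones, -"jitter"),
                 scenario = sc),
            class = "hsclone_cohort")
}

# evaluate true trajectories and sample gates for one stage
simulate_stage_observations <- function(clones, sc, stage, recipients) {
  weeks <- if (stage == "primary") sc$timepoints_primary else sc$timepoints_secondary
  params <- archetype_param_table(sc$archetypes, stage = stage)
  grid <- recipients %>%
    left_join(select(clones, "clone_id", "age_group", "fraction",
                     "true_label", "jitter"), by = "clone_id") %>%
    tidyr::expand_grid(week = weeks, lineage = .lineages) %>%
    left_join(params, by = c("true_label", "lineage"))
  true_pct <- trajectory_value(
    grid$week, plateau = pmin(100, grid$jitter * grid$plateau),
    onset = grid$onset, rise = grid$rise,
    decay_start = grid$decay_start, decay_rate = grid$decay_rate
  )
  gate_class <- .gate_class[grid$lineage]
  total <- numeric(nrow(grid))
  for (g in unique(gate_class)) {
    idx <- gate_class == g
    total[idx] <- runif_int(sum(idx), sc$gate_size_ranges[[g]])
  }
  donor <- rbinom(nrow(grid), size = total, prob = true_pct / 100)
  grid %>%
    mutate(stage = stage, donor_events = as.numeric(donor),
           total_events = as.numeric(total),
           percent = 100 * donor / total) %>%
    select("clone_id", "recipient_id", "stage", "age_group", "fraction",
           "week", "lineage", "donor_events", "total_events", "percent")
}

#' @export
print.hsclone_cohort <- function(x, ...) {
  cat("<hsclone_cohort>", nrow(x$clones), "clones (", x$scenario$age_group,
      ");", sum(x$clones$dead), "dead;",
      sum(x$clones$n_secondaries), "secondary recipients;",
      nrow(x$chimerism), "observations\n")
  invisible(x)
}

#' Censor clones as dead at a given week
#'
#' Marks the given clones dead, records the censoring week and drops their
#' observations after it. Used to build cohorts with an exact number of
#' censored recipients.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param clone_ids Clones to flag dead.
#' @param at_week Last observed week for the flagged clones.
#' @return The modified cohort.
#' @export
censor_clones <- function(cohort, clone_ids, at_week) {
  stopifnot(inherits(cohort, "hsclone_cohort"))
  unknown <- setdiff(clone_ids, cohort$clones$clone_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown clone_id(s): ", paste(head(unknown, 3), collapse = ", ")))
  }
  sel <- cohort$clones$clone_id %in% clone_ids
  cohort$clones$dead[sel] <- TRUE
  cohort$clones$death_week[sel] <- at_week
  cohort$clones$n_secondaries[sel] <- 0L
  hit <- cohort$chimerism$clone_id %in% clone_ids
  keep <- !hit | (cohort$chimerism$stage == "primary" &
                    cohort$chimerism$week <= at_week)
  cohort$chimerism <- cohort$chimerism[keep, ]
  cohort$chimerism$censored_week[cohort$chimerism$clone_id %in% clone_ids] <- at_week
  cohort
}
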