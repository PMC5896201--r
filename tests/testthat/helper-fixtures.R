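# Fixture builders: hand-constructed chimerism rows and noise-free cohorts.

# rows of the standard long chimerism table for one recipient; `percents` is
# a named list lineage -> vector over `weeks` (unnamed lineages omitted =
# unobserved). Counts are left NA unless gate_size is given.
series_rows <- function(clone_id, weeks, percents, stage = "primary",
                        recipient_id = clone_id, age_group = "young",
                        fraction = "F1", gate_size = NULL,
                        censored_week = NA_real_) {
  rows <- lapply(names(percents), function(l) {
    pct <- rep_len(percents[[l]], length(weeks))
    tibble::tibble(
      clone_id = clone_id, recipient_id = recipient_id, stage = stage,
      age_group = age_group, fraction = fraction, week = weeks, lineage = l,
      donor_events = if (is.null(gate_size)) NA_real_
                     else round(pct / 100 * gate_size),
      total_events = if (is.null(gate_size)) NA_real_ else gate_size,
      percent = pct, censored_week = censored_week
    )
  })
  dplyr::bind_rows(rows)
}

# noise-free cohort: each default archetype once, trajectories evaluated
# without jitter or gate sampling; one secondary recipient per engrafting
# archetype
noise_free_cohort <- function(archetypes = default_archetypes(),
                              weeks_primary = c(2, 3, 4, 8, 12, 16, 20, 24),
                              weeks_secondary = c(4, 12, 16, 20, 21)) {
  rows <- lapply(seq_along(archetypes), function(i) {
    a <- archetypes[[i]]
    id <- sprintf("NF%02d", i)
    prim <- simulate_true_trajectory(a, weeks_primary, jitter_sd = 0)
    prim_rows <- series_rows(id, weeks_primary,
                             as.list(as.data.frame(prim)))
    sec_rows <- NULL
    if (a$engraft_probability > 0) {
      sec <- simulate_true_trajectory(a, weeks_secondary, jitter_sd = 0,
                                      stage = "secondary")
      sec_rows <- series_rows(id, weeks_secondary,
                              as.list(as.data.frame(sec)),
                              stage = "secondary",
                              recipient_id = paste0(id, "-S1"))
    }
    dplyr::bind_rows(prim_rows, sec_rows)
  })
  chim <- dplyr::bind_rows(rows)
  truth <- tibble::tibble(
    clone_id = sprintf("NF%02d", seq_along(archetypes)),
    true_label = unname(vapply(archetypes, `[[`, character(1), "label"))
  )
  list(chimerism = chim, truth = truth)
}
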