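#' Classification criteria
#'
#' All thresholds and windows governing lineage positivity, the duration
#' class and the cell-type mapping.
#'
#' @param threshold_percent Reconstitution threshold tau in percent donor
#'   chimerism (default 0.005; 0.1 is the standard alternative for
#'   sensitivity analyses).
#' @param min_positive_timepoints Number of observed weeks a lineage must
#'   meet the threshold to count as positive (default 1).
#' @param min_donor_events Minimum donor events backing a positive
#'   observation, applied only when raw counts are available (default 2;
#'   guards against single-event artifacts: 0.005% of a 30,000-event gate is
#'   1.5 events).
#' @param terminal_week Last week of the primary follow-up (default 24);
#'   positivity here separates ST from IT/LT clones.
#' @param lt_secondary_week Earliest secondary-recipient week at which
#'   engraftment demonstrates long-term activity (default 16).
#' @param hsc_requires_all_five If `TRUE`, the HSC call requires all five
#'   lineages; default `FALSE`: nm, E and P plus at least one lymphoid
#'   lineage (B and/or T) suffice.
#' @return An object of class `hsclone_criteria`.
#' @export
classification_criteria <- function(threshold_percent = 0.005,
                                    min_positive_timepoints = 1L,
                                    min_donor_events = 2L,
                                    terminal_week = 24,
                                    lt_secondary_week = 16,
                                    hsc_requires_all_five = FALSE) {
  if (threshold_percent <= 0) abort("threshold_percent must be > 0")
  if (min_positive_timepoints < 1) abort("min_positive_timepoints must be >= 1")
  if (min_donor_events < 1) abort("min_donor_events must be >= 1")
  structure(list(threshold_percent = threshold_percent,
                 min_positive_timepoints = as.integer(min_positive_timepoints),
                 min_donor_events = as.integer(min_donor_events),
                 terminal_week = terminal_week,
                 lt_secondary_week = lt_secondary_week,
                 hsc_requires_all_five = isTRUE(hsc_requires_all_five)),
            class = "hsclone_criteria")
}

#' @export
print.hsclone_criteria <- function(x, ...) {
  cat("<hsclone_criteria> tau =", x$threshold_percent,
      "% | min timepoints =", x$min_positive_timepoints,
      "| min donor events =", x$min_donor_events,
      "| terminal week =", x$terminal_week,
      "| LT secondary week >=", x$lt_secondary_week, "\n")
  invisible(x)
}

# one observation counts toward positivity when it meets the threshold and,
# where counts exist, the minimum-event rule
observation_positive <- function(percent, donor_events, criteria) {
  percent >= criteria$threshold_percent &
    (is.na(donor_events) | donor_events >= criteria$min_donor_events)
}

#' Positive lineages of one chimerism series
#'
#' A lineage is positive when it has at least `min_positive_timepoints`
#' observed weeks at or above the threshold (and, when raw counts are
#' available, with at least `min_donor_events` donor events).
#'
#' @param series Rows of the long chimerism table for one recipient (columns
#'   `lineage`, `percent`, and optionally `donor_events`).
#' @param criteria A [classification_criteria()].
#' @return Character vector of positive lineages, in canonical order.
#' @export
lineage_positivity <- function(series, criteria = classification_criteria()) {
  if (!"donor_events" %in% names(series)) series$donor_events <- NA_real_
  pos <- observation_positive(series$percent, series$donor_events, criteria)
  counts <- tapply(pos, factor(series$lineage, levels = .lineages), sum)
  counts[is.na(counts)] <- 0
  .lineages[counts >= criteria$min_positive_timepoints]
}

#' Duration class of a clone
#'
#' Repopulating clones are classed by how long their output lasts:
#' * `none` — no positive lineage in the primary recipient
#'   (non-reconstituting);
#' * `ST` — reconstituting, but no lineage meets the threshold at the
#'   primary terminal week;
#' * `LT` — positive at the terminal week *and* at least one linked
#'   secondary recipient shows any lineage at or above threshold at or after
#'   `lt_secondary_week`;
#' * `IT` — positive at the terminal week without such secondary evidence.
#'   When no secondary assay exists the LT/IT distinction is unresolved;
#'   such clones are reported `IT` with `lt_it_unresolved = TRUE`.
#'
#' @param primary Rows of the long chimerism table for the primary recipient.
#' @param secondaries Rows for all linked secondary recipients (possibly
#'   zero rows).
#' @param criteria A [classification_criteria()].
#' @return List with `duration_class` (`"none"`, `"ST"`, `"IT"` or `"LT"`)
#'   and `lt_it_unresolved` (logical).
#' @export
duration_call <- function(primary, secondaries = NULL,
                          criteria = classification_criteria()) {
  if (is.null(secondaries)) {
    secondaries <- primary[0, , drop = FALSE]
  }
  if (!"donor_events" %in% names(primary)) primary$donor_events <- NA_real_
  if (nrow(secondaries) > 0 && !"donor_events" %in% names(secondaries)) {
    secondaries$donor_events <- NA_real_
  }
  lin <- lineage_positivity(primary, criteria)
  if (length(lin) == 0) {
    return(list(duration_class = "none", lt_it_unresolved = FALSE))
  }
  pos <- observation_positive(primary$percent, primary$donor_events, criteria)
  terminal_pos <- any(pos & primary$week == criteria$terminal_week)
  if (!terminal_pos) {
    return(list(duration_class = "ST", lt_it_unresolved = FALSE))
  }
  has_secondary <- nrow(secondaries) > 0
  lt_evidence <- FALSE
  if (has_secondary) {
    spos <- observation_positive(secondaries$percent, secondaries$donor_events,
                                 criteria)
    lt_evidence <- any(spos & secondaries$week >= criteria$lt_secondary_week)
  }
  if (lt_evidence) {
    list(duration_class = "LT", lt_it_unresolved = FALSE)
  } else {
    list(duration_class = "IT", lt_it_unresolved = !has_secondary)
  }
}

#' Map a lineage set and duration class to a cell type
#'
#' The taxonomy recognises the nested myeloid-restricted chain (platelets
#' only -> Mk; platelets + erythrocytes -> ME; + neutrophils/monocytes ->
#' CM), taking the suffix RP (repopulating progenitor) for ST clones and SC
#' (stem cell) for IT/LT clones; HSCs (full myeloid output plus lymphoid);
#' `non-reconstituting` for the empty set; and `other` for any remaining
#' combination (e.g. lymphoid-only output).
#'
#' @param lineages Character vector of positive lineages (subset of
#'   [lineage_codes()]).
#' @param duration `"none"`, `"ST"`, `"IT"` or `"LT"`.
#' @param criteria A [classification_criteria()] (controls whether HSC
#'   requires all five lineages).
#' @return A single taxonomy label (see [cell_types()]).
#' @export
cell_type_call <- function(lineages, duration,
                           criteria = classification_criteria()) {
  unknown <- setdiff(lineages, .lineages)
  if (length(unknown) > 0) {
    abort(paste0("unknown lineage code(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(lineages) == 0) return("non-reconstituting")
  if (!duration %in% c("ST", "IT", "LT")) {
    abort("reconstituting clones must have duration ST, IT or LT")
  }
  lineages <- unique(lineages)
  is_hsc <- if (criteria$hsc_requires_all_five) {
    setequal(lineages, .lineages)
  } else {
    all(.myeloid %in% lineages) && any(.lymphoid %in% lineages)
  }
  if (is_hsc) return(paste0(duration, "-HSC"))
  base <- if (setequal(lineages, "P")) "Mk"
          else if (setequal(lineages, c("E", "P"))) "ME"
          else if (setequal(lineages, c("nm", "E", "P"))) "CM"
          else NA_character_
  if (is.na(base)) return("other")
  suffix <- if (duration == "ST") "RP" else "SC"
  paste0(duration, "-", base, suffix)
}

#' Latent-HSC call
#'
#' A latent-HSC is a clone whose primary-recipient output was restricted to
#' myeloid lineages (a nonempty subset of nm, E, P) yet persisted to the
#' terminal week (IT/LT duration), and which revealed lymphoid potential —
#' B and/or T cells — after secondary transplantation. Requires at least one
#' secondary assay.
#'
#' @param lineages_primary Positive lineages in the primary recipient.
#' @param duration_class Duration class of the clone (`"ST"`, `"IT"`,
#'   `"LT"` or `"none"`).
#' @param lineages_secondary_union Union of positive lineages over all
#'   linked secondary recipients.
#' @return `TRUE` when the clone is a latent-HSC; the cell type is then
#'   reassigned to `"latent-HSC"`.
#' @export
latent_call <- function(lineages_primary, duration_class,
                        lineages_secondary_union) {
  length(lineages_primary) > 0 &&
    all(lineages_primary %in% .myeloid) &&
    duration_class %in% c("IT", "LT") &&
    any(.lymphoid %in% lineages_secondary_union)
}

# coerce classify input: cohort, or long chimerism table (+NULL clones)
as_cohort_tables <- function(x) {
  if (inherits(x, "hsclone_cohort")) {
    list(chimerism = x$chimerism, clones = x$clones)
  } else if (is.data.frame(x)) {
    list(chimerism = as_tibble(x), clones = NULL)
  } else {
    abort("x must be an hsclone_cohort or a long chimerism data frame")
  }
}

#' Classify every clone of a cohort
#'
#' Applies the full decision path to each surviving clone: lineage
#' positivity in the primary recipient, duration class from the primary
#' terminal week and linked secondary recipients, cell-type mapping, and the
#' latent-HSC override. Recipients flagged dead (non-missing
#' `censored_week`) are excluded before classification and receive no call.
#' The result is deterministic and independent of input row order.
#'
#' @param x An [simulate_cohort()] cohort or a long chimerism table (see
#'   [validate_table()] for the schema).
#' @param criteria A [classification_criteria()].
#' @return Tibble with one row per surviving clone, ordered by `clone_id`:
#'   `clone_id`, `age_group`, `fraction`, `lineages_primary`,
#'   `lineages_secondary_union` (both as `+`-separated strings, `NA` when no
#'   secondary assay exists), `n_secondaries`, `duration_class`, `cell_type`,
#'   `latent`, `lt_it_unresolved`. The criteria used and the number of
#'   excluded dead clones are attached as attributes.
#' @export
classify_cohort <- function(x, criteria = classification_criteria()) {
  dat <- as_cohort_tables(x)
  chim <- dat$chimerism
  if (nrow(chim) == 0) {
    out <- tibble(clone_id = character(), age_group = character(),
                  fraction = character(), lineages_primary = character(),
                  lineages_secondary_union = character(),
                  n_secondaries = integer(), duration_class = character(),
                  cell_type = character(), latent = logical(),
                  lt_it_unresolved = logical())
    attr(out, "criteria") <- criteria
    attr(out, "n_excluded_dead") <- 0L
    return(out)
  }
  if (!"donor_events" %in% names(chim)) chim$donor_events <- NA_real_
  if (!"censored_week" %in% names(chim)) chim$censored_week <- NA_real_

  dead_ids <- unique(chim$clone_id[!is.na(chim$censored_week)])
  if (!is.null(dat$clones)) {
    dead_ids <- union(dead_ids, dat$clones$clone_id[dat$clones$dead])
    no_obs <- setdiff(dat$clones$clone_id,
                      union(unique(chim$clone_id), dead_ids))
    if (length(no_obs) > 0) {
      abort(paste0("clone(s) with zero observed timepoints and no censoring ",
                   "flag: ", paste(head(no_obs, 3), collapse = ", ")))
    }
  }

  live <- chim %>% filter(!.data$clone_id %in% dead_ids)
  prim <- live %>%
    filter(.data$stage == "primary") %>%
    mutate(pos = observation_positive(.data$percent, .data$donor_events,
                                      criteria))
  meta <- prim %>% distinct(.data$clone_id, .data$age_group, .data$fraction)
  if (anyDuplicated(meta$clone_id) > 0) {
    abort("inconsistent age_group/fraction metadata within a clone")
  }

  lin_prim <- prim %>%
    group_by(.data$clone_id, .data$lineage) %>%
    summarise(npos = sum(.data$pos), .groups = "drop") %>%
    filter(.data$npos >= criteria$min_positive_timepoints) %>%
    group_by(.data$clone_id) %>%
    summarise(lineages_primary = lineage_set_string(.data$lineage),
              .groups = "drop")
  terminal <- prim %>%
    group_by(.data$clone_id) %>%
    summarise(terminal_pos = any(.data$pos &
                                   .data$week == criteria$terminal_week),
              .groups = "drop")

  sec <- live %>%
    filter(.data$stage == "secondary") %>%
    mutate(pos = observation_positive(.data$percent, .data$donor_events,
                                      criteria))
  orphan <- setdiff(unique(sec$clone_id), unique(prim$clone_id))
  if (length(orphan) > 0) {
    abort(paste0("secondary series without a linked primary: ",
                 paste(head(orphan, 3), collapse = ", ")))
  }
  sec_union <- sec %>%
    group_by(.data$clone_id, .data$recipient_id, .data$lineage) %>%
    summarise(npos = sum(.data$pos), .groups = "drop") %>%
    filter(.data$npos >= criteria$min_positive_timepoints) %>%
    group_by(.data$clone_id) %>%
    summarise(lineages_secondary_union = lineage_set_string(unique(.data$lineage)),
              .groups = "drop")
  sec_info <- sec %>%
    group_by(.data$clone_id) %>%
    summarise(n_secondaries = dplyr::n_distinct(.data$recipient_id),
              lt_evidence = any(.data$pos &
                                  .data$week >= criteria$lt_secondary_week),
              .groups = "drop")

  calls <- meta %>%
    left_join(lin_prim, by = "clone_id") %>%
    left_join(terminal, by = "clone_id") %>%
    left_join(sec_union, by = "clone_id") %>%
    left_join(sec_info, by = "clone_id") %>%
    mutate(
      lineages_primary = ifelse(is.na(.data$lineages_primary), "",
                                .data$lineages_primary),
      has_secondary = !is.na(.data$n_secondaries),
      n_secondaries = ifelse(.data$has_secondary, .data$n_secondaries, 0L),
      lt_evidence = ifelse(is.na(.data$lt_evidence), FALSE, .data$lt_evidence),
      lineages_secondary_union = dplyr::if_else(
        .data$has_secondary & is.na(.data$lineages_secondary_union), "",
        .data$lineages_secondary_union),
      duration_class = case_when(
        .data$lineages_primary == "" ~ "none",
        !.data$terminal_pos ~ "ST",
        .data$lt_evidence ~ "LT",
        TRUE ~ "IT"
      ),
      lt_it_unresolved = .data$duration_class == "IT" & !.data$has_secondary
    )

  calls$cell_type <- vapply(seq_len(nrow(calls)), function(i) {
    cell_type_call(lineage_set_from_string(calls$lineages_primary[i]),
                   calls$duration_class[i], criteria)
  }, character(1))
  calls$latent <- vapply(seq_len(nrow(calls)), function(i) {
    calls$has_secondary[i] && latent_call(
      lineage_set_from_string(calls$lineages_primary[i]),
      calls$duration_class[i],
      lineage_set_from_string(calls$lineages_secondary_union[i])
    )
  }, logical(1))
  calls$cell_type[calls$latent] <- "latent-HSC"

  out <- calls %>%
    select("clone_id", "age_group", "fraction", "lineages_primary",
           "lineages_secondary_union", "n_secondaries", "duration_class",
           "cell_type", "latent", "lt_it_unresolved") %>%
    arrange(.data$clone_id)
  attr(out, "criteria") <- criteria
  attr(out, "n_excluded_dead") <- length(dead_ids)
  out
}

#' Threshold sensitivity of the classification
#'
#' Re-runs [classify_cohort()] at each threshold and reports per-threshold
#' cell-type compositions together with the pairwise fraction of clones
#' whose cell type is unchanged between thresholds.
#'
#' @param x Cohort or long chimerism table.
#' @param thresholds Numeric vector of at least two positive thresholds
#'   (percent), e.g. `c(0.005, 0.1)`.
#' @param criteria Base [classification_criteria()]; each run overrides only
#'   `threshold_percent`.
#' @return List with `compositions` (tibble: `threshold`, `cell_type`, `n`,
#'   `p`) and `agreement` (tibble: `threshold_a`, `threshold_b`,
#'   `agreement`).
#' @export
threshold_sensitivity <- function(x, thresholds = c(0.005, 0.1),
                                  criteria = classification_criteria()) {
  if (length(thresholds) < 2) abort("need at least two thresholds")
  if (any(thresholds <= 0)) abort("thresholds must be positive")
  runs <- lapply(thresholds, function(tau) {
    crit <- criteria
    crit$threshold_percent <- tau
    classify_cohort(x, crit)
  })
  comp <- bind_rows(lapply(seq_along(thresholds), function(i) {
    calls <- runs[[i]]
    counts <- table(factor(calls$cell_type, levels = .cell_types))
    tibble(threshold = thresholds[i], cell_type = names(counts),
           n = as.integer(counts), p = as.integer(counts) / max(1, nrow(calls)))
  }))
  pairs <- utils::combn(seq_along(thresholds), 2)
  agreement <- bind_rows(lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tibble(threshold_a = thresholds[i], threshold_b = thresholds[j],
           agreement = mean(runs[[i]]$cell_type == runs[[j]]$cell_type))
  }))
  list(compositions = comp, agreement = agreement)
}
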