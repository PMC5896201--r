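#' Donor chimerism from flow-cytometry gate counts
#'
#' Chimerism is the percentage of donor-derived (reporter-positive) events
#' within a lineage gate of peripheral blood: `100 * donor_events /
#' total_events`.
#'
#' @param donor_events Number of donor-positive events in the gate.
#' @param total_events Total events in the gate (>= 1).
#' @return Chimerism percent in \[0, 100\]. Vectorised.
#' @examples
#' compute_chimerism(25, 500000) # 0.005
#' @export
compute_chimerism <- function(donor_events, total_events) {
  if (any(total_events < 1)) abort("total_events must be >= 1 (invalid gate)")
  if (any(donor_events < 0)) abort("donor_events must be >= 0")
  if (any(donor_events > total_events)) {
    abort("donor_events must not exceed total_events")
  }
  100 * donor_events / total_events
}

#' Smallest chimerism representable by a gate
#'
#' The detection floor of a gate of `total_events` events is the chimerism
#' corresponding to `min_donor_events` donor events. Useful to judge a
#' reconstitution threshold against gate size: 0.005% corresponds to 25
#' events in a 500,000-event erythrocyte gate but only 1.5 events in a
#' 30,000-event leukocyte gate.
#'
#' @param total_events Gate size (>= 1).
#' @param min_donor_events Minimum number of donor events deemed evidence
#'   (>= 1).
#' @return Percent floor, `100 * min_donor_events / total_events`. Vectorised.
#' @examples
#' detection_floor(500000, 25) # 0.005
#' detection_floor(30000, 2)   # ~0.0067: a 0.005% call needs < 2 events here
#' @export
detection_floor <- function(total_events, min_donor_events = 1) {
  if (any(total_events < 1)) abort("total_events must be >= 1")
  if (any(min_donor_events < 1)) abort("min_donor_events must be >= 1")
  100 * min_donor_events / total_events
}

# fixed column order of the long-format chimerism table
chimerism_columns <- function() {
  c("clone_id", "recipient_id", "stage", "age_group", "fraction",
    "week", "lineage", "donor_events", "total_events", "percent",
    "censored_week")
}

#' Assemble a long chimerism table from gate-count rows
#'
#' Groups raw gate rows (one per recipient x week x lineage) into the
#' package's standard long-format chimerism table, computing percents from
#' counts. When a `percent` column is also present, counts win; a mismatch
#' larger than 1e-6 percent raises a warning (counts carry the sampling
#' information the classifier's minimum-event rule needs). Missing
#' (week, lineage) cells are unobserved, never zero.
#'
#' @param gate_table Data frame with at least `recipient_id`, `week`,
#'   `lineage`, `donor_events`, `total_events`; optionally `clone_id`,
#'   `stage`, `age_group`, `fraction`, `percent`, `censored_week`.
#' @return A tibble with the standard chimerism columns (see
#'   [validate_table()] for the schema), one row per observed gate.
#' @export
assemble_series <- function(gate_table) {
  gate_table <- as_tibble(gate_table)
  if (nrow(gate_table) == 0) {
    out <- tibble(
      clone_id = character(), recipient_id = character(),
      stage = character(), age_group = character(), fraction = character(),
      week = numeric(), lineage = character(),
      donor_events = numeric(), total_events = numeric(),
      percent = numeric(), censored_week = numeric()
    )
    return(out[chimerism_columns()])
  }
  required <- c("recipient_id", "week", "lineage", "donor_events", "total_events")
  missing <- setdiff(required, names(gate_table))
  if (length(missing) > 0) {
    abort(paste0("gate_table lacks required columns: ",
                 paste(missing, collapse = ", ")))
  }
  bad_lin <- setdiff(unique(gate_table$lineage), .lineages)
  if (length(bad_lin) > 0) {
    abort(paste0("unknown lineage code(s): ", paste(bad_lin, collapse = ", ")))
  }
  dup <- duplicated(gate_table[c("recipient_id", "week", "lineage")])
  if (any(dup)) {
    abort(paste0("duplicated (recipient_id, week, lineage) keys, e.g. row ",
                 which(dup)[1]))
  }

  out <- gate_table
  if (!"clone_id" %in% names(out)) out$clone_id <- out$recipient_id
  if (!"stage" %in% names(out)) out$stage <- "primary"
  if (!"age_group" %in% names(out)) out$age_group <- "unknown"
  if (!"fraction" %in% names(out)) out$fraction <- "unknown"
  if (!"censored_week" %in% names(out)) out$censored_week <- NA_real_

  pct <- compute_chimerism(out$donor_events, out$total_events)
  if ("percent" %in% names(out)) {
    mism <- !is.na(out$percent) & abs(out$percent - pct) > 1e-6
    if (any(mism)) {
      warn(paste0(sum(mism), " row(s) with percent inconsistent with counts; ",
                  "counts take precedence"))
    }
  }
  out$percent <- pct
  out <- out[chimerism_columns()]
  arrange(out, .data$clone_id, .data$recipient_id, .data$week, .data$lineage)
}
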