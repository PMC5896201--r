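#' Validate a data table against a package schema
#'
#' Checks column presence, types and value ranges of the two table formats
#' the pipeline exchanges and returns a machine-readable list of problems
#' (empty when the table is valid): chimerism tables must have known lineage
#' codes, percents in \[0, 100\], non-negative integer-valued counts with
#' `donor_events <= total_events`, and non-negative weeks; calls tables must
#' carry taxonomy cell types and duration classes.
#'
#' @param x A data frame or a path to a CSV file.
#' @param schema `"chimerism"` or `"calls"`.
#' @return Tibble of errors with columns `row` (NA for table-level
#'   problems), `column`, `message`.
#' @export
validate_table <- function(x, schema = c("chimerism", "calls")) {
  schema <- match.arg(schema)
  if (is.character(x)) {
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  x <- as_tibble(x)
  errs <- list()
  add <- function(row, column, message) {
    errs[[length(errs) + 1]] <<- tibble(row = as.integer(row),
                                        column = column, message = message)
  }
  required <- if (schema == "chimerism") {
    chimerism_columns()
  } else {
    c("clone_id", "age_group", "fraction", "lineages_primary",
      "lineages_secondary_union", "duration_class", "cell_type", "latent")
  }
  missing <- setdiff(required, names(x))
  for (m in missing) add(NA, m, "required column missing")
  if (length(missing) > 0) return(bind_rows(errs))

  flag_rows <- function(bad, column, message) {
    for (r in which(bad)) add(r, column, message)
  }
  if (schema == "chimerism") {
    flag_rows(!x$lineage %in% .lineages, "lineage", "unknown lineage code")
    flag_rows(!x$stage %in% c("primary", "secondary"), "stage",
              "stage must be primary or secondary")
    flag_rows(!is.na(x$week) & x$week < 0, "week", "week must be >= 0")
    pct_bad <- !is.na(x$percent) & (x$percent < 0 | x$percent > 100)
    flag_rows(pct_bad, "percent", "percent must lie in [0, 100]")
    cnt <- !is.na(x$donor_events) & !is.na(x$total_events)
    flag_rows(cnt & x$total_events < 1, "total_events",
              "total_events must be >= 1")
    flag_rows(cnt & x$donor_events < 0, "donor_events",
              "donor_events must be >= 0")
    flag_rows(cnt & x$donor_events > x$total_events, "donor_events",
              "donor_events exceeds total_events")
  } else {
    flag_rows(!x$cell_type %in% .cell_types, "cell_type",
              "cell type outside the taxonomy")
    flag_rows(!x$duration_class %in% c("none", "ST", "IT", "LT"),
              "duration_class", "duration_class must be none/ST/IT/LT")
  }
  if (length(errs) == 0) {
    tibble(row = integer(), column = character(), message = character())
  } else {
    bind_rows(errs)
  }
}

stop_on_table_errors <- function(errs, what) {
  if (nrow(errs) > 0) {
    first <- errs[1, ]
    abort(paste0("invalid ", what, " table (", nrow(errs), " problem(s)); ",
                 "first: row ", first$row, ", column ", first$column, ": ",
                 first$message), class = "hsclone_schema_error")
  }
  invisible(NULL)
}

#' Read and write the long-format chimerism CSV
#'
#' The on-disk format is a UTF-8 CSV with header and fixed column order:
#' `clone_id, recipient_id, stage, age_group, fraction, week, lineage,
#' donor_events, total_events, percent, censored_week`. On read the table is
#' schema-validated; when counts are present the percent is recomputed from
#' them (counts win; mismatches beyond 1e-6 percent raise a warning).
#'
#' @param x Chimerism tibble (for writing).
#' @param path File path.
#' @return `read_chimerism()` returns the validated tibble;
#'   `write_chimerism()` returns `path` invisibly.
#' @export
write_chimerism <- function(x, path) {
  readr::write_csv(x[chimerism_columns()], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_chimerism
#' @export
read_chimerism <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         clone_id = "c", recipient_id = "c", stage = "c",
                         age_group = "c", fraction = "c", week = "d",
                         lineage = "c", donor_events = "d",
                         total_events = "d", percent = "d",
                         censored_week = "d"))
  stop_on_table_errors(validate_table(x, "chimerism"), "chimerism")
  cnt <- !is.na(x$donor_events) & !is.na(x$total_events)
  if (any(cnt)) {
    pct <- compute_chimerism(x$donor_events[cnt], x$total_events[cnt])
    mism <- !is.na(x$percent[cnt]) & abs(x$percent[cnt] - pct) > 1e-6
    if (any(mism)) {
      warn(paste0(sum(mism), " row(s) with percent inconsistent with counts; ",
                  "counts take precedence"))
    }
    x$percent[cnt] <- pct
  }
  x
}

#' Read and write the clone-calls CSV
#'
#' @param x Calls tibble from [classify_cohort()] (for writing).
#' @param path File path.
#' @return `read_calls()` returns the validated tibble; `write_calls()`
#'   returns `path` invisibly.
#' @export
write_calls <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         clone_id = "c", age_group = "c", fraction = "c",
                         lineages_primary = "c",
                         lineages_secondary_union = "c",
                         duration_class = "c", cell_type = "c",
                         latent = "l"))
  x$lineages_primary[is.na(x$lineages_primary)] <- ""
  stop_on_table_errors(validate_table(x, "calls"), "calls")
  x
}

#' Write a simulated cohort to disk
#'
#' Writes the observation table to `<dir>/chimerism.csv` and the truth
#' sidecar (clone metadata incl. true archetype labels) to
#' `<dir>/clones.csv`.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hsclone_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_chimerism(cohort$chimerism, file.path(dir, "chimerism.csv"))
  readr::write_csv(cohort$clones, file.path(dir, "clones.csv"),
                   progress = FALSE)
  invisible(dir)
}

# ---- structured config -----------------------------------------------------

criteria_to_list <- function(criteria) unclass(criteria)

criteria_from_list <- function(x) {
  known <- names(formals(classification_criteria))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown criteria key(s): ", paste(unknown, collapse = ", ")),
          class = "hsclone_config_error")
  }
  do.call(classification_criteria, x)
}

freqs_from_list <- function(x, age_group) {
  unknown <- setdiff(names(x), c("phsc_per_million", "shares"))
  if (length(unknown) > 0) {
    abort(paste0("unknown fraction_frequencies key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "hsclone_config_error")
  }
  fraction_frequencies(age_group, x$phsc_per_million, unlist(x$shares))
}

#' Serialize a scenario to (and from) a YAML-ready list
#'
#' Scenario presets round-trip through a plain nested list, the structure
#' written by [write_run_config()].
#'
#' @param sc An [scenario()].
#' @param x A list produced by `scenario_to_config()` (or parsed from YAML).
#' @return `scenario_to_config()` a list; `scenario_from_config()` an
#'   [scenario()].
#' @export
scenario_to_config <- function(sc) {
  validate_scenario(sc)
  list(
    age_group = sc$age_group,
    fraction_mixtures = lapply(sc$fraction_mixtures, as.list),
    fraction_frequencies = list(
      phsc_per_million = sc$fraction_frequencies$phsc_per_million,
      shares = as.list(sc$fraction_frequencies$shares)),
    archetypes = lapply(sc$archetypes, function(a) {
      lapply(unclass(a), function(v) if (is.numeric(v)) as.list(v) else v)
    }),
    death_probability = sc$death_probability,
    n_secondaries_range = as.list(sc$n_secondaries_range),
    gate_size_ranges = lapply(sc$gate_size_ranges, as.list),
    timepoints_primary = as.list(sc$timepoints_primary),
    timepoints_secondary = as.list(sc$timepoints_secondary),
    plateau_jitter_sd = sc$plateau_jitter_sd
  )
}

#' @rdname scenario_to_config
#' @export
scenario_from_config <- function(x) {
  num <- function(v) as.numeric(unlist(v))
  archetypes <- lapply(x$archetypes, function(a) {
    archetype_spec(
      label = a$label, plateau = num(a$plateau),
      onset_week = num(a$onset_week), rise_rate = num(a$rise_rate),
      decay_start_week = num(a$decay_start_week),
      decay_rate = num(a$decay_rate),
      engraft_probability = num(a$engraft_probability),
      secondary_plateau = num(a$secondary_plateau),
      secondary_onset_week = num(a$secondary_onset_week),
      secondary_rise_rate = num(a$secondary_rise_rate))
  })
  names(archetypes) <- vapply(archetypes, `[[`, character(1), "label")
  scenario(
    age_group = x$age_group,
    fraction_mixtures = lapply(x$fraction_mixtures, unlist),
    fraction_frequencies = freqs_from_list(x$fraction_frequencies,
                                           x$age_group),
    archetypes = archetypes,
    death_probability = num(x$death_probability),
    n_secondaries_range = num(x$n_secondaries_range),
    gate_size_ranges = lapply(x$gate_size_ranges, num),
    timepoints_primary = num(x$timepoints_primary),
    timepoints_secondary = num(x$timepoints_secondary),
    plateau_jitter_sd = num(x$plateau_jitter_sd)
  )
}

#' Read and write the run configuration
#'
#' A single human-editable YAML file drives the pipeline: input/output
#' paths, the classification-criteria block, per-age fraction-frequency
#' blocks, an optional scenario block for simulation, the seed and the log
#' level. Unknown top-level keys are rejected.
#'
#' @param path YAML file path.
#' @param config A run-config list (for writing).
#' @return `read_run_config()` returns the parsed, validated list with
#'   `criteria` realised as [classification_criteria()] and
#'   `fraction_frequencies` as [fraction_frequencies()] per age.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "hsclone_config_error")
  }
  raw <- yaml::read_yaml(path)
  known <- c("paths", "criteria", "fraction_frequencies", "scenario",
             "seed", "log_level")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "hsclone_config_error")
  }
  out <- raw
  out$criteria <- if (is.null(raw$criteria)) classification_criteria()
                  else criteria_from_list(raw$criteria)
  if (!is.null(raw$fraction_frequencies)) {
    out$fraction_frequencies <- lapply(
      names(raw$fraction_frequencies),
      function(age) freqs_from_list(raw$fraction_frequencies[[age]], age))
    names(out$fraction_frequencies) <- names(raw$fraction_frequencies)
  }
  if (!is.null(raw$scenario)) out$scenario <- scenario_from_config(raw$scenario)
  if (!is.null(raw$seed)) {
    if (raw$seed < 0 || raw$seed != as.integer(raw$seed)) {
      abort("seed must be a nonnegative integer",
            class = "hsclone_config_error")
    }
    out$seed <- as.integer(raw$seed)
  }
  out
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  cfg <- config
  if (inherits(cfg$criteria, "hsclone_criteria")) {
    cfg$criteria <- criteria_to_list(cfg$criteria)
  }
  if (!is.null(cfg$fraction_frequencies)) {
    cfg$fraction_frequencies <- lapply(cfg$fraction_frequencies, function(ff) {
      if (inherits(ff, "hsclone_fraction_frequencies")) {
        list(phsc_per_million = ff$phsc_per_million,
             shares = as.list(ff$shares))
      } else ff
    })
  }
  if (inherits(cfg$scenario, "hsclone_scenario")) {
    cfg$scenario <- scenario_to_config(cfg$scenario)
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

# ---- report ----------------------------------------------------------------

#' Write the estimation report
#'
#' Writes the frequency table (rows = cell types, columns = young, aged,
#' fold) as TSV, the within-pHSC composition as TSV, and a short markdown
#' report summarising inputs, criteria and headline numbers.
#'
#' @param freq_table A [compartment_table()] tibble.
#' @param young_est,aged_est The two [estimate_per_million()] objects.
#' @param dir Output directory (created if needed).
#' @param criteria Criteria used for classification (echoed in the report).
#' @return `dir`, invisibly.
#' @export
write_report <- function(freq_table, young_est, aged_est, dir,
                         criteria = classification_criteria()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- freq_table
  tab$fold <- format_fold(tab$fold)
  readr::write_tsv(tab, file.path(dir, "frequencies_per_million.tsv"),
                   progress = FALSE)
  comp <- tibble(cell_type = young_est$cell_type,
                 young = young_est$composition,
                 aged = aged_est$composition[match(young_est$cell_type,
                                                   aged_est$cell_type)])
  readr::write_tsv(comp, file.path(dir, "composition_within_phsc.tsv"),
                   progress = FALSE)
  lines <- c(
    "# Compartment estimation report", "",
    paste0("- threshold (percent): ", criteria$threshold_percent),
    paste0("- min donor events: ", criteria$min_donor_events),
    paste0("- terminal week: ", criteria$terminal_week),
    paste0("- young pHSC per 10^6 BM: ",
           attr(young_est, "phsc_per_million"),
           " (fraction shares cover ",
           signif(100 * attr(young_est, "share_total"), 4), "%)"),
    paste0("- aged pHSC per 10^6 BM: ", attr(aged_est, "phsc_per_million"),
           " (fraction shares cover ",
           signif(100 * attr(aged_est, "share_total"), 4), "%)"),
    paste0("- total per-million young/aged: ",
           signif(sum(freq_table$young), 6), " / ",
           signif(sum(freq_table$aged), 6)),
    "", "See frequencies_per_million.tsv and composition_within_phsc.tsv."
  )
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}
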