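#' Sorting-fraction frequencies of the phenotypic HSC compartment
#'
#' The phenotypic HSC (pHSC) compartment is the CD34-/low KSL bone-marrow
#' population; its abundance is expressed per million nucleated BM cells.
#' Fractions F1 (CD150+CD41-), F2 (CD150+CD41+) and F3 (CD150-CD41-) are the
#' sorted subsets single cells are transplanted from; their shares may sum to
#' less than 1 (the CD150-CD41+ quadrant is not assayed).
#'
#' @param age_group `"young"` or `"aged"` (free text allowed).
#' @param phsc_per_million pHSC cells per 10^6 nucleated BM cells (> 0).
#' @param shares Named numeric `c(F1 = ..., F2 = ..., F3 = ...)`, each in
#'   \[0, 1\], summing to at most 1.
#' @return An object of class `hsclone_fraction_frequencies`.
#' @export
fraction_frequencies <- function(age_group, phsc_per_million, shares) {
  if (phsc_per_million <= 0) abort("phsc_per_million must be > 0")
  if (!all(.fractions %in% names(shares))) {
    abort("shares must be named with F1, F2, F3")
  }
  shares <- shares[.fractions]
  if (any(shares < 0 | shares > 1)) abort("each share must lie in [0, 1]")
  if (sum(shares) > 1 + 1e-9) abort("shares must sum to at most 1")
  structure(list(age_group = age_group,
                 phsc_per_million = as.numeric(phsc_per_million),
                 shares = shares),
            class = "hsclone_fraction_frequencies")
}

#' @export
print.hsclone_fraction_frequencies <- function(x, ...) {
  cat("<fraction_frequencies>", x$age_group, "| pHSC per 10^6 BM:",
      x$phsc_per_million, "| shares:",
      paste0(names(x$shares), "=", signif(x$shares, 3), collapse = " "), "\n")
  invisible(x)
}

#' Define a simulation scenario
#'
#' A scenario bundles everything needed to simulate a single-cell
#' transplantation cohort for one age group: the archetype library, the
#' per-fraction mixture over archetypes, the fraction frequencies, the
#' recipient death probability, the secondary-transplant design and the
#' gate-size ranges of the flow-cytometry readout.
#'
#' @param age_group `"young"` or `"aged"`.
#' @param fraction_mixtures Named list (`F1`, `F2`, `F3`), each a named
#'   probability vector over archetype labels summing to 1 (tolerance 1e-9).
#' @param fraction_frequencies A [fraction_frequencies()] object.
#' @param archetypes Named list of [archetype_spec()] covering every label
#'   used in the mixtures.
#' @param death_probability Per-primary-recipient probability of dying during
#'   follow-up (default 30/451, the observed study rate); dead recipients are
#'   censored at a uniformly drawn observed timepoint and excluded from
#'   classification.
#' @param n_secondaries_range Integer range of secondary recipients per
#'   eligible primary (default 1-5).
#' @param gate_size_ranges Named list of `c(min, max)` event counts for the
#'   `leukocyte`, `platelet` and `erythrocyte` gate classes. Defaults:
#'   30,000-50,000 leukocytes, 20,000-50,000 platelets, a fixed 500,000
#'   erythrocytes.
#' @param timepoints_primary,timepoints_secondary Observation weeks. Defaults
#'   2,3,4,8,12,16,20,24 (primary) and 4,12,16,20,21 (secondary; the late
#'   21-22-week window is encoded as 21).
#' @param plateau_jitter_sd Log-scale SD of the per-clone plateau multiplier
#'   (default 0.5).
#' @return An object of class `hsclone_scenario`.
#' @export
scenario <- function(age_group,
                     fraction_mixtures,
                     fraction_frequencies,
                     archetypes = default_archetypes(),
                     death_probability = 30 / 451,
                     n_secondaries_range = c(1L, 5L),
                     gate_size_ranges = list(leukocyte = c(30000, 50000),
                                             platelet = c(20000, 50000),
                                             erythrocyte = c(500000, 500000)),
                     timepoints_primary = c(2, 3, 4, 8, 12, 16, 20, 24),
                     timepoints_secondary = c(4, 12, 16, 20, 21),
                     plateau_jitter_sd = 0.5) {
  sc <- structure(list(
    age_group = age_group,
    fraction_mixtures = fraction_mixtures,
    fraction_frequencies = fraction_frequencies,
    archetypes = archetypes,
    death_probability = death_probability,
    n_secondaries_range = as.integer(n_secondaries_range),
    gate_size_ranges = gate_size_ranges,
    timepoints_primary = timepoints_primary,
    timepoints_secondary = timepoints_secondary,
    plateau_jitter_sd = plateau_jitter_sd
  ), class = "hsclone_scenario")
  validate_scenario(sc)
  sc
}

#' Validate a scenario
#'
#' @param sc An `hsclone_scenario`.
#' @return `sc`, invisibly; aborts with a message on the first violated
#'   invariant (mixtures not summing to 1, unknown archetype labels, invalid
#'   death probability or gate ranges).
#' @export
validate_scenario <- function(sc) {
  if (!inherits(sc, "hsclone_scenario")) abort("not an hsclone_scenario")
  if (!all(.fractions %in% names(sc$fraction_mixtures))) {
    abort("fraction_mixtures must contain F1, F2 and F3")
  }
  for (f in .fractions) {
    mix <- sc$fraction_mixtures[[f]]
    if (abs(sum(mix) - 1) > 1e-9) {
      abort(paste0("mixture for ", f, " must sum to 1 (got ", sum(mix), ")"))
    }
    if (any(mix < 0)) abort(paste0("mixture for ", f, " has negative weights"))
    unknown <- setdiff(names(mix), names(sc$archetypes))
    if (length(unknown) > 0) {
      abort(paste0("mixture for ", f, " references unknown archetypes: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  if (!inherits(sc$fraction_frequencies, "hsclone_fraction_frequencies")) {
    abort("fraction_frequencies must be built with fraction_frequencies()")
  }
  if (sc$death_probability < 0 || sc$death_probability >= 1) {
    abort("death_probability must lie in [0, 1)")
  }
  if (length(sc$n_secondaries_range) != 2 ||
      sc$n_secondaries_range[1] < 1 ||
      sc$n_secondaries_range[1] > sc$n_secondaries_range[2]) {
    abort("n_secondaries_range must be an increasing integer range >= 1")
  }
  for (g in c("leukocyte", "platelet", "erythrocyte")) {
    r <- sc$gate_size_ranges[[g]]
    if (is.null(r) || length(r) != 2 || r[1] < 1 || r[1] > r[2]) {
      abort(paste0("gate_size_ranges$", g, " must be a valid c(min, max)"))
    }
  }
  if (length(sc$timepoints_primary) == 0 || any(diff(sc$timepoints_primary) <= 0)) {
    abort("timepoints_primary must be strictly increasing")
  }
  if (length(sc$timepoints_secondary) == 0 || any(diff(sc$timepoints_secondary) <= 0)) {
    abort("timepoints_secondary must be strictly increasing")
  }
  invisible(sc)
}

#' @export
print.hsclone_scenario <- function(x, ...) {
  cat("<hsclone_scenario>", x$age_group, "\n")
  print(x$fraction_frequencies)
  cat("  death_probability:", signif(x$death_probability, 4),
      "| secondaries per primary:", paste(x$n_secondaries_range, collapse = "-"),
      "\n")
  invisible(x)
}

# Published per-10^6-BM-cell frequencies of each functional cell type in
# young and aged marrow; the presets are constructed so their expected
# frequencies equal these columns.
reference_frequencies <- function() {
  tibble(
    cell_type = c("LT-HSC", "IT-HSC", "ST-HSC", "latent-HSC",
                  "LT-CMSC", "IT-CMSC", "ST-CMRP",
                  "LT-MESC", "IT-MESC", "ST-MERP",
                  "LT-MkSC", "IT-MkSC", "ST-MkRP",
                  "other", "non-reconstituting"),
    young = c(7.3, 5.6, 10.8, 0.0, 0.3, 1.7, 9.2, 0.3, 0.3, 1.3,
              0.0, 1.2, 6.7, 2.3, 20.3),
    aged  = c(21.0, 49.9, 52.4, 2.0, 0.0, 34.2, 75.1, 0.0, 9.1, 19.1,
              0.0, 20.4, 35.1, 10.8, 316.0)
  )
}

#' Young and aged cohort presets
#'
#' Returns the two built-in scenarios that emulate the published study
#' conditions: total pHSC abundance and within-compartment composition are
#' set so each preset's *expected* cell-type frequencies per 10^6 BM cells
#' equal the published estimates by construction (young total 67.3, aged
#' total 645.1 per 10^6 BM cells; the aged/young ratio is the ~10-fold
#' compartment expansion). Latent-HSC probability mass is confined to the
#' aged F2 (CD150+CD41+) fraction, where all latent clones were observed;
#' the compensating mass is taken from non-reconstituting cells so every
#' fraction mixture still sums to 1 and expectations are unchanged.
#'
#' @return Named list with elements `young` and `aged`, each an
#'   [scenario()] object.
#' @export
aging_scenarios <- function() {
  ref <- reference_frequencies()
  arch <- default_archetypes()
  shares <- list(
    young = c(F1 = 0.45, F2 = 0.15, F3 = 0.40),
    aged  = c(F1 = 0.15, F2 = 0.60, F3 = 0.25)
  )
  build <- function(age) {
    freq <- ref[[age]]
    total <- sum(freq)
    pi <- stats::setNames(freq / total, ref$cell_type)
    s <- shares[[age]]
    mix <- lapply(.fractions, function(f) pi)
    names(mix) <- .fractions
    # confine latent-HSCs to F2, compensating within non-reconstituting so
    # column sums and compartment-wide expectations are preserved exactly
    p_lat <- pi[["latent-HSC"]]
    if (p_lat > 0) {
      for (f in c("F1", "F3")) {
        mix[[f]][["latent-HSC"]] <- 0
        mix[[f]][["non-reconstituting"]] <-
          mix[[f]][["non-reconstituting"]] + p_lat
      }
      mix$F2[["latent-HSC"]] <- p_lat / s[["F2"]]
      mix$F2[["non-reconstituting"]] <-
        mix$F2[["non-reconstituting"]] - p_lat * (1 - s[["F2"]]) / s[["F2"]]
    }
    scenario(
      age_group = age,
      fraction_mixtures = mix,
      fraction_frequencies = fraction_frequencies(age, total, s),
      archetypes = arch
    )
  }
  list(young = build("young"), aged = build("aged"))
}

#' Expected cell-type frequencies of a scenario
#'
#' The frequency of cell type *t* per 10^6 BM cells implied by a scenario is
#' `N * sum_f s_f * p(t | f)`, with `N` the pHSC abundance, `s_f` the
#' fraction shares and `p(t | f)` the mixture weights. For the built-in
#' presets these equal the published estimates exactly.
#'
#' @param sc An [scenario()].
#' @return Tibble with columns `cell_type` and `per_million`.
#' @export
scenario_expected_frequencies <- function(sc) {
  validate_scenario(sc)
  ff <- sc$fraction_frequencies
  labels <- unique(unlist(lapply(sc$fraction_mixtures, names)))
  per_million <- vapply(labels, function(t) {
    ff$phsc_per_million * sum(vapply(.fractions, function(f) {
      mix <- sc$fraction_mixtures[[f]]
      w <- if (t %in% names(mix)) mix[[t]] else 0
      ff$shares[[f]] * w
    }, numeric(1)))
  }, numeric(1))
  tibble(cell_type = labels, per_million = unname(per_million))
}
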