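#' Per-fraction cell-type composition of classified clones
#'
#' Counts classified clones by sorting fraction and cell type and converts
#' counts to within-fraction proportions `p(t | f) = n_tf / n_f`. Every
#' taxonomy label appears in each fraction, with zero counts where unseen.
#' Clones outside the requested fractions (e.g. bulk CD34-KSL transplants
#' with unknown fraction) are ignored here; they can still be summarised
#' with plain counts.
#'
#' @param calls A [classify_cohort()] table.
#' @param fractions Fractions to tabulate (default F1, F2, F3). A fraction
#'   with no clones raises an error naming it.
#' @param types Cell-type levels (default [cell_types()]).
#' @return Tibble with columns `fraction`, `cell_type`, `n`, `p`.
#' @export
composition <- function(calls, fractions = .fractions, types = .cell_types) {
  calls <- calls[calls$fraction %in% fractions, , drop = FALSE]
  extra <- setdiff(unique(calls$cell_type), types)
  if (length(extra) > 0) {
    abort(paste0("cell type(s) outside the taxonomy: ",
                 paste(extra, collapse = ", ")))
  }
  counts <- table(factor(calls$fraction, levels = fractions),
                  factor(calls$cell_type, levels = types))
  n_f <- rowSums(counts)
  empty <- fractions[n_f == 0]
  if (length(empty) > 0) {
    abort(paste0("no classified clones in fraction(s): ",
                 paste(empty, collapse = ", ")))
  }
  out <- as_tibble(as.data.frame(counts, stringsAsFactors = FALSE))
  names(out) <- c("fraction", "cell_type", "n")
  out$n <- as.integer(out$n)
  out <- out %>%
    group_by(.data$fraction) %>%
    mutate(p = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    arrange(match(.data$fraction, fractions), match(.data$cell_type, types))
  out
}

#' Absolute cell-type frequencies per million BM cells
#'
#' Combines within-fraction compositions with fraction frequencies: the
#' frequency of cell type *t* per 10^6 BM cells is
#' `F_t = N * sum_f s_f * p(t | f)` where `N` is the pHSC abundance per 10^6
#' BM cells and `s_f` the share of fraction *f* within the pHSC compartment.
#' The within-pHSC composition is `pi_t = F_t / (N * sum_f s_f)`. By
#' construction `sum_t F_t = N * (s_F1 + s_F2 + s_F3)` exactly (equal to `N`
#' when the shares cover the whole compartment).
#'
#' @param comp A [composition()] table.
#' @param freqs A [fraction_frequencies()] object.
#' @return An `hsclone_estimate`: tibble with `cell_type`, `per_million`
#'   (`F_t`) and `composition` (`pi_t`), with `age_group`, `phsc_per_million`
#'   and `share_total` attached as attributes.
#' @export
estimate_per_million <- function(comp, freqs) {
  if (!inherits(freqs, "hsclone_fraction_frequencies")) {
    abort("freqs must be built with fraction_frequencies()")
  }
  have <- sort(unique(comp$fraction))
  if (!setequal(have, .fractions)) {
    abort(paste0("composition must cover exactly F1, F2, F3; got: ",
                 paste(have, collapse = ", ")))
  }
  N <- freqs$phsc_per_million
  s <- freqs$shares
  types <- unique(comp$cell_type)
  wide <- tidyr::pivot_wider(comp[c("fraction", "cell_type", "p")],
                             names_from = "fraction", values_from = "p")
  F_t <- N * (s[["F1"]] * wide$F1 + s[["F2"]] * wide$F2 + s[["F3"]] * wide$F3)
  out <- tibble(cell_type = wide$cell_type,
                per_million = F_t,
                composition = F_t / (N * sum(s)))
  out <- out[match(types, out$cell_type), ]
  structure(out, class = c("hsclone_estimate", class(tibble())),
            age_group = freqs$age_group,
            phsc_per_million = N, share_total = sum(s))
}

# round half away from zero to `digits` decimals (the convention of the
# published fold-change column; base round() is half-to-even)
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Age-related fold change
#'
#' `aged / young`, rounded half-away-from-zero to one decimal. Undefined
#' (returns `NA`) when the young frequency is zero; report writers render
#' such entries as `"n/a"` (see [format_fold()]).
#'
#' @param young,aged Non-negative frequencies (vectorised).
#' @return Numeric fold changes (NA where young = 0).
#' @examples
#' fold_change(7.3, 21.0) # 2.9
#' @export
fold_change <- function(young, aged) {
  if (any(young < 0) || any(aged < 0)) abort("frequencies must be >= 0")
  n <- max(length(young), length(aged))
  young <- rep_len(young, n); aged <- rep_len(aged, n)
  ifelse(young == 0, NA_real_, round_half_away(aged / young, 1))
}

#' Render fold changes for reports
#'
#' @param fold Numeric vector from [fold_change()].
#' @return Character vector; `NA` becomes `"n/a"`.
#' @export
format_fold <- function(fold) {
  ifelse(is.na(fold), "n/a", format(fold, trim = TRUE, nsmall = 1))
}

#' Grouped frequencies and fold changes
#'
#' Sums per-cell-type frequencies into named groups (e.g. all HSC duration
#' classes, or the ST myeloid-restricted progenitors) and recomputes the
#' fold change on the group totals.
#'
#' @param freq_table Tibble with columns `cell_type`, `young`, `aged`.
#' @param grouping Named list mapping group name -> member cell-type labels;
#'   each label may belong to at most one group, and unknown labels raise an
#'   error.
#' @return Tibble with `group`, `young`, `aged`, `fold`.
#' @examples
#' ref <- data.frame(cell_type = c("LT-HSC", "IT-HSC", "ST-HSC"),
#'                   young = c(7.3, 5.6, 10.8), aged = c(21.0, 49.9, 52.4))
#' aggregate_groups(ref, list(HSC = c("LT-HSC", "IT-HSC", "ST-HSC")))
#' @export
aggregate_groups <- function(freq_table, grouping) {
  members <- unlist(grouping, use.names = FALSE)
  unknown <- setdiff(members, freq_table$cell_type)
  if (length(unknown) > 0) {
    abort(paste0("grouping references unknown row label(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(members) > 0) {
    abort("each row label may belong to at most one group")
  }
  rows <- lapply(names(grouping), function(g) {
    sel <- freq_table$cell_type %in% grouping[[g]]
    tibble(group = g,
           young = sum(freq_table$young[sel]),
           aged = sum(freq_table$aged[sel]))
  })
  out <- bind_rows(rows)
  out$fold <- fold_change(out$young, out$aged)
  out
}

#' Bootstrap confidence intervals for per-million frequencies
#'
#' Resamples clones with replacement within each sorting fraction
#' (multinomially over cell types, preserving the per-fraction sample
#' sizes), recomputes every `F_t` per replicate and returns percentile
#' intervals.
#'
#' @param calls A [classify_cohort()] table.
#' @param freqs A [fraction_frequencies()] object.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed (draws are deterministic given it).
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Tibble with `cell_type`, `per_million`, `lower`, `upper`; the
#'   attribute `unreliable_fractions` names fractions with fewer than 2
#'   clones (intervals there are flagged, not suppressed).
#' @export
bootstrap_ci <- function(calls, freqs, B = 1000, seed = 1L, level = 0.95) {
  if (B < 100) abort("B must be >= 100")
  if (level <= 0 || level >= 1) abort("level must lie in (0, 1)")
  comp <- composition(calls)
  est <- estimate_per_million(comp, freqs)
  N <- freqs$phsc_per_million
  s <- freqs$shares
  types <- unique(comp$cell_type)
  n_f <- vapply(.fractions,
                function(f) sum(comp$n[comp$fraction == f]), numeric(1))
  unreliable <- .fractions[n_f < 2]

  boot_F <- withr::with_seed(seed, {
    acc <- matrix(0, nrow = length(types), ncol = B)
    for (f in .fractions) {
      p_f <- comp$p[comp$fraction == f][match(types,
                                              comp$cell_type[comp$fraction == f])]
      draws <- rmultinom(B, size = n_f[[f]], prob = p_f)
      acc <- acc + N * s[[f]] * draws / n_f[[f]]
    }
    acc
  })
  alpha <- (1 - level) / 2
  qs <- apply(boot_F, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  out <- tibble(cell_type = types,
                per_million = est$per_million[match(types, est$cell_type)],
                lower = qs[1, ], upper = qs[2, ])
  attr(out, "unreliable_fractions") <- unreliable
  attr(out, "B") <- B
  attr(out, "level") <- level
  out
}

#' Chi-square test comparing two compositions
#'
#' Pearson chi-square test of homogeneity on the 2 x k table of young versus
#' aged cell-type counts. Categories empty in both groups are dropped first,
#' so the degrees of freedom are `k - 1` over the remaining categories.
#'
#' @param young_counts,aged_counts Non-negative count vectors over the same
#'   categories (aligned by names when named, else by position).
#' @return List with `statistic`, `df` and `p_value`.
#' @export
composition_chisq <- function(young_counts, aged_counts) {
  if (!is.null(names(young_counts)) && !is.null(names(aged_counts))) {
    if (!setequal(names(young_counts), names(aged_counts))) {
      abort("count vectors must cover the same categories")
    }
    aged_counts <- aged_counts[names(young_counts)]
  } else if (length(young_counts) != length(aged_counts)) {
    abort("count vectors must have the same length")
  }
  if (any(young_counts < 0) || any(aged_counts < 0)) {
    abort("counts must be non-negative")
  }
  if (sum(young_counts) == 0 || sum(aged_counts) == 0) {
    abort("each group must have a positive total count")
  }
  keep <- young_counts + aged_counts > 0
  tab <- rbind(young = young_counts[keep], aged = aged_counts[keep])
  if (ncol(tab) < 2) {
    return(list(statistic = 0, df = 0L, p_value = 1))
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Side-by-side frequency table with fold changes
#'
#' Joins a young and an aged [estimate_per_million()] result into the
#' standard report table: one row per cell type with the two per-million
#' frequencies and the age-related fold change.
#'
#' @param young_est,aged_est `hsclone_estimate` objects.
#' @return Tibble with `cell_type`, `young`, `aged`, `fold`.
#' @export
compartment_table <- function(young_est, aged_est) {
  types <- union(young_est$cell_type, aged_est$cell_type)
  young <- young_est$per_million[match(types, young_est$cell_type)]
  aged <- aged_est$per_million[match(types, aged_est$cell_type)]
  young[is.na(young)] <- 0
  aged[is.na(aged)] <- 0
  tibble(cell_type = types, young = young, aged = aged,
         fold = fold_change(young, aged))
}
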