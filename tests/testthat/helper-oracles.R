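# Independent brute-force re-implementations used as oracles. These stay
# deliberately naive (explicit loops over clones, weeks and lineages) and
# share no code with the package internals they check.

oracle_classify <- function(chim, tau = 0.005, min_pts = 1, min_events = 2,
                            terminal_week = 24, lt_week = 16,
                            all_five = FALSE) {
  lineages <- c("nm", "E", "P", "B", "T")
  dead <- unique(chim$clone_id[!is.na(chim$censored_week)])
  ids <- sort(setdiff(unique(chim$clone_id), dead))
  out <- list()
  for (id in ids) {
    d <- chim[chim$clone_id == id, ]
    prim <- d[d$stage == "primary", ]
    sec <- d[d$stage == "secondary", ]
    ok <- function(rows) {
      hit <- rows$percent >= tau
      has_counts <- !is.na(rows$donor_events)
      hit[has_counts] <- hit[has_counts] &
        rows$donor_events[has_counts] >= min_events
      hit
    }
    lin <- character(0)
    for (l in lineages) {
      if (sum(ok(prim[prim$lineage == l, ])) >= min_pts) lin <- c(lin, l)
    }
    term <- prim[prim$week == terminal_week, ]
    terminal_pos <- nrow(term) > 0 && any(ok(term))
    sec_lin <- character(0)
    for (r in unique(sec$recipient_id)) {
      for (l in lineages) {
        rows <- sec[sec$recipient_id == r & sec$lineage == l, ]
        if (sum(ok(rows)) >= min_pts) sec_lin <- union(sec_lin, l)
      }
    }
    late <- sec[sec$week >= lt_week, ]
    lt_evidence <- nrow(late) > 0 && any(ok(late))
    dur <- if (length(lin) == 0) "none"
           else if (!terminal_pos) "ST"
           else if (lt_evidence) "LT"
           else "IT"
    myeloid_only <- length(lin) > 0 && all(lin %in% c("nm", "E", "P"))
    is_hsc <- if (all_five) setequal(lin, lineages)
              else all(c("nm", "E", "P") %in% lin) && any(c("B", "T") %in% lin)
    ct <- if (length(lin) == 0) "non-reconstituting"
          else if (is_hsc) paste0(dur, "-HSC")
          else if (setequal(lin, "P"))
            paste0(dur, "-Mk", if (dur == "ST") "RP" else "SC")
          else if (setequal(lin, c("E", "P")))
            paste0(dur, "-ME", if (dur == "ST") "RP" else "SC")
          else if (setequal(lin, c("nm", "E", "P")))
            paste0(dur, "-CM", if (dur == "ST") "RP" else "SC")
          else "other"
    latent <- nrow(sec) > 0 && myeloid_only && dur %in% c("IT", "LT") &&
      any(c("B", "T") %in% sec_lin)
    if (latent) ct <- "latent-HSC"
    out[[id]] <- tibble::tibble(
      clone_id = id,
      lineages_primary = paste(lineages[lineages %in% lin], collapse = "+"),
      duration_class = dur, cell_type = ct, latent = latent
    )
  }
  dplyr::bind_rows(out)
}

# per-clone weight sum: each classified clone of fraction f contributes
# N * s_f / n_f to its own cell type's per-million frequency
oracle_per_million <- function(calls, N, shares, types) {
  out <- stats::setNames(rep(0, length(types)), types)
  for (f in c("F1", "F2", "F3")) {
    rows <- calls[calls$fraction == f, ]
    n_f <- nrow(rows)
    for (i in seq_len(n_f)) {
      t <- rows$cell_type[i]
      out[t] <- out[t] + N * shares[[f]] / n_f
    }
  }
  out
}

# closed-form Pearson statistic on a 2 x k table
oracle_pearson <- function(y, a) {
  tab <- rbind(y, a)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(statistic = sum((tab - expd)^2 / expd),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}
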