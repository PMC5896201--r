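crit <- classification_criteria()

test_that("lineage positivity applies the threshold and the event guard", {
  s <- series_rows("c1", c(2, 3, 4, 8, 16, 24),
                   list(P = c(0, 0, 0, 0.8, 0.8, 0.8), nm = 0, E = 0,
                        B = 0, T = 0))
  expect_equal(lineage_positivity(s, crit), "P")

  all5 <- series_rows("c2", 24, list(nm = 0.01, E = 0.01, P = 0.01,
                                     B = 0.01, T = 0.01))
  expect_equal(lineage_positivity(all5, crit), c("nm", "E", "P", "B", "T"))

  below <- series_rows("c3", c(2, 8, 24), list(P = 0.004))
  expect_length(lineage_positivity(below, crit), 0)

  # 0.005% of a 40,000-event gate is two events; a single event at the same
  # percent is rejected when counts are available
  one_event <- series_rows("c4", 24, list(P = 0.005), gate_size = 40000)
  one_event$donor_events <- 1
  expect_length(lineage_positivity(one_event, crit), 0)
  one_event$donor_events <- 2
  expect_equal(lineage_positivity(one_event, crit), "P")
})

test_that("duration classes follow terminal-week and secondary evidence", {
  early <- series_rows("c1", c(2, 3, 4, 8, 12, 16, 20, 24),
                       list(P = c(1, 1, 1, 1, 0, 0, 0, 0)))
  expect_equal(duration_call(early, criteria = crit)$duration_class, "ST")

  prim <- series_rows("c2", c(2, 3, 4, 8, 12, 16, 20, 24),
                      list(nm = 5, E = 5, P = 5, B = 5, T = 5))
  sec_pos <- series_rows("c2", c(4, 12, 16, 20),
                         list(nm = 2, E = 2, P = 2, B = 2, T = 2),
                         stage = "secondary", recipient_id = "c2-S1")
  expect_equal(duration_call(prim, sec_pos, crit)$duration_class, "LT")

  sec_neg <- series_rows("c2", c(4, 12, 16, 20),
                         list(nm = c(2, 0, 0, 0), E = 0, P = 0, B = 0, T = 0),
                         stage = "secondary", recipient_id = "c2-S1")
  expect_equal(duration_call(prim, sec_neg, crit)$duration_class, "IT")

  unresolved <- duration_call(prim, NULL, crit)
  expect_equal(unresolved$duration_class, "IT")
  expect_true(unresolved$lt_it_unresolved)

  none <- series_rows("c3", c(2, 24), list(P = 0))
  expect_equal(duration_call(none, criteria = crit)$duration_class, "none")
})

test_that("cell-type mapping covers the whole taxonomy", {
  cases <- list(
    list(character(0), "none", "non-reconstituting"),
    list("P", "ST", "ST-MkRP"),
    list("P", "IT", "IT-MkSC"),
    list("P", "LT", "LT-MkSC"),
    list(c("E", "P"), "ST", "ST-MERP"),
    list(c("E", "P"), "IT", "IT-MESC"),
    list(c("E", "P"), "LT", "LT-MESC"),
    list(c("nm", "E", "P"), "ST", "ST-CMRP"),
    list(c("nm", "E", "P"), "IT", "IT-CMSC"),
    list(c("nm", "E", "P"), "LT", "LT-CMSC"),
    list(c("nm", "E", "P", "B"), "LT", "LT-HSC"),
    list(c("nm", "E", "P", "T"), "IT", "IT-HSC"),
    list(c("nm", "E", "P", "B", "T"), "LT", "LT-HSC"),
    list(c("nm", "E", "P", "B", "T"), "ST", "ST-HSC"),
    list("B", "ST", "other"),
    list(c("B", "T"), "IT", "other"),
    list("nm", "IT", "other"),
    list("E", "ST", "other"),
    list(c("nm", "P"), "LT", "other"),
    list(c("P", "B"), "IT", "other")
  )
  for (cs in cases) {
    expect_equal(cell_type_call(cs[[1]], cs[[2]], crit), cs[[3]],
                 label = paste0("{", paste(cs[[1]], collapse = ","), "} ",
                                cs[[2]]))
  }
  strict <- classification_criteria(hsc_requires_all_five = TRUE)
  expect_equal(cell_type_call(c("nm", "E", "P", "B"), "LT", strict), "other")
  expect_equal(cell_type_call(c("nm", "E", "P", "B", "T"), "LT", strict),
               "LT-HSC")
  expect_error(cell_type_call("X", "LT", crit), "unknown lineage")
})

test_that("latent-HSC requires myeloid-restricted persistence plus lymphoid secondary output", {
  expect_true(latent_call("P", "LT", c("nm", "E", "P", "B", "T")))
  expect_false(latent_call(c("nm", "E", "P", "B", "T"), "LT",
                           c("nm", "E", "P", "B", "T")))
  expect_false(latent_call(c("P", "E"), "LT", c("P", "E")))
  expect_false(latent_call("P", "ST", c("B")))
  expect_false(latent_call(character(0), "none", "B"))
  expect_true(latent_call(c("nm", "E", "P"), "IT", "B"))
})

test_that("classify_cohort is empty-safe, order-invariant and validates linkage", {
  empty <- classify_cohort(tibble::tibble())
  expect_equal(nrow(empty), 0)

  co <- simulate_cohort(aging_scenarios()$aged, 40, seed = 6)
  calls <- classify_cohort(co)
  shuffled <- co$chimerism[withr::with_seed(1, sample(nrow(co$chimerism))), ]
  calls2 <- classify_cohort(shuffled)
  expect_equal(as.data.frame(calls), as.data.frame(calls2))

  # every surviving clone receives exactly one taxonomy label
  expect_setequal(calls$clone_id,
                  co$clones$clone_id[!co$clones$dead])
  expect_true(all(calls$cell_type %in% cell_types()))

  orphan <- series_rows("ghost", c(4, 16), list(P = 1), stage = "secondary",
                        recipient_id = "ghost-S1")
  expect_error(classify_cohort(dplyr::bind_rows(co$chimerism, orphan)),
               "without a linked primary")

  # a clone known to the cohort but with no observations and no censor flag
  co$chimerism <- co$chimerism[co$chimerism$clone_id !=
                                 co$clones$clone_id[1], ]
  expect_error(classify_cohort(co), "zero observed timepoints")
})

test_that("classification agrees with the brute-force oracle on small cohorts", {
  presets <- aging_scenarios()
  for (seed in 1:6) {
    sc <- if (seed %% 2 == 0) presets$aged else presets$young
    co <- simulate_cohort(sc, 18, seed = seed)
    calls <- classify_cohort(co)
    ora <- oracle_classify(co$chimerism)
    expect_equal(calls$clone_id, ora$clone_id)
    expect_equal(calls$lineages_primary, ora$lineages_primary)
    expect_equal(calls$duration_class, ora$duration_class)
    expect_equal(calls$cell_type, ora$cell_type)
    expect_equal(calls$latent, ora$latent)
  }
  # and on the noise-free archetype cohort (no counts available)
  nf <- noise_free_cohort()
  calls <- classify_cohort(nf$chimerism)
  ora <- oracle_classify(nf$chimerism)
  expect_equal(calls$cell_type, ora$cell_type)
})

test_that("raising the threshold never enlarges lineage sets", {
  co <- simulate_cohort(aging_scenarios()$aged, 150, seed = 17)
  taus <- c(0.005, 0.02, 0.1, 1)
  runs <- lapply(taus, function(tau) {
    classify_cohort(co, classification_criteria(threshold_percent = tau))
  })
  for (i in seq_len(length(taus) - 1)) {
    lo <- runs[[i]]; hi <- runs[[i + 1]]
    for (j in seq_len(nrow(lo))) {
      set_lo <- strsplit(lo$lineages_primary[j], "+", fixed = TRUE)[[1]]
      set_hi <- strsplit(hi$lineages_primary[j], "+", fixed = TRUE)[[1]]
      expect_true(all(set_hi %in% set_lo))
    }
    # a non-reconstituting clone can never become reconstituting
    expect_true(all(hi$cell_type[lo$cell_type == "non-reconstituting"] ==
                      "non-reconstituting"))
  }
})

test_that("threshold sensitivity reports compositions and agreement", {
  expect_error(threshold_sensitivity(tibble::tibble(), 0.005), "at least two")
  expect_error(threshold_sensitivity(tibble::tibble(), c(-1, 0.1)),
               "positive")

  nf <- noise_free_cohort()
  sens <- threshold_sensitivity(nf$chimerism, c(0.005, 0.1))
  expect_equal(sens$agreement$agreement, 1)

  # a clone plateauing between the two thresholds flips to non-reconstituting
  mid <- series_rows("mid", c(2, 3, 4, 8, 12, 16, 20, 24), list(P = 0.05))
  s2 <- threshold_sensitivity(mid, c(0.005, 0.1))
  comp <- s2$compositions
  expect_equal(comp$n[comp$threshold == 0.005 &
                        comp$cell_type == "non-reconstituting"], 0L)
  expect_equal(comp$n[comp$threshold == 0.1 &
                        comp$cell_type == "non-reconstituting"], 1L)
  expect_equal(s2$agreement$agreement, 0)
})
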