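make_calls <- function(fractions, types, age = "young") {
  tibble::tibble(
    clone_id = sprintf("c%03d", seq_along(fractions)),
    age_group = age, fraction = fractions,
    lineages_primary = "", lineages_secondary_union = NA_character_,
    n_secondaries = 0L, duration_class = "none", cell_type = types,
    latent = FALSE, lt_it_unresolved = FALSE
  )
}

test_that("composition counts and proportions per fraction", {
  calls <- make_calls(rep("F1", 10), c(rep("LT-HSC", 6), rep("ST-MkRP", 4)))
  comp <- composition(calls, fractions = "F1")
  expect_equal(comp$p[comp$cell_type == "LT-HSC"], 0.6)
  expect_equal(comp$p[comp$cell_type == "ST-MkRP"], 0.4)
  expect_equal(sum(comp$p), 1)
  # zero-count types are present with p = 0
  expect_true(all(cell_types() %in% comp$cell_type))

  one <- composition(make_calls(rep(c("F1", "F2", "F3"), 4),
                                rep("IT-HSC", 12)))
  expect_true(all(one$p[one$cell_type == "IT-HSC"] == 1))

  perm <- calls[withr::with_seed(2, sample(nrow(calls))), ]
  expect_equal(composition(perm, fractions = "F1"), comp)

  expect_error(composition(calls), "F2")
})

test_that("per-million estimation does the share-weighted arithmetic", {
  calls <- make_calls(rep(c("F1", "F2", "F3"), each = 4), rep("LT-HSC", 12))
  ff <- fraction_frequencies("young", 100, c(F1 = 0.5, F2 = 0.3, F3 = 0.2))
  est <- estimate_per_million(composition(calls), ff)
  expect_equal(est$per_million[est$cell_type == "LT-HSC"], 100)
  expect_equal(sum(est$per_million), 100)

  # N=100, only F1 carries share 0.5, p(HSC|F1) = 0.2 -> F_HSC = 10
  calls2 <- make_calls(rep(c("F1", "F2", "F3"), each = 10),
                       c(rep("LT-HSC", 2), rep("non-reconstituting", 28)))
  ff2 <- fraction_frequencies("young", 100, c(F1 = 0.5, F2 = 0, F3 = 0))
  est2 <- estimate_per_million(composition(calls2), ff2)
  expect_equal(est2$per_million[est2$cell_type == "LT-HSC"], 10)
})

test_that("estimator matches the per-clone brute-force oracle", {
  withr::with_seed(31, {
    for (i in 1:100) {
      n_per <- sample(1:12, 3, replace = TRUE)
      fractions <- rep(c("F1", "F2", "F3"), times = n_per)
      types <- sample(cell_types(), length(fractions), replace = TRUE)
      calls <- make_calls(fractions, types)
      N <- runif(1, 10, 1000)
      s_raw <- runif(3)
      s <- s_raw / sum(s_raw) * runif(1, 0.5, 1)
      ff <- fraction_frequencies("young", N,
                                 c(F1 = s[1], F2 = s[2], F3 = s[3]))
      est <- estimate_per_million(composition(calls), ff)
      ora <- oracle_per_million(calls, N, ff$shares, cell_types())
      expect_equal(est$per_million[match(cell_types(), est$cell_type)],
                   unname(ora), tolerance = 1e-12)
      # conservation and scale equivariance
      expect_equal(sum(est$per_million), N * sum(s), tolerance = 1e-9)
      ff3 <- fraction_frequencies("young", 3 * N,
                                  c(F1 = s[1], F2 = s[2], F3 = s[3]))
      est3 <- estimate_per_million(composition(calls), ff3)
      expect_equal(est3$per_million, 3 * est$per_million, tolerance = 1e-9)
    }
  })
})

test_that("fold changes round half away from zero and handle zero baselines", {
  expect_equal(fold_change(7.3, 21.0), 2.9)
  expect_equal(fold_change(10.8, 52.4), 4.9)
  expect_true(is.na(fold_change(0, 2)))
  expect_equal(format_fold(fold_change(0, 2)), "n/a")
  expect_equal(fold_change(2, 0.5), 0.3) # 0.25 rounds away from zero
  expect_equal(fold_change(1, 0), 0)
  expect_error(fold_change(-1, 2), ">= 0")
})

test_that("grouped sums recompute folds on totals", {
  ref <- tibble::tibble(
    cell_type = c("LT-HSC", "IT-HSC", "ST-HSC", "ST-CMRP"),
    young = c(7.3, 5.6, 10.8, 9.2),
    aged = c(21.0, 49.9, 52.4, 75.1)
  )
  grp <- aggregate_groups(ref, list(HSC = c("LT-HSC", "IT-HSC", "ST-HSC")))
  expect_equal(grp$young, 23.7)
  expect_equal(grp$aged, 123.3)
  expect_equal(grp$fold, 5.2)
  expect_error(aggregate_groups(ref, list(g = "nope")), "unknown row label")
  expect_error(aggregate_groups(ref, list(a = "LT-HSC", b = "LT-HSC")),
               "at most one group")
})

test_that("bootstrap intervals are deterministic, stable in B, and degenerate when p = 1", {
  calls <- make_calls(rep(c("F1", "F2", "F3"), each = 30), "IT-HSC")
  ff <- fraction_frequencies("young", 200, c(F1 = 0.4, F2 = 0.35, F3 = 0.25))
  ci <- bootstrap_ci(calls, ff, B = 200, seed = 5)
  it <- ci[ci$cell_type == "IT-HSC", ]
  expect_equal(it$lower, 200)
  expect_equal(it$upper, 200)

  co <- simulate_cohort(aging_scenarios()$aged, 150, seed = 19)
  real_calls <- classify_cohort(co)
  ffa <- aging_scenarios()$aged$fraction_frequencies
  c1 <- bootstrap_ci(real_calls, ffa, B = 400, seed = 11)
  c1b <- bootstrap_ci(real_calls, ffa, B = 400, seed = 11)
  expect_identical(c1, c1b)
  c2 <- bootstrap_ci(real_calls, ffa, B = 800, seed = 12)
  nr <- c1$cell_type == "non-reconstituting"
  width <- c1$upper[nr] - c1$lower[nr]
  expect_lt(abs(c1$lower[nr] - c2$lower[nr]), 0.25 * width)
  expect_lt(abs(c1$upper[nr] - c2$upper[nr]), 0.25 * width)

  tiny <- make_calls(c("F1", "F2", "F2", "F3", "F3"), "IT-HSC")
  ci_tiny <- bootstrap_ci(tiny, ff, B = 100, seed = 1)
  expect_equal(attr(ci_tiny, "unreliable_fractions"), "F1")
  expect_error(bootstrap_ci(calls, ff, B = 50, seed = 1), "B must be")
})

test_that("preset frequencies are recovered within bootstrap intervals", {
  sc <- aging_scenarios()$aged
  truth <- scenario_expected_frequencies(sc)
  co <- simulate_cohort(sc, 2000, seed = 23)
  ci <- bootstrap_ci(classify_cohort(co), sc$fraction_frequencies,
                     B = 500, seed = 24)
  tab <- dplyr::inner_join(ci, truth, by = "cell_type")
  hit <- tab$lower <= tab$per_million.y & tab$per_million.y <= tab$upper
  expect_gte(mean(hit), 0.90)
})

test_that("composition chi-square matches the closed-form Pearson statistic", {
  same <- composition_chisq(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  res <- composition_chisq(c(10, 0), c(0, 10))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)

  # both-empty categories change nothing
  a <- composition_chisq(c(3, 7, 0), c(6, 2, 0))
  b <- composition_chisq(c(3, 7), c(6, 2))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$df, b$df)

  withr::with_seed(8, {
    for (i in 1:20) {
      k <- sample(2:8, 1)
      y <- rpois(k, 6); g <- rpois(k, 6)
      y[1] <- y[1] + 1; g[1] <- g[1] + 1
      res <- composition_chisq(y, g)
      ora <- oracle_pearson(y, g)
      expect_equal(res$statistic, ora$statistic, tolerance = 1e-12)
      expect_equal(res$df, ora$df)
    }
  })
  expect_error(composition_chisq(c(0, 0), c(0, 0)), "positive total")
})

test_that("compartment_table joins ages and formats folds downstream", {
  calls_y <- make_calls(rep(c("F1", "F2", "F3"), each = 10),
                        c(rep("LT-HSC", 15), rep("non-reconstituting", 15)))
  calls_a <- make_calls(rep(c("F1", "F2", "F3"), each = 10),
                        c(rep("LT-HSC", 24), rep("non-reconstituting", 6)),
                        age = "aged")
  ffy <- fraction_frequencies("young", 100, c(F1 = 1/3, F2 = 1/3, F3 = 1/3))
  ffa <- fraction_frequencies("aged", 1000, c(F1 = 1/3, F2 = 1/3, F3 = 1/3))
  tab <- compartment_table(
    estimate_per_million(composition(calls_y), ffy),
    estimate_per_million(composition(calls_a), ffa))
  lt <- tab[tab$cell_type == "LT-HSC", ]
  expect_equal(lt$young, 50)
  expect_equal(lt$aged, 800)
  expect_equal(lt$fold, 16)
})
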