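test_that("t-test handles identity, separation and degenerate samples", {
  r <- students_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_two_tailed, 1)
  expect_identical(r$stars, "")

  r2 <- students_t_test(c(1, 2, 3), c(101, 102, 103))
  expect_lt(r2$p_two_tailed, 0.01)
  expect_identical(r2$stars, "**")
  expect_equal(r2$df, 4)

  # sample with < 2 values: not-computable, no exception
  r3 <- students_t_test(c(1), c(1, 2, 3))
  expect_true(is.na(r3$p_two_tailed))
  expect_identical(r3$stars, "†")

  # zero-variance pairs
  r4 <- students_t_test(c(5, 5), c(5, 5))
  expect_equal(r4$p_two_tailed, 1)
  r5 <- students_t_test(c(5, 5), c(6, 6))
  expect_equal(r5$p_two_tailed, 0)
  expect_identical(r5$stars, "**")
})

test_that("t and p match the independent density/permutation oracle", {
  a <- c(2.1, 2.0)
  b <- c(3.0, 3.1)
  r <- students_t_test(a, b, "equal")
  # hand-computed pooled-variance t with df = 2
  sp2 <- (var(a) + var(b)) / 2
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 2 + 1 / 2))
  expect_equal(r$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_two_tailed, t_density_p(t_hand, 2), tolerance = 1e-6)
  # the observed split is the most extreme of all 6 relabelings
  expect_equal(permutation_p(a, b), 2 / 6, tolerance = 1e-12)
  expect_lt(r$p_two_tailed, 0.05)

  # Welch variant reports fractional df
  rw <- students_t_test(c(1, 2, 3, 9), c(4.2, 4.4, 4.1), "welch")
  tw <- t.test(c(1, 2, 3, 9), c(4.2, 4.4, 4.1))
  expect_equal(rw$t_statistic, unname(tw$statistic))
  expect_equal(rw$df, unname(tw$parameter))
  expect_equal(rw$p_two_tailed, tw$p.value)
})

test_that("significance stars use strict thresholds", {
  expect_identical(significance_stars(0.05), "")
  expect_identical(significance_stars(0.049), "*")
  expect_identical(significance_stars(0.01), "*")
  expect_identical(significance_stars(0.009), "**")
  expect_identical(significance_stars(NA_real_), "†")
})

make_aff <- function(variant, values, measurable = TRUE) {
  structure(list(variant = variant,
                 mean_ka = if (measurable) mean(values) else NA_real_,
                 sd_ka = if (measurable && length(values) > 1) sd(values) else 0,
                 n = length(values), n_total = length(values),
                 measurable = measurable,
                 values = if (measurable) values else numeric(0)),
            class = "affinity_summary")
}

make_tm <- function(variant, values) {
  out <- summarize_tm(as.list(values))
  out$variant <- variant
  out
}

test_that("reversion effects classify stability from replicate melts", {
  # evolved-variant melts at 66.0 +/- 0.1 vs the reversion at 62.4 +/- 0.6
  p4 <- make_tm("P4", c(65.93, 66.07))
  rev <- make_tm("P4_K98E", c(61.98, 62.82))
  rec <- reversion_effect(p4, rev, "E98K", context = "P4")
  expect_equal(rec$delta_tm, 3.6, tolerance = 1e-9)
  expect_lt(rec$p_tm, 0.05)
  expect_identical(rec$stability_class, "stabilizing")

  same <- reversion_effect(p4, p4, "E98K", context = "P4")
  expect_equal(same$delta_tm, 0)
  expect_identical(same$stability_class, "neutral")
})

test_that("unmeasurable affinity propagates the dagger convention", {
  p4 <- make_aff("P4", c(4.8e7, 5.2e7, 5.0e7))
  lost <- make_aff("P4_R100dG", numeric(0), measurable = FALSE)
  rec <- reversion_effect(p4, lost, "G100dR", context = "P4")
  expect_true(is.na(rec$p_ka))
  expect_identical(rec$affinity_stars, "†")
  # binding lost on reversion: the mutation is classified enhancing
  expect_identical(rec$affinity_class, "enhancing")

  # unmeasurable context: nothing can be computed
  p1 <- make_aff("P1", numeric(0), measurable = FALSE)
  rev <- make_aff("P1_K45E", numeric(0), measurable = FALSE)
  rec2 <- reversion_effect(p1, rev, "E45K", context = "P1")
  expect_identical(rec2$affinity_class, "not-computable")
})

test_that("swapping the comparison negates delta and preserves p", {
  a <- make_aff("A", c(1e7, 1.4e7, 1.2e7))
  b <- make_aff("B", c(2e7, 2.2e7, 2.4e7))
  r1 <- reversion_effect(a, b, "S50R", context = "A")
  r2 <- reversion_effect(b, a, "S50R", context = "B")
  expect_equal(r1$delta_ka, -r2$delta_ka)
  expect_equal(r1$p_ka, r2$p_ka)
})

test_that("classification is invariant under K_A unit changes", {
  a <- make_aff("A", c(1e7, 1.4e7, 1.2e7))
  b <- make_aff("B", c(2e7, 2.2e7, 2.4e7))
  a_nm <- make_aff("A", a$values / 1e9) # per-nM instead of per-M
  b_nm <- make_aff("B", b$values / 1e9)
  r <- reversion_effect(a, b, "S50R", context = "A")
  r_nm <- reversion_effect(a_nm, b_nm, "S50R", context = "A")
  expect_identical(r$affinity_class, r_nm$affinity_class)
  expect_equal(r$p_ka, r_nm$p_ka, tolerance = 1e-9)
})

test_that("the trade-off table pairs reversions with their contexts", {
  lin <- synthetic_vh_lineage()
  aff <- list(P4 = make_aff("P4", c(4.8e7, 5.2e7, 5.0e7)),
              P4_K45E = make_aff("P4_K45E", c(0.9e7, 1.1e7, 1.0e7)),
              P4_G82bS = make_aff("P4_G82bS", c(4.9e7, 5.1e7, 5.05e7)))
  stab <- list(P4 = make_tm("P4", c(65.93, 66.07)),
               P4_K45E = make_tm("P4_K45E", c(63.7, 63.9)),
               P4_G82bS = make_tm("P4_G82bS", c(65.9, 66.1)))
  tab <- build_tradeoff_table(aff, stab, lin)
  expect_equal(nrow(tab), 2L)
  k45 <- tab[tab$mutation == "E45K", ]
  expect_identical(k45$context_variant, "P4")
  expect_identical(k45$affinity_class, "enhancing")
  expect_identical(k45$stability_class, "stabilizing")
  g82b <- tab[tab$mutation == "S82bG", ]
  expect_identical(g82b$affinity_class, "neutral")
  expect_identical(g82b$stability_class, "neutral")
  # ordered by Kabat position
  expect_identical(tab$position, c("45", "82b"))
})

test_that("direct variant comparisons report delta and significance", {
  p4 <- make_tm("P4", c(65.93, 66.07))
  wt6 <- make_tm("WT6", c(70.2, 70.8))
  cmp <- compare_variants(wt6, p4)
  expect_equal(cmp$delta, 4.5, tolerance = 1e-9)
  expect_lt(cmp$p, 0.05)
})
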