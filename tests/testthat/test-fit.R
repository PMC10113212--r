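test_that("a saturated single-condition model fits perfectly", {
  d <- lineup_data("solo", "simultaneous", "morphed",
                   22, 14, 14, 8, 20, 22)
  f <- fit_mpt(d, seed = 1)
  expect_equal(f$df, 0L)
  expect_equal(f$g_squared, 0, tolerance = 1e-6)
  expect_true(is.na(f$p_value))
  expect_true(f$converged)
})

test_that("counts constructed at expected values recover the parameters", {
  # chosen so every expected cell is an integer at n = 400 per tree
  truth <- mpt_params(dP = 0.5, b = 0, g = 0.6, dA = 0.5)
  cond <- lineup_condition("x", "simultaneous", "morphed", 400, 400)
  e <- expected_counts(truth, cond)
  expect_equal(unname(e), c(220, 100, 80, 20, 100, 280))
  d <- lineup_data("x", "simultaneous", "morphed",
                   e[1], e[2], e[3], e[4], e[5], e[6])
  f <- suppressWarnings(fit_mpt(d, seed = 3, n_starts = 6))
  expect_equal(f$g_squared, 0, tolerance = 1e-5)
  expect_equal(coef_mpt(f, "dP", "x"), 0.5, tolerance = 1e-3)
  expect_equal(coef_mpt(f, "g", "x"), 0.6, tolerance = 1e-3)
  expect_equal(coef_mpt(f, "dA", "x"), 0.5, tolerance = 1e-3)
  expect_equal(coef_mpt(f, "b", "x"), 0, tolerance = 1e-3)
})

test_that("fitted G2 agrees with a brute-force likelihood oracle", {
  d <- toy_two_condition()
  f <- fit_mpt(d, toy_restrictions(), seed = 1)
  expect_equal(f$g_squared, brute_force_g2(d), tolerance = 1e-4)
})

test_that("expected counts of a fit conserve the per-tree totals", {
  set.seed(31)
  for (i in 1:5) {
    pars <- replicate(2, random_params(), simplify = FALSE)
    sim <- simulate_eyewitness(pars, n_participants = c(60, 80),
                               seed = 300 + i)
    f <- suppressWarnings(fit_mpt(sim, restriction_set(sim$condition,
                                                       share = list(dA = "all")),
                                  n_starts = 3, seed = i))
    tc <- trial_counts(sim)
    expect_equal(unname(rowSums(f$expected[, 1:3])),
                 tc$n_culprit_present, tolerance = 1e-6)
    expect_equal(unname(rowSums(f$expected[, 4:6])),
                 tc$n_culprit_absent, tolerance = 1e-6)
  }
})

test_that("fits are bit-reproducible given the seed", {
  d <- toy_two_condition()
  f1 <- fit_mpt(d, toy_restrictions(), seed = 99)
  f2 <- fit_mpt(d, toy_restrictions(), seed = 99)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$g_squared, f2$g_squared)
})

test_that("boundary estimates flag their standard errors", {
  # all identifications of the suspect: dP and dA estimates hit 1/0
  d <- lineup_data("x", "simultaneous", "morphed",
                   400, 0, 0, 400, 0, 0)
  expect_warning(f <- fit_mpt(d, seed = 1), "boundary")
  expect_true(any(f$boundary))
  expect_true(all(is.na(f$std_errors[f$boundary])))
})

test_that("Delta-G2 is additive along a chain of nested restrictions", {
  d <- load_fixture("exp2")
  rs_a <- base_restrictions(d)
  rs_b <- restrict_equal(rs_a, "b", c("sim_morphed", "sim_nonmorphed"))
  rs_c <- restrict_equal(rs_b, "b", "all")
  fa <- fit_mpt(d, rs_a, seed = 1)
  fb <- fit_mpt(d, rs_b, seed = 1)
  fc <- fit_mpt(d, rs_c, seed = 1)
  ab <- compare_mpt(fa, fb)
  bc <- compare_mpt(fb, fc)
  ac <- compare_mpt(fa, fc)
  expect_equal(ac$delta_g_squared,
               ab$delta_g_squared + bc$delta_g_squared, tolerance = 1e-4)
  expect_equal(ac$df, ab$df + bc$df)
})

test_that("non-nested and degenerate comparisons are structural errors", {
  d <- load_fixture("exp2")
  rs <- base_restrictions(d)
  f0 <- fit_mpt(d, rs, seed = 1)

  # a model compared with itself
  expect_error(compare_mpt(f0, fit_mpt(d, rs, seed = 2)),
               "same degrees of freedom")

  # same df but different partitions is caught by the df check too
  f_b <- fit_mpt(d, restrict_equal(rs, "b", c("sim_morphed",
                                              "sim_nonmorphed")),
                 seed = 1)
  # coarser in dP *and* g but not a refinement of f_b's partition
  rs_x <- restrict_equal(restrict_equal(rs, "dP", "all"), "g", "all")
  f_x <- fit_mpt(d, rs_x, seed = 1)
  expect_error(compare_mpt(f_b, f_x), "not nested")

  # swapped arguments
  expect_error(compare_mpt(f_b, f0), "swap")

  # different data
  d2 <- load_fixture("exp3")
  f3 <- fit_mpt(d2, base_restrictions(d2), seed = 1)
  expect_error(compare_mpt(f0, f3), "identical tables")
})

test_that("restrictions must cover the data's conditions", {
  d <- toy_two_condition()
  expect_error(fit_mpt(d, restriction_set(c("A", "Z")), seed = 1),
               "conditions")
})
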