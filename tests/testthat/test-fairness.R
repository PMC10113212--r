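test_that("Tredoux's E spans [1, k] with the documented extremes", {
  expect_equal(tredoux_e(rep(10, 6)), 6)
  expect_equal(tredoux_e(c(42, 0, 0, 0, 0, 0)), 1)
  expect_equal(tredoux_e(c(50, 10, 10, 10, 10, 10)),
               1 / (0.5^2 + 5 * 0.1^2))
  expect_equal(resultant_tredoux_e(c(20, 16, 16, 16, 16, 16)),
               1 / (0.2^2 + 5 * 0.16^2))
  expect_error(tredoux_e(c(0, 0, 0)), "empty")
})

test_that("E is permutation- and scale-invariant and interior otherwise", {
  set.seed(41)
  for (i in 1:50) {
    counts <- sample(0:30, 6, replace = TRUE)
    if (sum(counts) == 0) counts[1] <- 1
    e <- tredoux_e(counts)
    expect_gte(e, 1)
    expect_lte(e, 6 + 1e-12)
    expect_equal(tredoux_e(sample(counts)), e, tolerance = 1e-12)
    expect_equal(tredoux_e(counts * 7), e, tolerance = 1e-12)
    uniform <- length(unique(counts)) == 1L
    degenerate <- sum(counts > 0) == 1L
    if (!uniform && !degenerate) {
      expect_gt(e, 1)
      expect_lt(e, 6)
    }
  }
})

test_that("proportion of suspect selections reads the suspect slot", {
  expect_equal(proportion_suspect(choice_distribution(rep(5, 6), 3)), 1 / 6)
  expect_equal(proportion_suspect(choice_distribution(c(0, 12, 0, 0), 2)), 1)
  expect_equal(proportion_suspect(c(50, 10, 10, 10, 10, 10)), 0.5)
  expect_error(proportion_suspect(choice_distribution(c(1, 1), 3)),
               "out of bounds")
})

test_that("resultant suspect proportion matches the culprit-absent cells", {
  d <- load_fixture("exp2")
  got <- resultant_suspect_proportion(d)
  expect_equal(unname(got["sim_morphed"]), 93 / (93 + 161))
  expect_equal(unname(got["seq_morphed"]), 58 / (58 + 247))
  z <- lineup_data("z", "simultaneous", "morphed", 5, 5, 5, 0, 10, 5)
  expect_equal(unname(resultant_suspect_proportion(z)), 0)
  bad <- lineup_data("b", "simultaneous", "morphed", 5, 5, 5, 0, 0, 10)
  expect_error(resultant_suspect_proportion(bad), "culprit-absent")
})

test_that("resultant proportion is consistent with the model probabilities", {
  set.seed(42)
  for (i in 1:20) {
    params <- random_params()
    pr <- predict_categories(params)
    if (pr[["ca_suspect"]] + pr[["ca_filler"]] < 1e-6) next
    cond <- lineup_condition("c", "simultaneous", "morphed", 1000, 1000)
    e <- expected_counts(params, cond)
    d <- data.frame(condition = "c", lineup_format = "simultaneous",
                    filler_type = "morphed", t(e))
    class(d) <- c("lineup_data", "data.frame")
    expect_equal(unname(resultant_suspect_proportion(d)),
                 pr[["ca_suspect"]] /
                   (pr[["ca_suspect"]] + pr[["ca_filler"]]),
                 tolerance = 1e-9)
  }
})

test_that("identification rate pools suspect and filler picks", {
  d <- load_fixture("exp2")
  seq <- d[d$lineup_format == "sequential", ]
  expect_equal(identification_rate(seq),
               (112 + 220 + 58 + 247 + 130 + 201 + 67 + 234) /
                 (2 * 392 + 2 * 396))
  all_reject <- lineup_data("r", "simultaneous", "morphed",
                            0, 0, 50, 0, 0, 50)
  expect_equal(identification_rate(all_reject), 0)
  empty <- lineup_data("e", "simultaneous", "morphed", 0, 0, 0, 0, 0, 0)
  expect_error(identification_rate(empty), "no decisions")
})

test_that("averaging follows the per-lineup-then-mean convention", {
  d1 <- choice_distribution(c(30, 10, 10, 10, 10, 10), 1)
  d2 <- choice_distribution(c(10, 10, 10, 10, 10, 10), 1)
  avg <- average_fairness(list(d1, d2))
  expect_equal(avg$mean_e, (tredoux_e(d1) + tredoux_e(d2)) / 2)
  expect_equal(avg$prop_suspect, (30 + 10) / (80 + 60))
})
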