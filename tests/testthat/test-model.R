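test_that("predicted category probabilities match the tree structure", {
  # certain detection, no guessing: only the detection paths are reachable
  p <- predict_categories(mpt_params(dP = 1, b = 0, g = 0, dA = 1))
  expect_equal(unname(p[c("cp_suspect", "ca_reject")]), c(1, 1))
  expect_equal(unname(p[c("cp_filler", "cp_reject", "ca_suspect",
                          "ca_filler")]), rep(0, 4))

  # pure guessing splits 1 : (k - 1); both trees identical
  p <- predict_categories(mpt_params(dP = 0, b = 0, g = 1, dA = 0))
  expect_equal(unname(p[1:3]), c(1 / 6, 5 / 6, 0))
  expect_equal(unname(p[4:6]), unname(p[1:3]))

  # derived by summing the three culprit-present suspect paths by hand
  p <- predict_categories(mpt_params(dP = 0.27, b = 0.2, g = 0.59,
                                     dA = 0.04))
  by_hand <- 0.27 + (1 - 0.27) * 0.2 + (1 - 0.27) * (1 - 0.2) * 0.59 / 6
  expect_equal(unname(p[["cp_suspect"]]), by_hand, tolerance = 1e-12)
  expect_equal(round(by_hand, 4), 0.4734)
})

test_that("each tree's probabilities are non-negative and sum to 1", {
  set.seed(11)
  for (i in 1:200) {
    p <- predict_categories(random_params())
    expect_true(all(p >= 0))
    expect_equal(sum(p[1:3]), 1, tolerance = 1e-12)
    expect_equal(sum(p[4:6]), 1, tolerance = 1e-12)
  }
})

test_that("suspect probabilities are monotone in b, dP, dA", {
  set.seed(12)
  for (i in 1:50) {
    base <- list(dP = runif(1), b = runif(1), g = runif(1), dA = runif(1))
    bump <- function(nm) {
      up <- base
      up[[nm]] <- base[[nm]] + (1 - base[[nm]]) * 0.5
      list(lo = predict_categories(do.call(mpt_params, base)),
           hi = predict_categories(do.call(mpt_params, up)))
    }
    w <- bump("b")
    expect_gte(w$hi[["cp_suspect"]], w$lo[["cp_suspect"]])
    expect_gte(w$hi[["ca_suspect"]], w$lo[["ca_suspect"]])
    w <- bump("dP")
    expect_gte(w$hi[["cp_suspect"]], w$lo[["cp_suspect"]])
    w <- bump("dA")
    expect_gte(w$hi[["ca_reject"]], w$lo[["ca_reject"]])
  }
})

test_that("b = 0 makes the suspect a 1/(k-1) filler in the absent tree", {
  set.seed(13)
  for (k in c(2L, 4L, 6L, 10L)) {
    p <- predict_categories(mpt_params(dP = runif(1), b = 0,
                                       g = runif(1, 0.2, 0.9),
                                       dA = runif(1, 0, 0.8),
                                       lineup_size = k))
    expect_equal(p[["ca_suspect"]] / p[["ca_filler"]], 1 / (k - 1),
                 tolerance = 1e-12)
  }
})

test_that("closed form equals path enumeration through the eqn file", {
  set.seed(14)
  eqn <- parse_eqn(serialize_eqn("c1"))
  for (i in 1:25) {
    params <- random_params()
    vals <- c(dP_c1 = params$dP, b_c1 = params$b, g_c1 = params$g,
              dA_c1 = params$dA, u_c1 = 1 / params$lineup_size)
    enumerated <- eval_eqn(eqn, vals)
    direct <- predict_categories(params)
    expect_equal(enumerated[["c1.cp:cp_suspect"]],
                 direct[["cp_suspect"]], tolerance = 1e-12)
    expect_equal(enumerated[["c1.ca:ca_reject"]],
                 direct[["ca_reject"]], tolerance = 1e-12)
    expect_equal(enumerated[["c1.cp:cp_filler"]],
                 direct[["cp_filler"]], tolerance = 1e-12)
    expect_equal(enumerated[["c1.ca:ca_suspect"]],
                 direct[["ca_suspect"]], tolerance = 1e-12)
  }
})

test_that("expected counts scale probabilities by tree totals", {
  cond <- lineup_condition("x", "simultaneous", "morphed", 600, 600)
  e <- expected_counts(mpt_params(0, 0, 1, 0), cond)
  expect_equal(e[["cp_suspect"]], 100)

  empty <- lineup_condition("x", "simultaneous", "morphed", 0, 400)
  e <- expected_counts(mpt_params(0.3, 0.1, 0.5, 0.2), empty)
  expect_equal(unname(e[1:3]), rep(0, 3))

  set.seed(15)
  for (i in 1:20) {
    n <- sample(1:500, 2)
    cond <- lineup_condition("x", "sequential", "non-morphed", n[1], n[2])
    e <- expected_counts(random_params(), cond)
    expect_equal(sum(e[1:3]), n[1], tolerance = 1e-9)
    expect_equal(sum(e[4:6]), n[2], tolerance = 1e-9)
  }
})

test_that("invalid parameters are rejected with the offending field named", {
  expect_error(mpt_params(1.2, 0, 0, 0), "dP")
  expect_error(mpt_params(0.5, -0.1, 0, 0), "'b'")
  expect_error(mpt_params(0.5, 0.5, 2, 0), "'g'")
  expect_error(mpt_params(0.5, 0.5, 0.5, NA), "dA")
  expect_error(mpt_params(0.5, 0.5, 0.5, 0.5, lineup_size = 1), "lineup_size")
  expect_error(lineup_condition("x", "simultaneous", "morphed", -1, 10),
               "non-negative")
})
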