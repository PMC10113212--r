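# Shared fixtures and independent oracles for the test suite.

# random but valid model parameters, away from the exact boundary
random_params <- function(k = 6L) {
  mpt_params(dP = runif(1), b = runif(1), g = runif(1), dA = runif(1),
             lineup_size = k)
}

# a tiny two-condition dataset (integer counts, ~200 observations) used
# by the brute-force likelihood oracle
toy_two_condition <- function() {
  lineup_data(condition = c("A", "B"),
              lineup_format = "simultaneous",
              filler_type = c("morphed", "non-morphed"),
              cp_suspect = c(22, 15), cp_filler = c(14, 12),
              cp_reject = c(14, 23),
              ca_suspect = c(8, 5), ca_filler = c(20, 17),
              ca_reject = c(22, 28))
}

# restrictions used with toy_two_condition(): dP, g, dA shared, b free
toy_restrictions <- function() {
  restriction_set(c("A", "B"),
                  share = list(dP = "all", g = "all", dA = "all"))
}

# Brute-force maximizer of the same product-multinomial likelihood:
# coarse grid over the free parameters followed by Nelder-Mead polishing
# on the probability scale (clamped).  Independent of fit_mpt's logit
# parameterization and BFGS path.
brute_force_g2 <- function(data, n_grid = 5) {
  counts <- as.matrix(data[, c("cp_suspect", "cp_filler", "cp_reject",
                               "ca_suspect", "ca_filler", "ca_reject")])
  k <- 6
  # free vector: dP, g, dA shared; b per condition -> (dP, g, dA, bA, bB)
  ll <- function(th) {
    val <- 0
    for (i in 1:2) {
      dP <- th[1]; g <- th[2]; dA <- th[3]; b <- th[3 + i]
      p <- c(dP + (1 - dP) * b + (1 - dP) * (1 - b) * g / k,
             (1 - dP) * (1 - b) * g * (1 - 1 / k),
             (1 - dP) * (1 - b) * (1 - g),
             (1 - dA) * b + (1 - dA) * (1 - b) * g / k,
             (1 - dA) * (1 - b) * g * (1 - 1 / k),
             dA + (1 - dA) * (1 - b) * (1 - g))
      val <- val + sum(ifelse(counts[i, ] > 0,
                              counts[i, ] * log(pmax(p, 1e-300)), 0))
    }
    val
  }
  grid <- seq(0.1, 0.9, length.out = n_grid)
  cand <- list()
  for (a in grid) for (b in grid) for (cc in grid)
    for (d in grid) for (e in grid) {
      th <- c(a, b, cc, d, e)
      cand[[length(cand) + 1L]] <- list(th = th, v = ll(th))
    }
  cand <- cand[order(-vapply(cand, `[[`, numeric(1), "v"))]
  obj <- function(th) {
    if (any(th <= 0) || any(th >= 1)) return(1e10)
    -ll(th)
  }
  # polish the three best grid points, restarting Nelder-Mead twice each
  pol <- NULL
  for (c0 in cand[1:3]) {
    o <- optim(c0$th, obj, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-15))
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-15))
    if (is.null(pol) || o$value < pol$value) pol <- o
  }
  ll_sat <- 0
  for (i in 1:2) for (tr in list(1:3, 4:6)) {
    n <- counts[i, tr]; N <- sum(n)
    ll_sat <- ll_sat + sum(ifelse(n > 0, n * log(n / N), 0))
  }
  2 * (ll_sat + pol$value)
}
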