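#' Joint maximum-likelihood fit of the 2-HT model
#'
#' Fits the two-high-threshold eyewitness identification model jointly to
#' one or more conditions under equality restrictions, by maximising the
#' product-multinomial log-likelihood
#' \deqn{\ell(\theta) = \sum_{trees} \sum_{categories} n \log \pi(\theta)}
#' over an unconstrained logit transform of every free parameter group.
#' The optimiser (BFGS) is restarted from `n_starts` points: one start at
#' 0.5 for every parameter plus random starts drawn from the seed, and the
#' best likelihood is retained.  The goodness-of-fit statistic is
#' \deqn{G^2 = 2 \sum n \log(n / \hat e)} summed over cells with `n > 0`,
#' asymptotically chi-square with [mpt_df()] degrees of freedom.
#'
#' Standard errors come from the numerically differentiated observed
#' information matrix on the logit scale, delta-method back-transformed to
#' the probability scale.  Estimates at the boundary of the unit interval
#' are flagged and their standard error reported as `NA` rather than a
#' fabricated value.
#'
#' @param data A [lineup_data()] object (one row per condition).
#' @param restrictions A [restriction_set()]; `NULL` fits all four
#'   parameters freely in every condition.
#' @param lineup_size Number of lineup members (design constant).
#' @param n_starts Number of optimiser starts (the first is always the
#'   central start at 0.5).
#' @param seed Integer seed for the random restarts; recorded in the
#'   result so fits are bit-reproducible.
#' @param reltol Relative convergence tolerance on the log-likelihood.
#' @param se Compute standard errors (disable in large simulation loops
#'   where only the likelihood is needed).
#' @return An object of class `"mpt_fit"`: estimates and standard errors
#'   per free group, `log_likelihood`, `g_squared`, `df`, `p_value`,
#'   per-condition `expected` counts, `converged`, `boundary` flags,
#'   `n_total`, and the inputs needed for nested comparisons.
#' @examples
#' tabs <- load_fixture("exp2")
#' fit <- fit_mpt(tabs, base_restrictions(tabs), seed = 1)
#' fit
#' @export
fit_mpt <- function(data, restrictions = NULL, lineup_size = 6L,
                    n_starts = 10L, seed = 1L, reltol = 1e-12, se = TRUE) {
  stopifnot(inherits(data, "lineup_data"))
  if (is.null(restrictions))
    restrictions <- restriction_set(data$condition)
  if (!setequal(restrictions$conditions, data$condition))
    stop("restrictions do not cover the data's conditions", call. = FALSE)
  df <- mpt_df(data, restrictions)

  counts <- count_matrix(data)
  C <- nrow(counts)
  map <- restrictions$map
  groups_all <- unique(map$group)
  free <- setdiff(groups_all, names(restrictions$fixed))
  K <- length(free)
  fixed_vals <- restrictions$fixed
  # index of each (condition, parameter) slot into c(theta_free, fixed)
  value_names <- c(free, names(fixed_vals))
  idx <- matrix(NA_integer_, C, 4L,
                dimnames = list(data$condition, PARAM_NAMES))
  for (r in seq_len(nrow(map)))
    idx[map$condition[r], map$parameter[r]] <-
      match(map$group[r], value_names)

  nll <- function(eta) {
    v <- c(plogis(eta), fixed_vals)
    P <- category_probs(v[idx[, "dP"]], v[idx[, "b"]], v[idx[, "g"]],
                        v[idx[, "dA"]], lineup_size)
    if (C == 1L) P <- matrix(P, 1L)
    ll <- sum(ifelse(counts > 0, counts * log(pmax(P, 1e-300)), 0))
    -ll
  }

  if (K > 0L) {
    set.seed(as.integer(seed))
    starts <- c(list(rep(0, K)),
                replicate(max(0L, n_starts - 1L),
                          qlogis(runif(K, 0.05, 0.95)), simplify = FALSE))
    best <- NULL
    for (st in starts) {
      o <- tryCatch(
        optim(st, nll, method = "BFGS",
              control = list(maxit = 2000L, reltol = reltol)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best))
      stop("optimization failed in all ", n_starts, " starts", call. = FALSE)
    eta <- best$par
    converged <- best$convergence == 0L
    est <- setNames(plogis(eta), free)
  } else {
    eta <- numeric(0)
    converged <- TRUE
    est <- setNames(numeric(0), character(0))
  }

  v <- c(est, fixed_vals)
  P <- category_probs(v[idx[, "dP"]], v[idx[, "b"]], v[idx[, "g"]],
                      v[idx[, "dA"]], lineup_size)
  if (C == 1L) P <- matrix(P, 1L)
  tree_n <- cbind(rowSums(counts[, 1:3, drop = FALSE]),
                  rowSums(counts[, 4:6, drop = FALSE]))
  expected <- P * tree_n[, c(1, 1, 1, 2, 2, 2)]
  dimnames(expected) <- dimnames(counts)

  loglik <- -nll(eta)
  # saturated log-likelihood per tree
  ll_sat <- 0
  for (i in seq_len(C)) for (tr in list(1:3, 4:6)) {
    n <- counts[i, tr]; N <- sum(n)
    if (N > 0) ll_sat <- ll_sat + sum(ifelse(n > 0, n * log(n / N), 0))
  }
  g2 <- 2 * (ll_sat - loglik)
  zero_exp <- expected < 1e-12 & counts > 0
  if (any(zero_exp)) {
    warning("observed counts in cells with zero expected frequency; ",
            "G-squared is infinite", call. = FALSE)
    g2 <- Inf
  } else if (g2 < 0) {
    if (g2 < -1e-6)
      warning("negative G-squared (", format(g2),
              ") beyond numerical tolerance", call. = FALSE)
    g2 <- 0
  }
  p_value <- if (df > 0L) pchisq(g2, df, lower.tail = FALSE) else NA_real_

  boundary <- est < 1e-6 | est > 1 - 1e-6
  std_err <- setNames(rep(NA_real_, K), free)
  if (se && K > 0L) {
    H <- tryCatch(optimHess(eta, nll), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        d <- diag(V)
        ok <- d > 0
        std_err[ok] <- sqrt(d[ok]) * est[ok] * (1 - est[ok])
      }
    }
    if (any(boundary)) {
      warning("estimate(s) at the boundary of [0, 1]: ",
              paste(free[boundary], collapse = ", "),
              "; their standard errors are reported as NA", call. = FALSE)
      std_err[boundary] <- NA_real_
    }
  }

  structure(list(estimates = est, std_errors = std_err,
                 boundary = boundary, log_likelihood = loglik,
                 g_squared = g2, df = df, p_value = p_value,
                 expected = expected, converged = converged,
                 n_total = sum(counts), counts = counts,
                 restrictions = restrictions, lineup_size = lineup_size,
                 data = data, seed = as.integer(seed),
                 n_starts = as.integer(n_starts)),
            class = "mpt_fit")
}

#' @export
print.mpt_fit <- function(x, digits = 4, ...) {
  cat("2-HT model joint fit:", nrow(x$counts), "condition(s),",
      x$n_total, "decisions\n")
  cat(sprintf("  G2(%d) = %.*f, p = %.3f%s\n", x$df, 2, x$g_squared,
              if (is.na(x$p_value)) NA else x$p_value,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- data.frame(estimate = round(x$estimates, digits),
                    se = round(x$std_errors, digits))
  print(est)
  invisible(x)
}

#' @export
logLik.mpt_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$estimates),
            class = "logLik")
}

#' Extract the estimate shared by a set of conditions
#'
#' Convenience accessor: returns the fitted value of `parameter` in
#' `condition`, resolving the restriction group it belongs to.
#'
#' @param fit An [fit_mpt()] result.
#' @param parameter One of `dP`, `b`, `g`, `dA`.
#' @param condition A condition label present in the fit.
#' @param what `"estimate"` or `"se"`.
#' @return A single numeric value.
#' @export
coef_mpt <- function(fit, parameter, condition, what = c("estimate", "se")) {
  stopifnot(inherits(fit, "mpt_fit"))
  what <- match.arg(what)
  map <- fit$restrictions$map
  g <- map$group[map$parameter == parameter & map$condition == condition]
  if (!length(g)) stop("no such slot: ", parameter, "(", condition, ")",
                       call. = FALSE)
  if (g %in% names(fit$restrictions$fixed))
    return(if (what == "estimate") fit$restrictions$fixed[[g]] else NA_real_)
  if (what == "estimate") fit$estimates[[g]] else fit$std_errors[[g]]
}
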