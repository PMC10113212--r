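#' Nested model comparison by the Delta-G-squared statistic
#'
#' Tests an equality hypothesis by comparing a base model against a model
#' with one (or more) additional restriction(s).  The statistic is the
#' difference in likelihood-ratio fit statistics,
#' \deqn{\Delta G^2 = G^2_{restricted} - G^2_{base},}
#' asymptotically chi-square with degrees of freedom equal to the
#' difference in free parameter counts; the effect size is Cohen's
#' \eqn{w = \sqrt{\Delta G^2 / N}} with `N` the total number of
#' identification decisions entering the joint fit.
#'
#' Both fits must have been obtained on identical tables and the
#' restricted model's restriction set must strictly refine (coarsen the
#' free-parameter partition of) the base model's; comparing a model with
#' itself is an error, not a zero.
#'
#' @param base The less constrained [fit_mpt()] result.
#' @param restricted The fit with the additional restriction(s).
#' @return An object of class `"mpt_test"` with `delta_g_squared`, `df`,
#'   `p_value` and `w`.
#' @examples
#' tabs <- load_fixture("exp2")
#' rs <- base_restrictions(tabs)
#' f0 <- fit_mpt(tabs, rs, seed = 1)
#' f1 <- fit_mpt(tabs, restrict_equal(rs, "b", c("sim_morphed",
#'                                               "sim_nonmorphed")), seed = 1)
#' compare_mpt(f0, f1)
#' @export
compare_mpt <- function(base, restricted) {
  stopifnot(inherits(base, "mpt_fit"), inherits(restricted, "mpt_fit"))
  if (!identical(base$counts, restricted$counts))
    stop("the two models were not fitted on identical tables",
         call. = FALSE)
  if (base$lineup_size != restricted$lineup_size)
    stop("lineup sizes differ between the fits", call. = FALSE)
  df <- restricted$df - base$df
  if (df == 0L)
    stop("models have the same degrees of freedom; ",
         "a nested comparison needs a strictly smaller model",
         call. = FALSE)
  if (df < 0L)
    stop("'restricted' has more free parameters than 'base'; ",
         "swap the arguments", call. = FALSE)
  if (!is_refinement(base$restrictions, restricted$restrictions))
    stop("the restricted model is not nested within the base model",
         call. = FALSE)
  dg <- restricted$g_squared - base$g_squared
  if (dg < 0) {
    if (dg < -1e-6)
      warning("Delta-G-squared is negative (", format(dg),
              "); the restricted optimum beat the base optimum -- ",
              "refit with more starts", call. = FALSE)
    dg <- 0
  }
  structure(list(delta_g_squared = dg, df = df,
                 p_value = pchisq(dg, df, lower.tail = FALSE),
                 w = cohens_w(dg, base$n_total),
                 n_total = base$n_total),
            class = "mpt_test")
}

#' @export
print.mpt_test <- function(x, ...) {
  cat(sprintf("Delta-G2(%d) = %.2f, p = %.3f, w = %.2f  (N = %d)\n",
              x$df, x$delta_g_squared, x$p_value, x$w, x$n_total))
  invisible(x)
}

#' Cohen's w effect size for chi-square statistics
#'
#' @param delta_g_squared The (Delta-)G-squared statistic.
#' @param n_total Total number of observations underlying the fit.
#' @return `sqrt(delta_g_squared / n_total)`.  Small negative statistics
#'   (optimizer noise) are clamped to 0 with a warning.
#' @examples
#' cohens_w(21.89, 3132)  # ~0.08
#' @export
cohens_w <- function(delta_g_squared, n_total) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (delta_g_squared < 0) {
    warning("negative statistic clamped to 0", call. = FALSE)
    delta_g_squared <- 0
  }
  sqrt(delta_g_squared / n_total)
}

#' Minimum detectable effect size (chi-square sensitivity analysis)
#'
#' Solves for the effect size `w` detectable at significance level
#' `alpha` with the requested power, given `n_total` observations and a
#' chi-square test with `df` degrees of freedom.  The noncentrality
#' \eqn{\lambda} of the noncentral chi-square whose upper-tail mass beyond
#' the central critical value equals `power` is found by root-finding, and
#' \eqn{w = \sqrt{\lambda / N}} is returned.
#'
#' @param alpha Significance level, in (0, 1).
#' @param power Target power, in (0, 1).
#' @param n_total Number of observations.
#' @param df Degrees of freedom of the test (1 for a single equality
#'   restriction).
#' @return The minimum detectable Cohen's `w`.
#' @examples
#' sensitivity_w(0.05, 0.95, n_total = 3132, df = 1)  # ~0.064
#' @export
sensitivity_w <- function(alpha, power, n_total, df = 1L) {
  if (!(alpha > 0 && alpha < 1) || !(power > 0 && power < 1))
    stop("alpha and power must lie strictly between 0 and 1",
         call. = FALSE)
  if (n_total <= 0 || df < 1L)
    stop("n_total must be positive and df >= 1", call. = FALSE)
  crit <- qchisq(1 - alpha, df)
  f <- function(l) pchisq(crit, df, ncp = l, lower.tail = FALSE) - power
  if (power <= alpha) return(0)
  root <- uniroot(f, lower = 0, upper = 100,
                  extendInt = "upX", tol = 1e-10)$root
  sqrt(root / n_total)
}

#' Pooled two-proportion z test
#'
#' The classical large-sample test for the difference of two independent
#' proportions with the pooled variance estimate:
#' \deqn{z = \frac{\hat p_1 - \hat p_2}
#'   {\sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}},}
#' where \eqn{\hat p} pools the successes of both groups.  The two-sided
#' p-value uses the standard normal distribution.
#'
#' @param successes1,n1 Successes and trials in group 1.
#' @param successes2,n2 Successes and trials in group 2.
#' @return A list with elements `z`, `p_value`, `p1`, `p2`, `pooled`.
#' @examples
#' two_proportion_z(30, 100, 10, 100)  # z ~ 3.54
#' @export
two_proportion_z <- function(successes1, n1, successes2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive",
                               call. = FALSE)
  if (successes1 < 0 || successes1 > n1 || successes2 < 0 ||
      successes2 > n2)
    stop("successes must lie between 0 and the group size", call. = FALSE)
  p1 <- successes1 / n1
  p2 <- successes2 / n2
  pool <- (successes1 + successes2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) {
    warning("pooled proportion is degenerate (0 or 1); z set to 0",
            call. = FALSE)
    z <- 0
  } else {
    z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  }
  list(z = z, p_value = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2,
       pooled = pool)
}
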