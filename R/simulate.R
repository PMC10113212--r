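#' Simulate eyewitness response tables from the 2-HT model
#'
#' Draws per-condition category counts from the product-multinomial
#' distribution the estimator assumes: each participant contributes
#' `lineups_per_participant` independent lineup decisions, split evenly
#' between culprit-present and culprit-absent lineups, with category
#' probabilities given by [predict_categories()].  Decisions are
#' independent within participants (no participant-level random effect),
#' matching the likelihood of [fit_mpt()].
#'
#' @param params A single [mpt_params()] object or a list of them, one
#'   per condition (recycled if length 1).
#' @param n_participants Participants per condition (recycled).
#' @param labels Condition labels; defaults to `cond1, cond2, ...`.
#' @param lineup_format,filler_type Condition metadata, recycled.
#' @param lineups_per_participant Decisions per participant; must be even
#'   (equal culprit-present / culprit-absent split).  Default 4.
#' @param seed Integer seed; required so simulated datasets are
#'   reproducible.  Recorded as attribute `seed` of the result.
#' @return A [lineup_data()] object with one row per condition.
#' @examples
#' p <- mpt_params(dP = 0.27, b = 0.15, g = 0.59, dA = 0.04)
#' simulate_eyewitness(p, n_participants = 200, seed = 1)
#' @export
simulate_eyewitness <- function(params, n_participants,
                                labels = NULL,
                                lineup_format = "simultaneous",
                                filler_type = "non-morphed",
                                lineups_per_participant = 4L,
                                seed) {
  if (inherits(params, "mpt_params")) params <- list(params)
  stopifnot(all(vapply(params, inherits, TRUE, "mpt_params")))
  lpp <- as.integer(lineups_per_participant)
  if (lpp < 2L || lpp %% 2L != 0L)
    stop("lineups_per_participant must be a positive even number",
         call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  C <- max(length(params), length(n_participants))
  params <- rep_len(params, C)
  n_participants <- rep_len(as.integer(n_participants), C)
  if (any(n_participants < 0)) stop("n_participants must be >= 0",
                                    call. = FALSE)
  if (is.null(labels)) labels <- paste0("cond", seq_len(C))
  lineup_format <- rep_len(lineup_format, C)
  filler_type <- rep_len(filler_type, C)

  set.seed(as.integer(seed))
  counts <- matrix(0L, C, 6L, dimnames = list(labels, CATEGORIES))
  for (i in seq_len(C)) {
    pr <- predict_categories(params[[i]])
    n_tree <- n_participants[i] * lpp %/% 2L
    if (n_tree > 0L) {
      counts[i, 1:3] <- rmultinom(1L, n_tree, pr[1:3])
      counts[i, 4:6] <- rmultinom(1L, n_tree, pr[4:6])
    }
  }
  out <- lineup_data(labels, lineup_format, filler_type,
                     counts[, 1], counts[, 2], counts[, 3],
                     counts[, 4], counts[, 5], counts[, 6])
  attr(out, "seed") <- as.integer(seed)
  attr(out, "lineups_per_participant") <- lpp
  out
}

#' Simulate mock-witness choices over a lineup
#'
#' Each witness selects the suspect with probability
#' `(1 + suspect_bias) / (k + suspect_bias)` and otherwise chooses
#' uniformly among the `k - 1` fillers.  `suspect_bias = 0` gives the
#' perfectly fair lineup in which every member attracts `1/k` of the
#' choices; as `suspect_bias` grows, the suspect absorbs all choices.
#'
#' @param k Lineup size, `>= 2`.
#' @param suspect_bias Non-negative bias knob.
#' @param n_witnesses Number of mock witnesses.
#' @param seed Integer seed.
#' @param suspect_index Position of the suspect (default 1).
#' @return A [choice_distribution()] with attribute `seed`.
#' @examples
#' simulate_mock_witness(k = 6, suspect_bias = 2, n_witnesses = 100,
#'                       seed = 1)
#' @export
simulate_mock_witness <- function(k = 6L, suspect_bias = 0,
                                  n_witnesses, seed,
                                  suspect_index = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (suspect_bias < 0) stop("suspect_bias must be >= 0", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  n_witnesses <- as.integer(n_witnesses)
  if (n_witnesses < 0L) stop("n_witnesses must be >= 0", call. = FALSE)
  p_sus <- (1 + suspect_bias) / (k + suspect_bias)
  prob <- rep((1 - p_sus) / (k - 1L), k)
  prob[suspect_index] <- p_sus
  set.seed(as.integer(seed))
  counts <- if (n_witnesses > 0L) as.integer(rmultinom(1L, n_witnesses,
                                                       prob))
            else integer(k)
  out <- choice_distribution(counts, suspect_index)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Parameter recovery study
#'
#' Repeatedly simulates data from known parameter values, refits the
#' model under the supplied restrictions, and summarises recovery per
#' free parameter group: mean estimate, bias, empirical SD, root mean
#' squared error, mean estimated standard error, and coverage of the
#' +/- 2 SE Wald interval.  Fit failures are counted, not fatal.
#'
#' @param params List of [mpt_params()], one per condition (the truth).
#' @param n_participants Participants per condition.
#' @param restrictions A [restriction_set()] over the simulated condition
#'   labels, or a function of the simulated [lineup_data()] returning one
#'   (e.g. [base_restrictions]).
#' @param replications Number of Monte Carlo replications.
#' @param seed Integer master seed; replication `r` uses `seed + r`.
#' @param labels,lineup_format,filler_type Passed to
#'   [simulate_eyewitness()].
#' @param n_starts Optimiser starts per fit (2 is plenty at realistic n).
#' @return A data frame of class `"recovery_summary"` with one row per
#'   free group; attribute `n_failed` counts failed fits.  Groups whose
#'   slots mix different generating values get `true = NA`.
#' @export
parameter_recovery_study <- function(params, n_participants, restrictions,
                                     replications, seed,
                                     labels = NULL,
                                     lineup_format = "simultaneous",
                                     filler_type = "non-morphed",
                                     n_starts = 2L) {
  stopifnot(replications >= 1L)
  if (inherits(params, "mpt_params")) params <- list(params)
  C <- length(params)
  if (is.null(labels)) labels <- paste0("cond", seq_len(C))

  template <- simulate_eyewitness(params, n_participants, labels,
                                  lineup_format, filler_type, seed = seed)
  rs <- if (is.function(restrictions)) restrictions(template)
        else restrictions
  stopifnot(inherits(rs, "restriction_set"))
  free <- setdiff(unique(rs$map$group), names(rs$fixed))

  # generating value per group; NA when slots disagree
  truth <- vapply(free, function(g) {
    sl <- rs$map[rs$map$group == g, ]
    vals <- mapply(function(cond, par) params[[match(cond, labels)]][[par]],
                   sl$condition, sl$parameter)
    if (max(vals) - min(vals) < 1e-12) vals[[1]] else NA_real_
  }, numeric(1))

  est <- se <- matrix(NA_real_, replications, length(free),
                      dimnames = list(NULL, free))
  n_failed <- 0L
  for (r in seq_len(replications)) {
    sim <- simulate_eyewitness(params, n_participants, labels,
                               lineup_format, filler_type,
                               seed = seed + r)
    fit <- tryCatch(
      suppressWarnings(fit_mpt(sim, rs, n_starts = n_starts,
                               seed = seed + r)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { n_failed <- n_failed + 1L; next }
    est[r, names(fit$estimates)] <- fit$estimates
    se[r, names(fit$std_errors)] <- fit$std_errors
  }

  cover <- vapply(free, function(g) {
    ok <- !is.na(est[, g]) & !is.na(se[, g]) & !is.na(truth[[g]])
    if (!any(ok)) return(NA_real_)
    mean(abs(est[ok, g] - truth[[g]]) <= 2 * se[ok, g])
  }, numeric(1))

  out <- data.frame(
    group = free,
    true = truth,
    mean_estimate = colMeans(est, na.rm = TRUE),
    bias = colMeans(est, na.rm = TRUE) - truth,
    empirical_sd = apply(est, 2, stats::sd, na.rm = TRUE),
    rmse = sqrt(colMeans((est - rep(truth, each = replications))^2,
                         na.rm = TRUE)),
    mean_se = colMeans(se, na.rm = TRUE),
    coverage_2se = cover,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_failed") <- n_failed
  attr(out, "replications") <- replications
  class(out) <- c("recovery_summary", "data.frame")
  out
}
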