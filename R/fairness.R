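#' Tredoux's E effective lineup size
#'
#' The reciprocal of the sum of squared choice proportions,
#' \deqn{E = 1 / \sum_i p_i^2,}
#' where \eqn{p_i} is the proportion of choices falling on lineup member
#' `i`.  `E` ranges from 1 (every choice on a single member) to `k`, the
#' nominal lineup size (choices evenly distributed); it estimates the
#' number of lineup members that function as plausible alternatives.
#' This is the point-value formulation, without the sampling-variance
#' correction or confidence interval of the original derivation.
#'
#' @param dist A [choice_distribution()] or a bare vector of non-negative
#'   counts.
#' @return Effective size, a number in `[1, k]`.
#' @examples
#' tredoux_e(c(50, 10, 10, 10, 10, 10))  # 3.33
#' @export
tredoux_e <- function(dist) {
  counts <- choice_counts(dist)
  total <- sum(counts)
  if (total <= 0) stop("choice distribution is empty", call. = FALSE)
  p <- counts / total
  1 / sum(p^2)
}

#' Resultant Tredoux's E from culprit-absent identifications
#'
#' Mathematically identical to [tredoux_e()]; the distinction is the
#' provenance of the counts: the distribution of eyewitness
#' identifications across the members of culprit-absent lineups
#' (rejections excluded), rather than mock-witness choices.  Fairness
#' computed this way is called "resultant" lineup fairness.
#'
#' @inheritParams tredoux_e
#' @return Effective size, a number in `[1, k]`.
#' @export
resultant_tredoux_e <- function(dist) tredoux_e(dist)

#' Proportion of suspect selections
#'
#' The share of choices falling on the suspect; `1/k` indicates a
#' perfectly fair lineup, larger values indicate that the suspect stands
#' out.
#'
#' @param dist A [choice_distribution()].
#' @param suspect_index Suspect position, only needed when `dist` is a
#'   bare count vector.
#' @return A proportion in `[0, 1]`.
#' @export
proportion_suspect <- function(dist, suspect_index = 1L) {
  counts <- choice_counts(dist)
  if (inherits(dist, "choice_distribution"))
    suspect_index <- dist$suspect_index
  total <- sum(counts)
  if (total <= 0) stop("choice distribution is empty", call. = FALSE)
  counts[[suspect_index]] / total
}

choice_counts <- function(dist) {
  if (inherits(dist, "choice_distribution")) return(dist$counts)
  if (is.numeric(dist)) {
    if (any(dist < 0) || length(dist) < 2L)
      stop("counts must be >= 2 non-negative numbers", call. = FALSE)
    return(dist)
  }
  stop("expected a choice_distribution or a count vector", call. = FALSE)
}

#' Resultant proportion of suspect selections
#'
#' Computed from eyewitness responses to culprit-absent lineups:
#' innocent-suspect identifications divided by all identifications
#' (innocent-suspect plus filler) in culprit-absent lineups.  Rejections
#' do not enter the denominator.
#'
#' @param data A [lineup_data()] object.
#' @return A named numeric vector, one proportion per condition.
#' @examples
#' d <- load_fixture("exp2")
#' round(resultant_suspect_proportion(d), 2)
#' @export
resultant_suspect_proportion <- function(data) {
  stopifnot(inherits(data, "lineup_data"))
  denom <- data$ca_suspect + data$ca_filler
  if (any(denom <= 0))
    stop("no culprit-absent identifications in condition(s): ",
         paste(data$condition[denom <= 0], collapse = ", "), call. = FALSE)
  setNames(data$ca_suspect / denom, data$condition)
}

#' Overall identification rate
#'
#' The proportion of lineup decisions that were identifications (suspect
#' or filler, in both culprit-present and culprit-absent lineups) rather
#' than rejections, pooled over the supplied conditions.
#'
#' @param data A [lineup_data()] object; subset rows to pool over a
#'   specific lineup format.
#' @return A single proportion.
#' @examples
#' d <- load_fixture("exp2")
#' identification_rate(d[d$lineup_format == "sequential", ])  # 0.81
#' @export
identification_rate <- function(data) {
  data <- as_lineup_data(data)
  ids <- sum(data$cp_suspect, data$cp_filler, data$ca_suspect,
             data$ca_filler)
  total <- ids + sum(data$cp_reject, data$ca_reject)
  if (total <= 0) stop("no decisions in the data", call. = FALSE)
  ids / total
}

#' Average fairness measures over several lineups
#'
#' The convention for multi-lineup conditions: Tredoux's E is computed
#' separately per lineup and then averaged arithmetically; the proportion
#' of suspect selections is pooled across lineups weighted by their
#' choice counts (with equal counts per lineup the two conventions
#' coincide).
#'
#' @param dists A list of [choice_distribution()] objects.
#' @return A list with `mean_e` and `prop_suspect`.
#' @export
average_fairness <- function(dists) {
  stopifnot(length(dists) >= 1L)
  es <- vapply(dists, tredoux_e, numeric(1))
  sus <- vapply(dists, function(d) d$counts[[d$suspect_index]], numeric(1))
  tot <- vapply(dists, function(d) sum(d$counts), numeric(1))
  list(mean_e = mean(es), prop_suspect = sum(sus) / sum(tot))
}
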