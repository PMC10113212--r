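#' Parameters of the 2-HT eyewitness identification model
#'
#' Bundles the four latent-process probabilities of the two-high-threshold
#' eyewitness identification model together with the lineup size.  The
#' lineup size is a design constant (the number of photographs shown), not
#' an estimated quantity: it enters the model only through the `1/k` split
#' of guessing-based selections between the suspect and the fillers.
#'
#' @param dP Probability of detecting the presence of the culprit
#'   (culprit-present lineups only).
#' @param b Probability of biased suspect selection: choosing the suspect
#'   without memory because the suspect stands out from the fillers.  This
#'   is the model's lineup-unfairness measure.
#' @param g Probability of guessing-based selection among the lineup
#'   members when neither detection nor biased selection has occurred.
#' @param dA Probability of detecting the absence of the culprit
#'   (culprit-absent lineups only).
#' @param lineup_size Number of lineup members, an integer `>= 2`.
#'   Defaults to 6, the conventional six-person photo lineup.
#'
#' @return An object of class `"mpt_params"`.
#' @examples
#' p <- mpt_params(dP = 0.27, b = 0.2, g = 0.59, dA = 0.04)
#' predict_categories(p)
#' @export
mpt_params <- function(dP, b, g, dA, lineup_size = 6L) {
  x <- structure(
    list(dP = as.numeric(dP), b = as.numeric(b), g = as.numeric(g),
         dA = as.numeric(dA), lineup_size = as.integer(lineup_size)),
    class = "mpt_params")
  validate_mpt_params(x)
  x
}

validate_mpt_params <- function(x) {
  for (nm in PARAM_NAMES) {
    v <- x[[nm]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("parameter '", nm, "' must be a single probability in [0, 1], got ",
           deparse(v), call. = FALSE)
  }
  k <- x$lineup_size
  if (length(k) != 1L || is.na(k) || k < 2L)
    stop("parameter 'lineup_size' must be an integer >= 2, got ",
         deparse(k), call. = FALSE)
  invisible(x)
}

#' @export
print.mpt_params <- function(x, ...) {
  cat("2-HT eyewitness identification model parameters\n")
  cat(sprintf("  dP = %.4f  b = %.4f  g = %.4f  dA = %.4f  (k = %d)\n",
              x$dP, x$b, x$g, x$dA, x$lineup_size))
  invisible(x)
}

#' Predicted response-category probabilities
#'
#' Maps model parameters onto the six observable response categories: for
#' culprit-present lineups, culprit identifications (`cp_suspect`), filler
#' identifications (`cp_filler`) and rejections (`cp_reject`); for
#' culprit-absent lineups, innocent-suspect identifications (`ca_suspect`),
#' filler identifications (`ca_filler`) and rejections (`ca_reject`).
#'
#' With `k` the lineup size, the culprit-present tree gives
#' \deqn{P(suspect) = dP + (1-dP)b + (1-dP)(1-b)g/k}
#' \deqn{P(filler)  = (1-dP)(1-b)g(1 - 1/k)}
#' \deqn{P(reject)  = (1-dP)(1-b)(1-g)}
#' and the culprit-absent tree
#' \deqn{P(suspect) = (1-dA)b + (1-dA)(1-b)g/k}
#' \deqn{P(filler)  = (1-dA)(1-b)g(1 - 1/k)}
#' \deqn{P(reject)  = dA + (1-dA)(1-b)(1-g).}
#' The exact value `1/k` is used throughout (not a rounded decimal), so each
#' tree's three probabilities sum to 1 identically.
#'
#' @param params An [mpt_params()] object.
#' @return A named numeric vector of length 6 in the canonical category
#'   order `cp_suspect, cp_filler, cp_reject, ca_suspect, ca_filler,
#'   ca_reject`, with attribute `lineup_size`.
#' @examples
#' # pure guessing splits 1 : (k - 1) between suspect and fillers
#' predict_categories(mpt_params(0, 0, 1, 0))
#' @export
predict_categories <- function(params) {
  validate_mpt_params(params)
  p <- category_probs(params$dP, params$b, params$g, params$dA,
                      params$lineup_size)
  structure(setNames(p, CATEGORIES), lineup_size = params$lineup_size)
}

# Closed-form tree probabilities; vectorised over parameters.  Returns a
# length-6 vector (or 6-column matrix) in canonical category order.
category_probs <- function(dP, b, g, dA, k) {
  u <- 1 / k
  cbind(dP + (1 - dP) * b + (1 - dP) * (1 - b) * g * u,
        (1 - dP) * (1 - b) * g * (1 - u),
        (1 - dP) * (1 - b) * (1 - g),
        (1 - dA) * b + (1 - dA) * (1 - b) * g * u,
        (1 - dA) * (1 - b) * g * (1 - u),
        dA + (1 - dA) * (1 - b) * (1 - g))[if (length(dP) == 1L) 1L else TRUE, ]
}

#' Experimental condition metadata
#'
#' Describes one between-participants lineup condition: its label, the
#' lineup format, the filler type, and the number of culprit-present and
#' culprit-absent lineup trials observed in it.
#'
#' @param label Unique identifier string.
#' @param lineup_format `"simultaneous"` or `"sequential"`.
#' @param filler_type `"morphed"` or `"non-morphed"`.
#' @param n_culprit_present,n_culprit_absent Non-negative trial counts.
#' @return An object of class `"lineup_condition"`.
#' @export
lineup_condition <- function(label, lineup_format, filler_type,
                             n_culprit_present, n_culprit_absent) {
  lineup_format <- match.arg(lineup_format, LINEUP_FORMATS)
  filler_type <- match.arg(filler_type, FILLER_TYPES)
  ncp <- as.integer(n_culprit_present)
  nca <- as.integer(n_culprit_absent)
  if (is.na(ncp) || ncp < 0L || is.na(nca) || nca < 0L)
    stop("trial counts must be non-negative integers", call. = FALSE)
  structure(list(label = as.character(label), lineup_format = lineup_format,
                 filler_type = filler_type, n_culprit_present = ncp,
                 n_culprit_absent = nca),
            class = "lineup_condition")
}

#' Expected category counts under given parameters
#'
#' Multiplies each tree's predicted category probabilities by that tree's
#' trial count.  Per-tree sums equal the trial counts exactly, which is the
#' conservation property the G-squared statistic relies on.
#'
#' @param params An [mpt_params()] object.
#' @param condition A [lineup_condition()] object supplying the trial
#'   counts.
#' @return A named numeric vector of length 6 (canonical category order)
#'   of real-valued expected counts.
#' @export
expected_counts <- function(params, condition) {
  stopifnot(inherits(condition, "lineup_condition"))
  p <- predict_categories(params)
  n <- rep(c(condition$n_culprit_present, condition$n_culprit_absent),
           each = 3L)
  setNames(as.numeric(p) * n, CATEGORIES)
}
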