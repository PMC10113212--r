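#' Export the model in the MPT equation-file (.eqn) format
#'
#' Writes the branch structure of the 2-HT eyewitness identification model
#' in the de facto `.eqn` dialect used by the classic MPT fitting tools:
#' the first line gives the number of branch lines that follow; every other
#' line is `tree category product-of-parameters`, complements written as
#' `(1-param)`.  One tree block pair (culprit-present, culprit-absent) is
#' emitted per condition, with parameters suffixed by the condition label
#' (e.g. `dP_simM`).  The guessing split constant `1/k` is written as the
#' parameter `u_<label>`, which consumers must treat as fixed at
#' `1/lineup_size`; this keeps the file within the plain product-term
#' dialect, which has no numeric literals.
#'
#' Each condition contributes 10 branch lines: five culprit-present paths
#' (three terminating in a suspect identification, one in a filler
#' identification, one in a rejection) and five culprit-absent paths (two
#' suspect, one filler, two rejection).
#'
#' @param condition_labels Character vector of condition labels.
#' @param lineup_size Lineup size recorded in a trailing comment.
#' @return A character scalar holding the equation file text.
#' @seealso [parse_eqn()] for the inverse, and [eval_eqn()] which sums the
#'   parsed branch products into category probabilities.
#' @examples
#' cat(serialize_eqn("simM"))
#' @export
serialize_eqn <- function(condition_labels, lineup_size = 6L) {
  stopifnot(length(condition_labels) >= 1L, !anyDuplicated(condition_labels))
  lines <- character(0)
  for (lab in condition_labels) {
    p <- function(nm) paste0(nm, "_", lab)
    cp <- paste0(lab, ".cp")
    ca <- paste0(lab, ".ca")
    dP <- p("dP"); b <- p("b"); g <- p("g"); dA <- p("dA"); u <- p("u")
    nd <- paste0("(1-", dP, ")"); nb <- paste0("(1-", b, ")")
    ng <- paste0("(1-", g, ")"); na <- paste0("(1-", dA, ")")
    nu <- paste0("(1-", u, ")")
    lines <- c(
      lines,
      paste(cp, "cp_suspect", dP),
      paste(cp, "cp_suspect", paste(nd, b, sep = "*")),
      paste(cp, "cp_suspect", paste(nd, nb, g, u, sep = "*")),
      paste(cp, "cp_filler",  paste(nd, nb, g, nu, sep = "*")),
      paste(cp, "cp_reject",  paste(nd, nb, ng, sep = "*")),
      paste(ca, "ca_suspect", paste(na, b, sep = "*")),
      paste(ca, "ca_suspect", paste(na, nb, g, u, sep = "*")),
      paste(ca, "ca_filler",  paste(na, nb, g, nu, sep = "*")),
      paste(ca, "ca_reject",  dA),
      paste(ca, "ca_reject",  paste(na, nb, ng, sep = "*")))
  }
  paste0(length(lines), "\n", paste(lines, collapse = "\n"),
         "\n# u_* fixed at 1/", lineup_size, " (guessing split constant)\n")
}

#' Parse an MPT equation file
#'
#' Reads the `.eqn` dialect written by [serialize_eqn()]: a leading
#' branch-count line, then `tree category term` lines where `term` is a
#' `*`-separated product of parameter names and `(1-name)` complements.
#' Lines starting with `#` are comments.
#'
#' @param text Equation-file text (character scalar or vector of lines).
#' @return A data frame of class `"mpt_eqn"` with columns `tree`,
#'   `category` and a list column `factors`; each factor is a
#'   `(name, complement)` pair.
#' @export
parse_eqn <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty equation file", call. = FALSE)
  n_declared <- suppressWarnings(as.integer(lines[[1]]))
  body <- lines[-1]
  if (!is.na(n_declared) && n_declared != length(body))
    stop("declared branch count (", n_declared, ") does not match body (",
         length(body), " lines)", call. = FALSE)
  parts <- strsplit(body, "[[:space:]]+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed branch line ", bad[[1]] + 1L, ": ", body[[bad[[1]]]],
         call. = FALSE)
  parse_term <- function(term) {
    f <- strsplit(term, "*", fixed = TRUE)[[1]]
    comp <- grepl("^\\(1-.+\\)$", f)
    name <- ifelse(comp, sub("^\\(1-(.+)\\)$", "\\1", f), f)
    data.frame(name = name, complement = comp, stringsAsFactors = FALSE)
  }
  out <- data.frame(tree = vapply(parts, `[[`, "", 1L),
                    category = vapply(parts, `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  out$factors <- lapply(vapply(parts, `[[`, "", 3L), parse_term)
  class(out) <- c("mpt_eqn", "data.frame")
  out
}

#' Evaluate a parsed equation file at given parameter values
#'
#' Sums branch products by category, i.e. performs the path-enumeration
#' computation of the category probabilities.  This is deliberately an
#' independent route to the same quantities as [predict_categories()] and
#' is used as its oracle in the test suite.
#'
#' @param eqn An object from [parse_eqn()].
#' @param values Named numeric vector supplying every parameter name used
#'   in the file (including the `u_*` split constants).
#' @return Named numeric vector of summed branch probabilities per
#'   category (names are `tree.category` collapsed to `category` when
#'   unambiguous, otherwise `tree:category`).
#' @export
eval_eqn <- function(eqn, values) {
  stopifnot(inherits(eqn, "mpt_eqn"))
  branch <- vapply(eqn$factors, function(f) {
    v <- values[f$name]
    if (anyNA(v))
      stop("missing value for parameter(s): ",
           paste(f$name[is.na(v)], collapse = ", "), call. = FALSE)
    prod(ifelse(f$complement, 1 - v, v))
  }, numeric(1))
  key <- paste(eqn$tree, eqn$category, sep = ":")
  tapply(branch, key, sum)
}
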