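#' Equality restrictions across conditions
#'
#' A restriction set maps every (condition, parameter) slot of a joint
#' multi-condition model onto a named free parameter group; slots in the
#' same group are constrained to be equal, and a group may instead be fixed
#' at a constant.  This is the device behind "base models" in MPT
#' analyses: e.g. one shared culprit-absence-detection probability across
#' all conditions.
#'
#' @param conditions Character vector of condition labels the set covers.
#' @param share Named list describing equality constraints.  Each element
#'   is named after a model parameter (`dP`, `b`, `g`, `dA`) and is either
#'   the string `"all"` (share across every condition) or a character
#'   vector / list of character vectors of condition labels to tie
#'   together.  Slots not mentioned remain condition-specific free
#'   parameters.
#' @param fix Optional list of `list(param =, conditions =, value =)`
#'   entries fixing a (possibly shared) slot group at a constant in
#'   `[0, 1]`.  `conditions = "all"` is allowed.
#' @return An object of class `"restriction_set"` with elements
#'   `conditions`, `map` (a data frame `condition, parameter, group`) and
#'   `fixed` (named numeric vector by group).
#' @examples
#' rs <- restriction_set(
#'   c("simM", "simN", "seqM", "seqN"),
#'   share = list(dA = "all",
#'                dP = list(c("simM", "simN"), c("seqM", "seqN")),
#'                g  = list(c("simM", "simN"), c("seqM", "seqN"))))
#' n_free_groups(rs)
#' @export
restriction_set <- function(conditions, share = list(), fix = list()) {
  conditions <- as.character(conditions)
  if (!length(conditions) || anyDuplicated(conditions))
    stop("conditions must be a non-empty set of unique labels",
         call. = FALSE)
  map <- expand.grid(condition = conditions, parameter = PARAM_NAMES,
                     stringsAsFactors = FALSE)
  map$group <- paste0(map$parameter, "[", map$condition, "]")

  assign_group <- function(map, param, conds) {
    if (identical(conds, "all")) conds <- conditions
    conds <- as.character(conds)
    unknown <- setdiff(conds, conditions)
    if (length(unknown))
      stop("unknown condition(s) in restriction: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (length(conds) < 2L && !identical(conds, conditions))
      stop("a shared group needs at least two conditions", call. = FALSE)
    sel <- map$parameter == param & map$condition %in% conds
    gname <- paste0(param, "[", paste(conds, collapse = "+"), "]")
    if (any(map$group[sel] != paste0(param, "[", map$condition[sel], "]")))
      stop("slot (", param, ") assigned to more than one shared group",
           call. = FALSE)
    map$group[sel] <- gname
    map
  }
  for (param in names(share)) {
    if (!param %in% PARAM_NAMES)
      stop("unknown parameter in share: ", param, call. = FALSE)
    spec <- share[[param]]
    if (identical(spec, "all") || is.character(spec))
      spec <- list(spec)
    for (conds in spec) map <- assign_group(map, param, conds)
  }

  fixed <- numeric(0)
  for (fx in fix) {
    if (!all(c("param", "value") %in% names(fx)))
      stop("each fix entry needs 'param' and 'value'", call. = FALSE)
    conds <- if (is.null(fx$conditions)) "all" else fx$conditions
    if (identical(conds, "all")) conds <- conditions
    sel <- map$parameter == fx$param & map$condition %in% conds
    if (!any(sel))
      stop("fix entry matches no slot", call. = FALSE)
    grp <- unique(map$group[sel])
    val <- as.numeric(fx$value)
    if (is.na(val) || val < 0 || val > 1)
      stop("fixed values must lie in [0, 1]", call. = FALSE)
    fixed[grp] <- val
  }

  structure(list(conditions = conditions, map = map, fixed = fixed),
            class = "restriction_set")
}

#' @rdname restriction_set
#' @param x A `restriction_set`.
#' @export
n_free_groups <- function(x) {
  stopifnot(inherits(x, "restriction_set"))
  length(setdiff(unique(x$map$group), names(x$fixed)))
}

#' @export
print.restriction_set <- function(x, ...) {
  cat("restriction set over", length(x$conditions), "condition(s):",
      paste(x$conditions, collapse = ", "), "\n")
  grp <- split(paste0(x$map$parameter, "(", x$map$condition, ")"),
               x$map$group)
  for (g in names(grp)) {
    fx <- if (g %in% names(x$fixed))
      sprintf("  [fixed at %.4g]", x$fixed[[g]]) else ""
    cat("  ", g, " <- ", paste(grp[[g]], collapse = " = "), fx, "\n",
        sep = "")
  }
  cat("free parameter groups:", n_free_groups(x), "\n")
  invisible(x)
}

#' The base-model restrictions of the lineup-fairness analysis
#'
#' Builds the standard base model used throughout the multi-condition
#' analyses: culprit-absence detection `dA` shared across all conditions;
#' culprit-presence detection `dP` and guessing-based selection `g` each
#' shared among the conditions of the same lineup format (simultaneous,
#' sequential); biased suspect selection `b` free per condition.  With
#' four conditions this leaves 9 free parameter groups and 7 degrees of
#' freedom for the goodness-of-fit test.
#'
#' @param data A [lineup_data()] object (the `lineup_format` column drives
#'   the within-format sharing).
#' @return A [restriction_set()].
#' @export
base_restrictions <- function(data) {
  stopifnot(inherits(data, "lineup_data"))
  by_format <- split(data$condition, data$lineup_format)
  by_format <- by_format[lengths(by_format) >= 2L]
  share <- list(dA = "all")
  if (length(by_format)) {
    share$dP <- unname(by_format)
    share$g <- unname(by_format)
  }
  restriction_set(data$condition, share = share)
}

#' Add an equality restriction to an existing set
#'
#' Merges the free groups currently holding `parameter` in the given
#' conditions into a single group.  This is how nested models are built
#' for Delta-G-squared tests (e.g. restricting `b` to be equal between a
#' morphed and a non-morphed condition).
#'
#' @param x A [restriction_set()].
#' @param parameter One of `dP`, `b`, `g`, `dA`.
#' @param conditions Labels whose slots are tied together (or `"all"`).
#' @return A new `restriction_set` with one fewer (or equally many) free
#'   groups.
#' @export
restrict_equal <- function(x, parameter, conditions) {
  stopifnot(inherits(x, "restriction_set"))
  parameter <- match.arg(parameter, PARAM_NAMES)
  if (identical(conditions, "all")) conditions <- x$conditions
  unknown <- setdiff(conditions, x$conditions)
  if (length(unknown))
    stop("unknown condition(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sel <- x$map$parameter == parameter & x$map$condition %in% conditions
  old <- unique(x$map$group[sel])
  if (any(old %in% names(x$fixed)))
    stop("cannot merge a fixed group; unfix it first", call. = FALSE)
  take <- x$map$group %in% old
  conds_all <- sort(unique(x$map$condition[take]))
  gname <- paste0(parameter, "[", paste(conds_all, collapse = "+"), "]")
  x$map$group[take] <- gname
  x
}

#' Read a restriction configuration from JSON
#'
#' Schema:
#' \preformatted{
#' {"share": [{"param": "dA", "conditions": "all"},
#'            {"param": "dP", "conditions": ["simM", "simN"]}],
#'  "fix":   [{"param": "g", "conditions": ["seqM"], "value": 0.5}]}
#' }
#'
#' @param path Path to a JSON file.
#' @param conditions Condition labels of the data the restrictions apply
#'   to.
#' @return A [restriction_set()].
#' @export
read_restrictions <- function(path, conditions) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  share <- list()
  for (s in cfg$share) {
    conds <- if (identical(s$conditions, "all")) "all"
             else unlist(s$conditions)
    share[[s$param]] <- c(share[[s$param]], list(conds))
  }
  fix <- lapply(cfg$fix, function(f)
    list(param = f$param,
         conditions = if (is.null(f$conditions) ||
                          identical(f$conditions, "all")) "all"
                      else unlist(f$conditions),
         value = f$value))
  restriction_set(conditions, share = share, fix = fix)
}

# Partition-refinement test: TRUE when `restricted` can be obtained from
# `base` by merging base groups (and keeping fixes consistent), i.e. the
# two models are strictly nested with `restricted` the smaller one.
is_refinement <- function(base, restricted) {
  if (!setequal(base$conditions, restricted$conditions)) return(FALSE)
  key <- paste(base$map$condition, base$map$parameter)
  rmap <- restricted$map$group[match(key, paste(restricted$map$condition,
                                                restricted$map$parameter))]
  # every base group must land in exactly one restricted group
  ok <- all(tapply(rmap, base$map$group, function(g) length(unique(g)) == 1L))
  ok && identical_fixed(base, restricted, rmap)
}

identical_fixed <- function(base, restricted, rmap) {
  # a fix in the base must persist with the same value in the restricted
  for (g in names(base$fixed)) {
    tg <- unique(rmap[base$map$group == g])
    if (!(tg %in% names(restricted$fixed)) ||
        restricted$fixed[[tg]] != base$fixed[[g]]) return(FALSE)
  }
  TRUE
}

#' Degrees of freedom of a joint fit
#'
#' Each non-empty tree (two per condition: culprit-present and
#' culprit-absent) contributes two free category proportions; the free
#' parameter groups of the restriction set are subtracted.
#'
#' @param data A [lineup_data()] object.
#' @param restrictions A [restriction_set()] covering `data`'s conditions;
#'   `NULL` means all 4 parameters free per condition.
#' @return Integer degrees of freedom.
#' @export
mpt_df <- function(data, restrictions = NULL) {
  stopifnot(inherits(data, "lineup_data"))
  if (is.null(restrictions))
    restrictions <- restriction_set(data$condition)
  if (!setequal(restrictions$conditions, data$condition))
    stop("restriction set does not cover the data's conditions",
         call. = FALSE)
  tc <- trial_counts(data)
  n_trees <- sum(tc$n_culprit_present > 0) + sum(tc$n_culprit_absent > 0)
  df <- 2L * n_trees - n_free_groups(restrictions)
  if (df < 0L)
    stop("model is over-parameterized: ", n_free_groups(restrictions),
         " free groups for ", 2L * n_trees, " independent categories",
         call. = FALSE)
  df
}
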