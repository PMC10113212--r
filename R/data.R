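#' Observed response-frequency tables
#'
#' A `lineup_data` object holds one row per experimental condition with the
#' six observed response-category counts (the sufficient statistics of the
#' 2-HT model): culprit identifications, filler identifications and
#' rejections from culprit-present lineups, and innocent-suspect
#' identifications, filler identifications and rejections from
#' culprit-absent lineups.
#'
#' @param condition Character vector of unique condition labels.
#' @param lineup_format `"simultaneous"` or `"sequential"`, recycled.
#' @param filler_type `"morphed"` or `"non-morphed"`, recycled.
#' @param cp_suspect,cp_filler,cp_reject Culprit-present counts.
#' @param ca_suspect,ca_filler,ca_reject Culprit-absent counts.
#' @return A data frame of class `"lineup_data"` with the nine canonical
#'   columns.
#' @examples
#' lineup_data("simA", "simultaneous", "morphed", 177, 120, 101, 93, 161, 144)
#' @export
lineup_data <- function(condition, lineup_format, filler_type,
                        cp_suspect, cp_filler, cp_reject,
                        ca_suspect, ca_filler, ca_reject) {
  x <- data.frame(condition = as.character(condition),
                  lineup_format = as.character(lineup_format),
                  filler_type = as.character(filler_type),
                  cp_suspect = as.integer(cp_suspect),
                  cp_filler = as.integer(cp_filler),
                  cp_reject = as.integer(cp_reject),
                  ca_suspect = as.integer(ca_suspect),
                  ca_filler = as.integer(ca_filler),
                  ca_reject = as.integer(ca_reject),
                  stringsAsFactors = FALSE)
  class(x) <- c("lineup_data", "data.frame")
  validate_lineup_data(x)
}

#' @rdname lineup_data
#' @param x A data frame with the canonical `lineup_data` columns.
#' @export
as_lineup_data <- function(x) {
  need <- c("condition", "lineup_format", "filler_type", CATEGORIES)
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  do.call(lineup_data, as.list(x[need]))
}

validate_lineup_data <- function(x) {
  if (nrow(x) < 1L) stop("at least one condition is required", call. = FALSE)
  if (anyDuplicated(x$condition))
    stop("condition labels must be unique", call. = FALSE)
  if (!all(x$lineup_format %in% LINEUP_FORMATS))
    stop("lineup_format must be one of: ",
         paste(LINEUP_FORMATS, collapse = ", "), call. = FALSE)
  if (!all(x$filler_type %in% FILLER_TYPES))
    stop("filler_type must be one of: ",
         paste(FILLER_TYPES, collapse = ", "), call. = FALSE)
  cnt <- as.matrix(x[CATEGORIES])
  if (any(is.na(cnt)) || any(cnt < 0))
    stop("category counts must be non-negative integers", call. = FALSE)
  x
}

# counts matrix (conditions x 6) in canonical order
count_matrix <- function(data) {
  m <- as.matrix(data[CATEGORIES])
  rownames(m) <- data$condition
  storage.mode(m) <- "double"
  m
}

#' Trial counts per condition
#'
#' @param data A [lineup_data()] object.
#' @return A data frame with per-condition culprit-present and
#'   culprit-absent totals.
#' @export
trial_counts <- function(data) {
  data.frame(condition = data$condition,
             n_culprit_present = data$cp_suspect + data$cp_filler +
               data$cp_reject,
             n_culprit_absent = data$ca_suspect + data$ca_filler +
               data$ca_reject)
}

#' Read and write response-frequency tables as CSV
#'
#' The CSV schema has a mandatory header with columns
#' `condition,lineup_format,filler_type,cp_suspect,cp_filler,cp_reject,ca_suspect,ca_filler,ca_reject`.
#'
#' @param path File path.
#' @return `read_lineup_csv()` returns a [lineup_data()] object;
#'   `write_lineup_csv()` returns `path` invisibly.
#' @export
read_lineup_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  as_lineup_data(x)
}

#' @rdname read_lineup_csv
#' @param data A [lineup_data()] object.
#' @export
write_lineup_csv <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mock-witness choice distribution over lineup members
#'
#' Counts of choices falling on each of the `k` members of one lineup,
#' with the position of the suspect recorded.  This is the data structure
#' underlying Tredoux's E and the proportion of suspect selections; the
#' same structure describes "resultant" distributions built from
#' culprit-absent eyewitness identifications (rejections excluded).
#'
#' @param counts Non-negative integer vector, one entry per lineup member.
#' @param suspect_index Position of the suspect in `counts`.
#' @return An object of class `"choice_distribution"`.
#' @examples
#' choice_distribution(c(50, 10, 10, 10, 10, 10), suspect_index = 1)
#' @export
choice_distribution <- function(counts, suspect_index = 1L) {
  counts <- as.integer(counts)
  if (length(counts) < 2L || any(is.na(counts)) || any(counts < 0))
    stop("counts must be >= 2 non-negative integers", call. = FALSE)
  suspect_index <- as.integer(suspect_index)
  if (is.na(suspect_index) || suspect_index < 1L ||
      suspect_index > length(counts))
    stop("suspect_index out of bounds", call. = FALSE)
  structure(list(counts = counts, suspect_index = suspect_index,
                 k = length(counts)),
            class = "choice_distribution")
}

#' @export
print.choice_distribution <- function(x, ...) {
  cat(sprintf("choice distribution over %d lineup members (suspect at %d)\n",
              x$k, x$suspect_index))
  cat("  counts:", x$counts, "\n")
  invisible(x)
}

#' Read mock-witness choice counts from CSV
#'
#' Schema: `lineup_id,member_index,is_suspect,count`, one row per lineup
#' member, exactly one suspect per lineup.
#'
#' @param path File path.
#' @return A named list of [choice_distribution()] objects, one per
#'   `lineup_id`.
#' @export
read_choices_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("lineup_id", "member_index", "is_suspect", "count")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(split(x, x$lineup_id), function(d) {
    d <- d[order(d$member_index), ]
    s <- which(as.logical(d$is_suspect))
    if (length(s) != 1L)
      stop("each lineup must have exactly one suspect", call. = FALSE)
    choice_distribution(d$count, s)
  })
  out
}
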