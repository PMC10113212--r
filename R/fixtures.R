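# Registered fixtures: observed six-category response frequencies of the
# three eyewitness experiments (four between-participants conditions each)
# and the shared base-model restriction configuration.  Condition sample
# sizes (participants): exp2 199/190/196/198, exp3 197/180/195/188,
# exp4 183/200/194/184; each participant contributed four lineup
# decisions, two per tree, so every tree total must equal participants x 2.
fixture_registry <- function() {
  list(
    exp2 = list(file = "exp2.csv", participants = c(199, 190, 196, 198)),
    exp3 = list(file = "exp3.csv", participants = c(197, 180, 195, 188)),
    exp4 = list(file = "exp4.csv", participants = c(183, 200, 194, 184)),
    base_restrictions = list(file = "restrictions/base.json"))
}

#' Load a bundled dataset or restriction configuration
#'
#' Available fixtures: `"exp2"`, `"exp3"`, `"exp4"` (observed
#' response-frequency tables, four conditions each) and
#' `"base_restrictions"` (the shared base-model configuration: `dA` equal
#' across conditions, `dP` and `g` equal within lineup format, `b` free).
#' Tables are validated at load time: every tree total must equal the
#' recorded number of participants times two, so any transcription error
#' fails loudly.
#'
#' @param name Fixture name.
#' @return A [lineup_data()] object, or a [restriction_set()] for
#'   `"base_restrictions"`.
#' @examples
#' load_fixture("exp2")
#' @export
load_fixture <- function(name) {
  reg <- fixture_registry()
  if (!name %in% names(reg))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  entry <- reg[[name]]
  path <- system.file("extdata", entry$file, package = "lineupmpt",
                      mustWork = TRUE)
  if (name == "base_restrictions") {
    d <- load_fixture("exp2")  # canonical condition labels
    return(read_restrictions(path, d$condition))
  }
  d <- read_lineup_csv(path)
  tc <- trial_counts(d)
  expect <- entry$participants * 2L
  if (!all(tc$n_culprit_present == expect) ||
      !all(tc$n_culprit_absent == expect))
    stop("fixture '", name, "' failed the participants x 2 row-sum check",
         call. = FALSE)
  d
}
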