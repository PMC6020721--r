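#' Compose a QSM statement for a genetic test report
#'
#' Builds the standardized quality-assurance statement describing whether a
#' sample's test met its declared QSM, in one of three styles:
#' \itemize{
#'   \item `short`: `"This test met QSM C50_B10(85)_M20(95)"`;
#'   \item `full`: the short form plus `" using <tool chain>"`;
#'   \item `summary`: `"This test met QSM"` with no threshold text.
#' }
#' Regions that failed the QSM but are covered by `exception_labels` are
#' excluded from the claim and rendered as a trailing
#' `"{except <labels>}"` clause -- in the canonical styles "not met" is
#' expressed only through exceptions, the statement still reads "met".
#' Failing regions without a sanctioned exception label produce a
#' non-canonical "did not meet" variant listing them, flagged as such via
#' `canonical = FALSE` in the returned object.
#'
#' @param qsm A [qsm_spec()] (its own `exceptions` field is ignored here;
#'   exceptions come from the evaluations and labels).
#' @param evaluations An [evaluate_sample()] result, or a data frame with
#'   columns `region_name` and `pass_QSM`, from one sample.
#' @param style One of `"short"`, `"full"`, `"summary"`.
#' @param exception_labels Optional named character vector mapping region
#'   names to display labels (several regions may share one label, e.g. the
#'   exons of one gene grouped as `"PMS2 exons 12-15"`). Labels referencing
#'   unknown regions are an error.
#' @return An object of class `qsm_statement`: a list with `style`, `met`
#'   (`TRUE` iff every non-excepted region passed), `canonical`,
#'   `exceptions` (display labels in order of first appearance),
#'   `failing_regions` and `text`.
#' @export
make_statement <- function(qsm, evaluations,
                           style = c("short", "full", "summary"),
                           exception_labels = NULL) {
  stopifnot(inherits(qsm, "qsm_spec"))
  style <- match.arg(style)
  tab <- if (inherits(evaluations, "qsm_sample_eval")) evaluations$regions
         else evaluations
  stopifnot(is.data.frame(tab),
            all(c("region_name", "pass_QSM") %in% names(tab)))

  if (!is.null(exception_labels)) {
    if (is.null(names(exception_labels)) ||
        any(!nzchar(names(exception_labels))))
      stop("exception_labels must be named by region name", call. = FALSE)
    unknown <- setdiff(names(exception_labels), tab$region_name)
    if (length(unknown))
      stop("exception label refers to unknown region(s): ",
           paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }

  failing <- tab$region_name[!tab$pass_QSM]
  excepted <- intersect(failing, names(exception_labels))
  uncovered <- setdiff(failing, excepted)
  # display labels of excepted failing regions, deduplicated in order of
  # first appearance
  labels <- unique(unname(exception_labels[
    names(exception_labels)[names(exception_labels) %in% excepted]]))

  met <- length(uncovered) == 0L
  spec_txt <- switch(style,
    short = render_qsm(strip_exceptions(qsm), "short"),
    full = render_qsm(strip_exceptions(qsm), "full"),
    summary = "")
  head <- if (met) "This test met QSM" else "This test did not meet QSM"
  text <- if (nzchar(spec_txt)) paste(head, spec_txt) else head
  if (met && length(labels))
    text <- paste0(text, " {except ", paste(labels, collapse = ", "), "}")
  if (!met)
    text <- paste0(text, " (regions not meeting QSM: ",
                   paste(uncovered, collapse = ", "), ")")

  structure(
    list(style = style, met = met, canonical = met,
         exceptions = if (met) labels else character(),
         failing_regions = failing, text = text),
    class = "qsm_statement")
}

strip_exceptions <- function(qsm) {
  qsm$exceptions <- character()
  qsm
}

#' @export
print.qsm_statement <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' @export
format.qsm_statement <- function(x, ...) x$text
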