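#' Aggregate QSM evaluations across a cohort
#'
#' Counts, for each test region, the number of samples in which the QSM and
#' each individual metric were not met; flags regions failing the QSM in
#' more than `review_percent` percent of samples for review; and records
#' each sample's count of passing regions together with the cohort median.
#'
#' The review rule is a strict inequality evaluated on exact integers
#' (`100 * fails > review_percent * n_samples`), so with 960 samples and the
#' default 1% the minimal fail count triggering review is 10 (9.6 is the
#' exact 1% point), and with a single sample any failure triggers review.
#' The median of per-sample pass counts uses the lower-middle order
#' statistic for even cohort sizes, so it is always an observed count.
#'
#' @param evaluations A list of [evaluate_sample()] results, or of data
#'   frames with columns `region_name`, `pass_C`, `pass_B`, `pass_M` (and
#'   optionally `pass_QSM`, computed as the conjunction when absent), one
#'   per sample. All samples must share the same regions in the same order.
#'   Names supply sample identifiers.
#' @param review_percent Review threshold as a percentage of samples;
#'   default 1.
#' @return An object of class `qsm_cohort`: a list with `n_samples`,
#'   `qsm` (when available), `per_region_fail` (data frame: `region_name`,
#'   `fail_C`, `fail_B`, `fail_M`, `fail_QSM`, `review_flagged`),
#'   `review_flagged` (character vector of region names), `per_sample_pass`
#'   (named integer vector), `median_pass` and `review_percent`.
#' @export
summarize_cohort <- function(evaluations, review_percent = 1) {
  if (!is.list(evaluations) || !length(evaluations))
    stop("evaluations must be a non-empty list of per-sample evaluations",
         call. = FALSE)
  stopifnot(is.numeric(review_percent), length(review_percent) == 1L,
            review_percent >= 0)

  tabs <- lapply(evaluations, function(e) {
    tab <- if (inherits(e, "qsm_sample_eval")) e$regions else e
    stopifnot(is.data.frame(tab),
              all(c("region_name", "pass_C", "pass_B", "pass_M")
                  %in% names(tab)))
    if (is.null(tab$pass_QSM))
      tab$pass_QSM <- tab$pass_C & tab$pass_B & tab$pass_M
    tab
  })
  ids <- names(evaluations)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(seq_along(evaluations), function(i) {
      e <- evaluations[[i]]
      if (inherits(e, "qsm_sample_eval")) e$sample_id
      else paste0("sample", i)
    }, "")
  if (anyDuplicated(ids))
    stop("duplicate sample identifiers in cohort", call. = FALSE)

  ref <- tabs[[1]]$region_name
  same <- vapply(tabs, function(t) identical(t$region_name, ref), TRUE)
  if (!all(same))
    stop("samples were evaluated against different region sets (BED ",
         "mismatch): sample ", sQuote(ids[which(!same)[1]]),
         " does not match ", sQuote(ids[1]), call. = FALSE)
  qsms <- unique(unlist(lapply(evaluations, function(e)
    if (inherits(e, "qsm_sample_eval")) render_qsm(e$qsm))))
  if (length(qsms) > 1L)
    stop("samples were evaluated against different QSMs: ",
         paste(qsms, collapse = " vs "), call. = FALSE)

  n <- length(tabs)
  count_fail <- function(col)
    Reduce(`+`, lapply(tabs, function(t) as.integer(!t[[col]])))
  per_region <- data.frame(
    region_name = ref,
    fail_C = count_fail("pass_C"),
    fail_B = count_fail("pass_B"),
    fail_M = count_fail("pass_M"),
    fail_QSM = count_fail("pass_QSM"),
    stringsAsFactors = FALSE)
  per_region$review_flagged <-
    100 * per_region$fail_QSM > review_percent * n

  per_sample_pass <- vapply(tabs, function(t) sum(t$pass_QSM), 0L)
  names(per_sample_pass) <- ids

  structure(
    list(n_samples = n,
         qsm = if (length(qsms)) qsms else NULL,
         per_region_fail = per_region,
         review_flagged = per_region$region_name[per_region$review_flagged],
         per_sample_pass = per_sample_pass,
         median_pass = median_lower(per_sample_pass),
         review_percent = review_percent),
    class = "qsm_cohort")
}

# Lower-middle median: the ceiling(n/2)-th order statistic.  Deterministic
# and always an observed value, unlike the interpolating default.
median_lower <- function(x) {
  s <- sort(x)
  unname(s[ceiling(length(s) / 2)])
}

#' Per-region fail-count table for a cohort
#'
#' Tabulates, for every test region, the number of cohort samples failing
#' each metric and the QSM overall, with the review flag. Rows are ordered
#' by `fail_QSM` descending with region name ascending as the tiebreak, and
#' a final `TOTAL` row carries the column sums.
#'
#' @param summary A [summarize_cohort()] result.
#' @return A data frame with columns `region_name`, `fail_C`, `fail_B`,
#'   `fail_M`, `fail_QSM`, `review_flagged` (NA on the totals row).
#' @export
region_fail_table <- function(summary) {
  stopifnot(inherits(summary, "qsm_cohort"))
  t <- summary$per_region_fail
  ord <- order(-t$fail_QSM, t$region_name)
  t <- t[ord, , drop = FALSE]
  totals <- data.frame(region_name = "TOTAL",
                       fail_C = sum(t$fail_C), fail_B = sum(t$fail_B),
                       fail_M = sum(t$fail_M), fail_QSM = sum(t$fail_QSM),
                       review_flagged = NA, stringsAsFactors = FALSE)
  out <- rbind(t, totals)
  rownames(out) <- NULL
  out
}

#' @export
print.qsm_cohort <- function(x, ...) {
  cat("QSM cohort summary: ", x$n_samples, " samples",
      if (!is.null(x$qsm)) paste0(" against ", x$qsm), "\n",
      "  median regions passing per sample: ", x$median_pass, "\n",
      "  regions review-flagged (QSM failed in >", x$review_percent,
      "% of samples): ", length(x$review_flagged), "\n", sep = "")
  if (length(x$review_flagged))
    cat("  ", paste(x$review_flagged, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.qsm_cohort <- function(object, ...) {
  list(n_samples = object$n_samples,
       median_pass = object$median_pass,
       n_review_flagged = length(object$review_flagged),
       review_flagged = object$review_flagged)
}
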