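#' Evaluate one region against a QSM
#'
#' Applies the QSM pass rule to a per-base profile. A region passes a
#' metric only if 100% of its constituent bases pass that metric:
#' \itemize{
#'   \item C: every base has `depth >= X`;
#'   \item B: every base has at least `P_Y` percent of its aligned base
#'     calls at base quality `>= Y`;
#'   \item M: every base has at least `P_Z` percent of its covering reads
#'     at mapping quality `>= Z`.
#' }
#' All thresholds are inclusive. Percentage comparisons use exact
#' scaled-integer arithmetic, so a base at exactly the declared percentage
#' passes. Zero-depth bases fail B and M as well as C (absence of reads is
#' absence of evidence for base and mapping quality alike), unless the
#' corresponding percentage is 0. The region passes the QSM iff it passes
#' all three metrics; a region failing any metric is "QSM-flagged".
#'
#' @param profiles A [profile_region()] result (non-empty, one region).
#' @param qsm A [qsm_spec()].
#' @return An object of class `qsm_region_eval`: a list with
#'   `region_name`, logical `pass_C`, `pass_B`, `pass_M`, `pass_QSM`, and
#'   `first_fail`, a named integer vector giving the 1-based genomic
#'   position of the leftmost failing base per failing metric (empty when
#'   all pass).
#' @export
evaluate_region <- function(profiles, qsm) {
  stopifnot(inherits(qsm, "qsm_spec"))
  if (!is.data.frame(profiles) || nrow(profiles) == 0L)
    stop("profiles must be a non-empty per-base profile; a zero-width ",
         "region is a BED defect", call. = FALSE)
  req <- c("pos", "depth", "n_base", "n_bq_pass", "n_mq_pass")
  stopifnot(all(req %in% names(profiles)))

  ok_C <- profiles$depth >= qsm$X
  ok_B <- pct_at_least(profiles$n_bq_pass, profiles$n_base, qsm$P_Y)
  ok_M <- pct_at_least(profiles$n_mq_pass, profiles$depth, qsm$P_Z)

  first_fail <- integer(0)
  for (metric in c("C", "B", "M")) {
    ok <- switch(metric, C = ok_C, B = ok_B, M = ok_M)
    if (!all(ok)) {
      ff <- profiles$pos[which.min(ok)] + 1L  # 1-based genomic position
      first_fail[metric] <- ff
    }
  }

  structure(
    list(region_name = attr(profiles, "region_name") %||% NA_character_,
         pass_C = all(ok_C), pass_B = all(ok_B), pass_M = all(ok_M),
         pass_QSM = all(ok_C) && all(ok_B) && all(ok_M),
         first_fail = first_fail,
         n_bases = nrow(profiles)),
    class = "qsm_region_eval")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.qsm_region_eval <- function(x, ...) {
  verdict <- if (x$pass_QSM) "PASS" else "QSM-flagged"
  cat("region ", x$region_name, ": ", verdict,
      " (C=", x$pass_C, " B=", x$pass_B, " M=", x$pass_M, ")\n", sep = "")
  if (length(x$first_fail))
    cat("  first failing base: ",
        paste0(names(x$first_fail), "@", x$first_fail, collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Evaluate every region of a sample against a QSM
#'
#' Profiles and evaluates each BED region of one sample's BAM, in BED
#' order, and summarises how many regions met the QSM and each individual
#' metric.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param regions A [load_bed()] table (or path to a BED file).
#' @param qsm A [qsm_spec()] or QSM string.
#' @param policy A [read_filter_policy()].
#' @param sample_id Sample identifier; defaults to the BAM file basename
#'   without extension.
#' @param keep_profiles Keep the per-base profiles in the result (needed
#'   for per-base TSV output). Default `FALSE`.
#' @return An object of class `qsm_sample_eval`: a list with `sample_id`,
#'   `qsm`, `policy`, `regions` (the evaluation table: one row per region
#'   with pass flags and first-failing positions) and `summary`
#'   (`n_regions`, `n_pass`, `n_pass_C`, `n_pass_B`, `n_pass_M`).
#' @export
evaluate_sample <- function(bam, regions, qsm,
                            policy = read_filter_policy(),
                            sample_id = NULL, keep_profiles = FALSE) {
  if (is.character(qsm)) qsm <- parse_qsm(qsm)
  if (is.character(regions)) regions <- load_bed(regions)
  regions <- as_qsm_regions(regions)
  bf <- open_indexed_bam(bam)
  if (is.null(sample_id))
    sample_id <- tools::file_path_sans_ext(basename(
      if (inherits(bam, "BamFile")) Rsamtools::path(bam) else bam))

  profs <- vector("list", nrow(regions))
  evs <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    pr <- profile_region(bf, regions[i, ], qsm, policy)
    evs[[i]] <- evaluate_region(pr, qsm)
    if (keep_profiles) profs[[i]] <- pr
  }

  ffpos <- function(e, m) if (m %in% names(e$first_fail))
    e$first_fail[[m]] else NA_integer_
  tab <- data.frame(
    region_name = regions$name,
    chrom = regions$chrom,
    start = regions$start,
    end = regions$end,
    pass_C = vapply(evs, `[[`, TRUE, "pass_C"),
    pass_B = vapply(evs, `[[`, TRUE, "pass_B"),
    pass_M = vapply(evs, `[[`, TRUE, "pass_M"),
    pass_QSM = vapply(evs, `[[`, TRUE, "pass_QSM"),
    first_fail_C = vapply(evs, ffpos, 1L, "C"),
    first_fail_B = vapply(evs, ffpos, 1L, "B"),
    first_fail_M = vapply(evs, ffpos, 1L, "M"),
    stringsAsFactors = FALSE)

  structure(
    list(sample_id = sample_id,
         qsm = qsm,
         policy = policy,
         regions = tab,
         profiles = if (keep_profiles) stats::setNames(profs, regions$name),
         summary = list(n_regions = nrow(tab),
                        n_pass = sum(tab$pass_QSM),
                        n_pass_C = sum(tab$pass_C),
                        n_pass_B = sum(tab$pass_B),
                        n_pass_M = sum(tab$pass_M))),
    class = "qsm_sample_eval")
}

#' @export
print.qsm_sample_eval <- function(x, ...) {
  s <- x$summary
  cat("sample ", x$sample_id, " against QSM ", render_qsm(x$qsm), "\n",
      "  regions meeting QSM: ", s$n_pass, "/", s$n_regions,
      " (C: ", s$n_pass_C, ", B: ", s$n_pass_B, ", M: ", s$n_pass_M, ")\n",
      sep = "")
  flagged <- x$regions$region_name[!x$regions$pass_QSM]
  if (length(flagged))
    cat("  QSM-flagged: ", paste(flagged, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.qsm_sample_eval <- function(object, ...) {
  c(list(sample_id = object$sample_id, qsm = render_qsm(object$qsm)),
    object$summary)
}
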