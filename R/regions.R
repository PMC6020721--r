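#' Load test regions from a BED file
#'
#' Reads a BED file (tab-separated, at least three columns) of test regions.
#' Coordinates follow the BED convention -- 0-based, half-open -- and are
#' kept that way internally; user-facing reports print 1-based inclusive
#' coordinates. Column 4 supplies the region name when present; otherwise a
#' name is synthesised as `"chrom:start-end"` from the raw BED coordinates.
#' `track`, `browser`, comment (`#`) and blank lines are skipped. Region
#' names must be unique within a file. A strand column, if present, is
#' ignored: depth, base-quality and mapping-quality evaluation are all
#' strand-agnostic. Overlapping regions are allowed and evaluated
#' independently (densely tiled capture designs overlap by construction).
#'
#' @param path Path to a BED file.
#' @return A data frame of class `qsm_regions` with columns `chrom`,
#'   `start` (0-based), `end` (exclusive), `name` and `width`, in file
#'   order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr10\t89623194\t89623294\tPTEN_ex1", bed)
#' load_bed(bed)
#' @export
load_bed <- function(path) {
  if (!file.exists(path))
    stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track\\b|browser\\b|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    stop("BED file contains no data lines: ", path, call. = FALSE)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED line ", lineno[which(nf < 3L)[1]], " has fewer than 3 columns",
         call. = FALSE)

  chrom <- vapply(fields, `[`, "", 1L)
  start_s <- vapply(fields, `[`, "", 2L)
  end_s <- vapply(fields, `[`, "", 3L)
  bad_num <- !grepl("^[0-9]+$", start_s) | !grepl("^[0-9]+$", end_s)
  if (any(bad_num))
    stop("BED line ", lineno[which(bad_num)[1]],
         ": start/end are not non-negative integers", call. = FALSE)
  start <- as.numeric(start_s)
  end <- as.numeric(end_s)
  bad_iv <- end <= start
  if (any(bad_iv))
    stop("BED line ", lineno[which(bad_iv)[1]], ": end (", end[bad_iv][1],
         ") must be greater than start (", start[bad_iv][1], ")",
         call. = FALSE)

  name <- ifelse(nf >= 4L,
                 vapply(fields, function(f) f[4], ""),
                 NA_character_)
  synth <- is.na(name) | !nzchar(name)
  name[synth] <- paste0(chrom[synth], ":", start_s[synth], "-", end_s[synth])
  dup <- duplicated(name)
  if (any(dup))
    stop("BED line ", lineno[which(dup)[1]], ": duplicate region name ",
         sQuote(name[dup][1]), call. = FALSE)

  structure(
    data.frame(chrom = chrom, start = as.integer(start),
               end = as.integer(end), name = name,
               width = as.integer(end - start),
               stringsAsFactors = FALSE),
    class = c("qsm_regions", "data.frame"))
}

# Validate a regions table supplied directly (same contract as load_bed).
as_qsm_regions <- function(x) {
  if (inherits(x, "qsm_regions")) return(x)
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end", "name") %in% names(x)))
  if (any(x$end <= x$start)) stop("regions must have end > start",
                                  call. = FALSE)
  if (anyDuplicated(x$name)) stop("region names must be unique",
                                  call. = FALSE)
  structure(
    data.frame(chrom = as.character(x$chrom), start = as.integer(x$start),
               end = as.integer(x$end), name = as.character(x$name),
               width = as.integer(x$end - x$start), stringsAsFactors = FALSE),
    class = c("qsm_regions", "data.frame"))
}

# 1-based inclusive coordinate string for reports.
format_region_1based <- function(chrom, start0, end0) {
  paste0(chrom, ":", start0 + 1L, "-", end0)
}
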