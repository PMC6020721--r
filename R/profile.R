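#' Read filter policy for pileup profiling
#'
#' Controls which alignment records enter the per-base profile, expressed as
#' SAM flag exclusions. The defaults mirror common variant-caller read
#' intake: unmapped, secondary, supplementary, duplicate-marked and
#' QC-fail reads are excluded. Every switch is configurable so the policy
#' can be matched to the hard filters of the variant caller whose behaviour
#' the QSM is meant to reflect. The policy is recorded verbatim in every
#' output header for provenance.
#'
#' @param exclude_unmapped Drop unmapped reads (flag 0x4). Default `TRUE`.
#' @param exclude_secondary Drop secondary alignments (0x100). Default `TRUE`.
#' @param exclude_supplementary Drop supplementary alignments (0x800).
#'   Default `TRUE`.
#' @param exclude_duplicates Drop duplicate-marked reads (0x400). Default
#'   `TRUE`.
#' @param exclude_qcfail Drop QC-fail reads (0x200). Default `TRUE`.
#' @return An object of class `qsm_policy`.
#' @export
read_filter_policy <- function(exclude_unmapped = TRUE,
                               exclude_secondary = TRUE,
                               exclude_supplementary = TRUE,
                               exclude_duplicates = TRUE,
                               exclude_qcfail = TRUE) {
  p <- list(exclude_unmapped = isTRUE(exclude_unmapped),
            exclude_secondary = isTRUE(exclude_secondary),
            exclude_supplementary = isTRUE(exclude_supplementary),
            exclude_duplicates = isTRUE(exclude_duplicates),
            exclude_qcfail = isTRUE(exclude_qcfail))
  structure(p, class = "qsm_policy")
}

#' @export
format.qsm_policy <- function(x, ...) {
  paste(paste0(names(x), "=", unlist(x)), collapse = " ")
}

#' @export
print.qsm_policy <- function(x, ...) {
  cat("read filter policy:", format(x), "\n")
  invisible(x)
}

policy_scan_flag <- function(policy) {
  flg <- function(excl) if (excl) FALSE else NA
  Rsamtools::scanBamFlag(
    isUnmappedQuery = flg(policy$exclude_unmapped),
    isSecondaryAlignment = flg(policy$exclude_secondary),
    isSupplementaryAlignment = flg(policy$exclude_supplementary),
    isDuplicate = flg(policy$exclude_duplicates),
    isNotPassingQualityControls = flg(policy$exclude_qcfail))
}

# Open a BAM, insisting on a coordinate index; errors name the expected
# index path so pipelines can diagnose a missing .BAI immediately.
open_indexed_bam <- function(bam) {
  if (inherits(bam, "BamFile")) return(bam)
  if (!file.exists(bam))
    stop("BAM file not found: ", bam, call. = FALSE)
  idx <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
  hit <- idx[file.exists(idx)]
  if (!length(hit))
    stop("BAM index not found; expected ", idx[1], " (or ", idx[2], ")",
         call. = FALSE)
  Rsamtools::BamFile(bam, index = hit[1])
}

# Detect "chr10" vs "10" dialect mismatches between BED and BAM header.
check_chrom <- function(bamfile, chrom) {
  known <- names(Rsamtools::scanBamHeader(bamfile)$targets)
  if (chrom %in% known) return(invisible(TRUE))
  alt <- if (startsWith(chrom, "chr")) sub("^chr", "", chrom)
         else paste0("chr", chrom)
  if (alt %in% known)
    stop("chromosome-name dialect mismatch: BED uses ", sQuote(chrom),
         " but the BAM header uses ", sQuote(alt), call. = FALSE)
  stop("chromosome ", sQuote(chrom), " is absent from the BAM header (",
       "header names: ", paste(utils::head(known, 5), collapse = ", "),
       if (length(known) > 5) ", ..." else "", ")", call. = FALSE)
}

#' Per-base quality profile of one region
#'
#' Computes, for every reference position of a region, the four pileup
#' counts the QSM metrics are built on:
#' \describe{
#'   \item{`depth`}{reads whose alignment covers the position (metric C).
#'     CIGAR `D` (deletion) spans count -- a read aligned across a position
#'     attests to coverage even without a base call there -- while `N`
#'     (reference skip) spans do not.}
#'   \item{`n_base`}{covering reads that present an aligned base at the
#'     position (`M`/`=`/`X` operations only).}
#'   \item{`n_bq_pass`}{covering reads whose base call at the position has
#'     Phred base quality at least `Y` from the QSM.}
#'   \item{`n_mq_pass`}{covering reads with mapping quality at least `Z`
#'     from the QSM. A MAPQ of 255 means "unavailable" and never passes any
#'     `Z > 0`: unknown quality must not pass a quality floor.}
#' }
#' Both mates of an overlapping read pair count separately, and no base
#' alignment quality (BAQ) adjustment is applied: the counts reflect the
#' BAM's stored qualities, as a variant caller without base-level hard
#' filtering would see them.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file (or a
#'   `BamFile`).
#' @param region One row of a [load_bed()] table (or any list with `chrom`,
#'   `start`, `end`, `name`; coordinates 0-based half-open).
#' @param qsm A [qsm_spec()] supplying thresholds `Y` and `Z`.
#' @param policy A [read_filter_policy()].
#' @return A data frame of class `qsm_profile` with one row per reference
#'   position: `chrom`, `pos` (0-based), `depth`, `n_base`, `n_bq_pass`,
#'   `n_mq_pass`. The region name, QSM and policy travel as attributes.
#' @export
profile_region <- function(bam, region, qsm, policy = read_filter_policy()) {
  stopifnot(inherits(qsm, "qsm_spec"), inherits(policy, "qsm_policy"))
  bf <- open_indexed_bam(bam)
  chrom <- as.character(region$chrom)
  start0 <- as.integer(region$start)
  end0 <- as.integer(region$end)
  if (end0 <= start0) stop("region has end <= start", call. = FALSE)
  check_chrom(bf, chrom)

  width <- end0 - start0
  lo <- start0 + 1L          # 1-based inclusive bounds
  hi <- end0
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(lo, hi))
  param <- Rsamtools::ScanBamParam(flag = policy_scan_flag(policy),
                                   what = c("mapq", "qual"),
                                   which = which)
  gal <- GenomicAlignments::readGAlignments(bf, param = param)

  depth <- integer(width)
  n_base <- integer(width)
  n_bq <- integer(width)
  n_mq <- integer(width)

  if (length(gal)) {
    cig <- GenomicAlignments::cigar(gal)
    pos <- GenomicRanges::start(gal)
    mapq <- S4Vectors::mcols(gal)$mapq
    mq_pass <- if (qsm$Z == 0L) rep(TRUE, length(gal))
               else !is.na(mapq) & mapq != 255L & mapq >= qsm$Z

    # depth: reference-consuming ops except N (refskip asserts no alignment)
    covR <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cig, ops = c("M", "=", "X", "D"), pos = pos)
    ridx <- rep(seq_along(gal), lengths(covR))
    covU <- unlist(covR, use.names = FALSE)
    cs <- pmax(GenomicRanges::start(covU), lo)
    ce <- pmin(GenomicRanges::end(covU), hi)
    ok <- ce >= cs
    if (any(ok)) {
      posv <- sequence(ce[ok] - cs[ok] + 1L, from = cs[ok]) - lo + 1L
      readv <- rep(ridx[ok], ce[ok] - cs[ok] + 1L)
      depth <- tabulate(posv, nbins = width)
      n_mq <- tabulate(posv[mq_pass[readv]], nbins = width)
    }

    # aligned bases: M/=/X ranges paired along reference and query space,
    # giving each base's reference position and its quality-string offset
    refR <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cig, ops = c("M", "=", "X"), pos = pos)
    qryR <- GenomicAlignments::cigarRangesAlongQuerySpace(
      cig, ops = c("M", "=", "X"))
    ridx2 <- rep(seq_along(gal), lengths(refR))
    refU <- unlist(refR, use.names = FALSE)
    qryU <- unlist(qryR, use.names = FALSE)
    rs <- GenomicRanges::start(refU); re <- GenomicRanges::end(refU)
    qs <- GenomicRanges::start(qryU)
    clip_lo <- pmax(rs, lo); clip_hi <- pmin(re, hi)
    ok2 <- clip_hi >= clip_lo
    if (any(ok2)) {
      w2 <- clip_hi[ok2] - clip_lo[ok2] + 1L
      refpos <- sequence(w2, from = clip_lo[ok2]) - lo + 1L
      qrypos <- sequence(w2, from = qs[ok2] + (clip_lo[ok2] - rs[ok2]))
      readv2 <- rep(ridx2[ok2], w2)
      quals <- methods::as(S4Vectors::mcols(gal)$qual, "IntegerList")
      qlen <- lengths(quals)
      qoff <- c(0L, cumsum(qlen))[readv2]
      qv <- unlist(quals, use.names = FALSE)[qoff + qrypos]
      n_base <- tabulate(refpos, nbins = width)
      n_bq <- tabulate(refpos[qv >= qsm$Y], nbins = width)
    }
  }

  structure(
    data.frame(chrom = chrom, pos = seq.int(start0, end0 - 1L),
               depth = depth, n_base = n_base, n_bq_pass = n_bq,
               n_mq_pass = n_mq, stringsAsFactors = FALSE),
    class = c("qsm_profile", "data.frame"),
    region_name = as.character(region$name),
    qsm = render_qsm(qsm), policy = format(policy))
}

#' Base-quality pass fraction of profiled positions
#'
#' The fraction of aligned base calls at each position with base quality at
#' least `Y`: `n_bq_pass / n_base`, defined as 0 where `n_base` is 0 (no
#' base call means no evidence of adequate base quality). Pass/fail
#' decisions against the QSM percentage are taken in exact integer
#' arithmetic, not on this floating-point value.
#'
#' @param p A `qsm_profile` data frame (or any data frame with `n_bq_pass`
#'   and `n_base`).
#' @return Numeric vector in `[0, 1]`, one value per position.
#' @export
bq_fraction <- function(p) {
  ifelse(p$n_base == 0L, 0, p$n_bq_pass / p$n_base)
}

#' Mapping-quality pass fraction of profiled positions
#'
#' The fraction of covering reads at each position with mapping quality at
#' least `Z`: `n_mq_pass / depth`, defined as 0 where `depth` is 0. The
#' denominator is the full depth (MAPQ is a per-read property, so
#' deletion-spanning reads carry one too).
#'
#' @param p A `qsm_profile` data frame (or any data frame with `n_mq_pass`
#'   and `depth`).
#' @return Numeric vector in `[0, 1]`, one value per position.
#' @export
mq_fraction <- function(p) {
  ifelse(p$depth == 0L, 0, p$n_mq_pass / p$depth)
}

#' @export
print.qsm_profile <- function(x, ...) {
  cat("per-base profile of region ", attr(x, "region_name"), " (",
      nrow(x), " positions, QSM ", attr(x, "qsm"), ")\n", sep = "")
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more positions\n")
  invisible(x)
}
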