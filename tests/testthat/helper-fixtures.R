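# Shared fixture-building shortcuts for the test suite.

tscp_qsm <- function() parse_qsm("C50_B10(85)_M20(95)")

# Write explicit SAM lines (header included) to a sorted, indexed BAM.
sam_to_bam <- function(lines, prefix = tempfile()) {
  sam <- paste0(prefix, ".sam")
  writeLines(lines, sam)
  tmp <- Rsamtools::asBam(sam, paste0(prefix, ".u"), overwrite = TRUE,
                          indexDestination = FALSE)
  Rsamtools::sortBam(tmp, prefix)
  unlink(tmp)
  Rsamtools::indexBam(paste0(prefix, ".bam"))
  list(sam = sam, bam = paste0(prefix, ".bam"))
}

sam_header <- function(chrom = "chrT", len = 1000L) {
  c("@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", chrom, "\tLN:", len))
}

# One SAM alignment line with sensible defaults.
sam_read <- function(qname, pos, cigar, chrom = "chrT", flag = 0L,
                     mapq = 60L, bq = 30L, qlen = NULL) {
  if (is.null(qlen)) {
    toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    qlen <- sum(as.integer(sub(".$", "", toks))[
      substring(toks, nchar(toks)) %in% c("M", "I", "S", "=", "X")])
  }
  paste(qname, flag, chrom, pos, mapq, cigar, "*", 0, 0,
        strrep("A", qlen), strrep(rawToChar(as.raw(33L + bq)), qlen),
        sep = "\t")
}

region_row <- function(chrom, start, end, name = "r") {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             stringsAsFactors = FALSE)
}

# A one-sample region table of pass flags, for cohort-level tests that
# need no BAMs.
flags_table <- function(pass_C, pass_B = TRUE, pass_M = TRUE,
                        names = NULL) {
  n <- max(length(pass_C), length(pass_B), length(pass_M))
  if (is.null(names)) names <- sprintf("reg%02d", seq_len(n))
  data.frame(region_name = names,
             pass_C = rep_len(pass_C, n), pass_B = rep_len(pass_B, n),
             pass_M = rep_len(pass_M, n), stringsAsFactors = FALSE)
}
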