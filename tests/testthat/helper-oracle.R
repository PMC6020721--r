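# Brute-force pileup oracle: a naive per-column scan of the SAM text.
# Parses SAM fields and CIGARs itself and walks every read base-by-base,
# entirely independent of the package's profiler (which goes through
# GenomicAlignments).  Quadratic and slow on purpose.

oracle_profile <- function(sam_path, chrom, start0, end0, Y, Z,
                           exclude_flags = c(0x4, 0x100, 0x800, 0x400,
                                             0x200)) {
  width <- end0 - start0
  depth <- integer(width); n_base <- integer(width)
  n_bq <- integer(width); n_mq <- integer(width)
  lo1 <- start0 + 1L; hi1 <- end0   # 1-based inclusive window

  mask <- Reduce(bitwOr, as.integer(exclude_flags), 0L)
  for (line in readLines(sam_path)) {
    if (startsWith(line, "@")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (bitwAnd(as.integer(f[2]), mask) != 0L) next
    if (f[3] != chrom) next
    pos <- as.integer(f[4])          # 1-based leftmost
    if (pos > hi1) next
    # crude span upper bound (sum of every CIGAR length) just to skip
    # reads that cannot reach the window
    lens <- as.integer(regmatches(f[6], gregexpr("[0-9]+", f[6]))[[1]])
    if (pos + sum(lens) < lo1) next
    mapq <- as.integer(f[5])
    qual <- utf8ToInt(f[11]) - 33L   # per-base Phred scores
    mq_ok <- (Z == 0L) || (mapq != 255L && mapq >= Z)

    toks <- regmatches(f[6], gregexpr("[0-9]+[MIDNSHP=X]", f[6]))[[1]]
    refp <- pos; qp <- 1L
    for (tok in toks) {
      L <- as.integer(sub(".$", "", tok))
      op <- substring(tok, nchar(tok))
      if (op %in% c("M", "=", "X")) {
        for (k in 0:(L - 1L)) {
          rp <- refp + k
          if (rp >= lo1 && rp <= hi1) {
            j <- rp - lo1 + 1L
            depth[j] <- depth[j] + 1L
            n_base[j] <- n_base[j] + 1L
            if (qual[qp + k] >= Y) n_bq[j] <- n_bq[j] + 1L
            if (mq_ok) n_mq[j] <- n_mq[j] + 1L
          }
        }
        refp <- refp + L; qp <- qp + L
      } else if (op == "D") {
        for (k in 0:(L - 1L)) {
          rp <- refp + k
          if (rp >= lo1 && rp <= hi1) {
            j <- rp - lo1 + 1L
            depth[j] <- depth[j] + 1L
            if (mq_ok) n_mq[j] <- n_mq[j] + 1L
          }
        }
        refp <- refp + L
      } else if (op == "N") {
        refp <- refp + L
      } else if (op %in% c("I", "S")) {
        qp <- qp + L
      }                              # H, P consume nothing
    }
  }
  data.frame(chrom = chrom, pos = seq.int(start0, end0 - 1L),
             depth = depth, n_base = n_base, n_bq_pass = n_bq,
             n_mq_pass = n_mq, stringsAsFactors = FALSE)
}
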