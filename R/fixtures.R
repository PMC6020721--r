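#' Recipe for one synthetic test region
#'
#' Describes a region and the reads to simulate over it so that every
#' per-base count the profiler reports has a closed-form expectation.
#' Reads are placement-and-quality scaffolds, not sequence simulations:
#' each read fully spans the region (with a few bases of random start/end
#' jitter outside it), carries uniformly "high" or "low" base qualities and
#' a "high" or "low" mapping quality. Optional CIGAR overrides create
#' deletion/insertion coverage cases for individual reads.
#'
#' Setting `mq_high` or `mq_low` to 255 produces reads whose mapping
#' quality is "unavailable" in SAM terms; `mq_low = 0` with a small
#' `mq_pass_frac` emulates the mapping-quality collapse seen over genes
#' with highly homologous pseudogenes.
#'
#' @param chrom Reference name.
#' @param start,end Region coordinates, 0-based half-open.
#' @param name Region name (defaults to `"chrom:start-end"`).
#' @param depth Number of reads fully spanning the region (>= 0).
#' @param bq_pass_frac Fraction of reads whose base calls all carry
#'   `bq_high`; the rest carry `bq_low`.
#' @param mq_pass_frac Fraction of reads with mapping quality `mq_high`;
#'   the rest get `mq_low`.
#' @param bq_high,bq_low Phred base qualities for the two read classes.
#' @param mq_high,mq_low Mapping qualities for the two read classes.
#' @param indels Optional list of `list(read = i, cigar = "...")` CIGAR
#'   overrides applied to individual reads (1-based read index).
#' @param seed Seed for start/end jitter of this recipe's reads.
#' @return An object of class `qsm_recipe`.
#' @export
region_recipe <- function(chrom, start, end, name = NULL, depth = 60L,
                          bq_pass_frac = 1, mq_pass_frac = 1,
                          bq_high = 30L, bq_low = 2L,
                          mq_high = 60L, mq_low = 0L,
                          indels = NULL, seed = 1L) {
  stopifnot(end > start, start >= 0, depth >= 0,
            bq_pass_frac >= 0, bq_pass_frac <= 1,
            mq_pass_frac >= 0, mq_pass_frac <= 1,
            bq_high <= 93, bq_low <= 93, mq_high <= 255, mq_low <= 255)
  if (is.null(name)) name <- paste0(chrom, ":", start, "-", end)
  structure(
    list(chrom = as.character(chrom), start = as.integer(start),
         end = as.integer(end), name = name, depth = as.integer(depth),
         bq_pass_frac = bq_pass_frac, mq_pass_frac = mq_pass_frac,
         bq_high = as.integer(bq_high), bq_low = as.integer(bq_low),
         mq_high = as.integer(mq_high), mq_low = as.integer(mq_low),
         indels = indels, seed = as.integer(seed)),
    class = "qsm_recipe")
}

# Evaluate code under a given seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Parse a CIGAR into (length, op) pairs with a plain regex; used only by
# the generator's bookkeeping, never by the profiler.
parse_cigar <- function(cigar) {
  m <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar)[[1]]
  parts <- regmatches(cigar, gregexpr("([0-9]+)([MIDNSHP=X])", cigar))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(cigar))
    stop("malformed CIGAR: ", cigar, call. = FALSE)
  data.frame(len = as.integer(sub("[MIDNSHP=X]$", "", parts)),
             op = sub("^[0-9]+", "", parts), stringsAsFactors = FALSE)
}

cigar_ref_len <- function(ops) sum(ops$len[ops$op %in% c("M", "D", "N",
                                                         "=", "X")])
cigar_qry_len <- function(ops) sum(ops$len[ops$op %in% c("M", "I", "S",
                                                         "=", "X")])

mq_passes <- function(mq, Z) Z == 0L | (mq != 255L & mq >= Z)

#' Build a synthetic SAM/BAM/BED fixture with known expectations
#'
#' Writes a valid coordinate-sorted SAM file (plus BAM and index) realising
#' a list of [region_recipe()]s, the matching BED file of regions, and a
#' per-position expectation table of `(depth, n_base, n_bq_pass,
#' n_mq_pass)` computed in closed form from the recipes under the supplied
#' QSM's `Y` and `Z` thresholds. The expectation table is derived from the
#' recipes' bookkeeping alone -- it never consults the profiler -- so it
#' serves as an independent oracle for pileup counting.
#'
#' @param recipes A list of [region_recipe()]s (a single recipe is
#'   accepted). Region names must be unique.
#' @param out_prefix Output path prefix; `<prefix>.sam`, `<prefix>.bam`,
#'   `<prefix>.bam.bai`, `<prefix>.bed` and `<prefix>.expected.tsv` are
#'   written.
#' @param qsm A [qsm_spec()] (or QSM string) supplying the `Y`/`Z`
#'   thresholds under which expected pass counts are computed.
#' @param reference_lengths Optional named integer vector of reference
#'   lengths per chromosome; defaults to the rightmost read end plus a
#'   margin. Reads extending past a declared length are an error.
#' @param jitter Maximum random extension of reads beyond each region
#'   boundary (bases); default 5.
#' @return A list with paths `sam`, `bam`, `bed`, `expected_tsv`, the
#'   `expectations` data frame (`region`, `chrom`, `pos`, `depth`,
#'   `n_base`, `n_bq_pass`, `n_mq_pass`), and the `recipes`.
#' @export
build_fixture <- function(recipes, out_prefix,
                          qsm = parse_qsm("C50_B10(85)_M20(95)"),
                          reference_lengths = NULL, jitter = 5L) {
  if (inherits(recipes, "qsm_recipe")) recipes <- list(recipes)
  stopifnot(length(recipes) >= 1L,
            all(vapply(recipes, inherits, TRUE, "qsm_recipe")))
  if (is.character(qsm)) qsm <- parse_qsm(qsm)
  names <- vapply(recipes, `[[`, "", "name")
  if (anyDuplicated(names))
    stop("recipe region names must be unique", call. = FALSE)

  reads <- list()   # per-read records across recipes
  exps <- list()
  for (k in seq_along(recipes)) {
    r <- recipes[[k]]
    width <- r$end - r$start
    exp_depth <- integer(width); exp_base <- integer(width)
    exp_bq <- integer(width); exp_mq <- integer(width)

    if (r$depth > 0L) {
      n_bq_high <- round(r$depth * r$bq_pass_frac)
      n_mq_high <- round(r$depth * r$mq_pass_frac)
      # MQ-high reads from the front, BQ-high reads from the back, so the
      # two classes cross rather than coincide
      bq <- ifelse(seq_len(r$depth) > r$depth - n_bq_high,
                   r$bq_high, r$bq_low)
      mq <- ifelse(seq_len(r$depth) <= n_mq_high, r$mq_high, r$mq_low)
      jit <- with_seed(r$seed, {
        cbind(lead = sample.int(jitter + 1L, r$depth, replace = TRUE) - 1L,
              tail = sample.int(jitter + 1L, r$depth, replace = TRUE) - 1L)
      })
      starts <- pmax(r$start - jit[, "lead"], 0L)
      ends <- r$end + jit[, "tail"]

      override <- rep(NA_character_, r$depth)
      for (ov in r$indels) {
        if (ov$read < 1L || ov$read > r$depth)
          stop("indel override read index out of range", call. = FALSE)
        override[ov$read] <- ov$cigar
      }

      for (i in seq_len(r$depth)) {
        if (is.na(override[i])) {
          len <- ends[i] - starts[i]
          ops <- data.frame(len = len, op = "M")
        } else {
          ops <- parse_cigar(override[i])
          len <- cigar_ref_len(ops)
          ends[i] <- starts[i] + len
        }
        qlen <- cigar_qry_len(ops)
        reads[[length(reads) + 1L]] <- list(
          qname = sprintf("%s_r%04d", r$name, i),
          chrom = r$chrom, pos1 = starts[i] + 1L, mapq = mq[i],
          cigar = paste0(ops$len, ops$op, collapse = ""),
          seq = strrep("A", qlen),
          qual = strrep(rawToChar(as.raw(33L + bq[i])), qlen),
          end0 = starts[i] + len)

        # expectation bookkeeping: walk the CIGAR over the region window
        bq_ok <- bq[i] >= qsm$Y
        mq_ok <- mq_passes(mq[i], qsm$Z)
        refp <- starts[i]
        for (j in seq_len(nrow(ops))) {
          op <- ops$op[j]; L <- ops$len[j]
          if (op %in% c("M", "=", "X", "D", "N")) {
            if (op != "N") {
              sel <- seq.int(refp, refp + L - 1L)
              sel <- sel[sel >= r$start & sel < r$end] - r$start + 1L
              if (length(sel)) {
                exp_depth[sel] <- exp_depth[sel] + 1L
                if (mq_ok) exp_mq[sel] <- exp_mq[sel] + 1L
                if (op != "D") {
                  exp_base[sel] <- exp_base[sel] + 1L
                  if (bq_ok) exp_bq[sel] <- exp_bq[sel] + 1L
                }
              }
            }
            refp <- refp + L
          }
        }
      }
    }
    exps[[k]] <- data.frame(
      region = r$name, chrom = r$chrom,
      pos = seq.int(r$start, r$end - 1L),
      depth = exp_depth, n_base = exp_base,
      n_bq_pass = exp_bq, n_mq_pass = exp_mq,
      stringsAsFactors = FALSE)
  }

  chroms <- unique(vapply(recipes, `[[`, "", "chrom"))
  max_end <- vapply(chroms, function(ch) {
    ends <- c(vapply(recipes, function(r)
      if (r$chrom == ch) r$end else 0L, 0L),
      vapply(reads, function(rd)
        if (rd$chrom == ch) rd$end0 else 0L, 0L))
    max(ends)
  }, 0L)
  if (is.null(reference_lengths)) {
    reference_lengths <- max_end + 10L
  } else {
    reference_lengths <- reference_lengths[chroms]
    if (any(is.na(reference_lengths)))
      stop("reference_lengths missing for chromosome(s): ",
           paste(chroms[is.na(reference_lengths)], collapse = ", "),
           call. = FALSE)
    over <- max_end > reference_lengths
    if (any(over))
      stop("reads extend past the declared reference length on ",
           paste(chroms[over], collapse = ", "), call. = FALSE)
  }

  # SAM: header + reads sorted by (chrom in header order, position)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", chroms, "\tLN:", reference_lengths[chroms]))
  if (length(reads)) {
    ord <- order(match(vapply(reads, `[[`, "", "chrom"), chroms),
                 vapply(reads, `[[`, 0L, "pos1"),
                 vapply(reads, `[[`, "", "qname"))
    lines <- vapply(reads[ord], function(rd)
      paste(rd$qname, 0L, rd$chrom, rd$pos1, rd$mapq, rd$cigar,
            "*", 0L, 0L, rd$seq, rd$qual, sep = "\t"), "")
  } else lines <- character()

  sam <- paste0(out_prefix, ".sam")
  writeLines(c(hdr, lines), sam)
  bed <- paste0(out_prefix, ".bed")
  writeLines(vapply(recipes, function(r)
    paste(r$chrom, r$start, r$end, r$name, sep = "\t"), ""), bed)

  tmp <- Rsamtools::asBam(sam, paste0(out_prefix, ".unsorted"),
                          overwrite = TRUE, indexDestination = FALSE)
  Rsamtools::sortBam(tmp, out_prefix)
  unlink(tmp)
  bam <- paste0(out_prefix, ".bam")
  Rsamtools::indexBam(bam)

  expectations <- do.call(rbind, exps)
  expected_tsv <- paste0(out_prefix, ".expected.tsv")
  utils::write.table(expectations, expected_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  list(sam = sam, bam = bam, bed = bed, expected_tsv = expected_tsv,
       expectations = expectations, recipes = recipes, qsm = qsm)
}

#' Randomized region recipes for property testing
#'
#' Draws `n` recipes with random widths, depths, pass fractions and
#' quality levels (including occasional MAPQ-255 reads and deletion
#' CIGAR overrides), reproducibly from `seed`. Regions are spaced apart
#' on one synthetic chromosome so their reads do not interfere.
#'
#' @param n Number of recipes.
#' @param seed RNG seed.
#' @param chrom Chromosome name for all recipes.
#' @param max_depth Maximum read count per recipe.
#' @return A list of [region_recipe()]s.
#' @export
random_region_recipes <- function(n, seed = 1L, chrom = "chrS",
                                  max_depth = 120L) {
  with_seed(seed, {
    gap <- 80L
    recipes <- vector("list", n)
    cursor <- 20L
    for (i in seq_len(n)) {
      width <- sample(8:40, 1L)
      depth <- sample(0:max_depth, 1L)
      mq_high <- sample(c(60L, 37L, 255L), 1L, prob = c(.6, .3, .1))
      indels <- NULL
      if (depth > 0L && stats::runif(1) < 0.3) {
        dlen <- sample(1:3, 1L)
        flank <- max(2L, width %/% 3L)
        indels <- list(list(
          read = sample.int(depth, 1L),
          cigar = sprintf("%dM%dD%dM", flank, dlen, width + 6L)))
      }
      recipes[[i]] <- region_recipe(
        chrom = chrom, start = cursor, end = cursor + width,
        name = sprintf("R%03d", i), depth = depth,
        bq_pass_frac = stats::runif(1, 0.5, 1),
        mq_pass_frac = stats::runif(1, 0.5, 1),
        bq_high = sample(25:40, 1L), bq_low = sample(0:9, 1L),
        mq_high = mq_high, mq_low = sample(c(0L, 5L, 19L), 1L),
        seed = sample.int(1e6, 1L))
      cursor <- cursor + width + gap
    }
    recipes
  })
}
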