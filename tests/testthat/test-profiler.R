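qsm_default <- parse_qsm("C50_B10(85)_M20(95)")

test_that("uniform spanning reads give the closed-form pileup counts", {
  r <- region_recipe("chrT", 100, 110, "u", depth = 60,
                     bq_pass_frac = 55 / 60, mq_pass_frac = 1, seed = 11)
  fx <- build_fixture(list(r), tempfile())
  p <- profile_region(fx$bam, region_row("chrT", 100, 110, "u"),
                      qsm_default)
  expect_identical(nrow(p), 10L)
  expect_true(all(p$depth == 60L))
  expect_true(all(p$n_base == 60L))
  expect_true(all(p$n_bq_pass == 55L))
  expect_true(all(p$n_mq_pass == 60L))
  expect_equal(bq_fraction(p), rep(55 / 60, 10))
  expect_equal(mq_fraction(p), rep(1, 10))
})

test_that("a region with no overlapping reads profiles to all zeros", {
  r <- region_recipe("chrT", 100, 110, "u", depth = 10, seed = 1)
  fx <- build_fixture(list(r), tempfile())
  p <- profile_region(fx$bam, region_row("chrT", 500, 520, "empty"),
                      qsm_default)
  expect_true(all(p$depth == 0L))
  expect_true(all(p$n_base == 0L & p$n_bq_pass == 0L & p$n_mq_pass == 0L))
  expect_equal(bq_fraction(p), rep(0, 20))
  expect_equal(mq_fraction(p), rep(0, 20))
})

test_that("deletion spans count toward depth but carry no base call", {
  # one read, CIGAR 5M2D5M starting at 0-based position 0
  fx <- sam_to_bam(c(sam_header("chrT", 100),
                     sam_read("r1", 1, "5M2D5M")))
  p <- profile_region(fx$bam, region_row("chrT", 0, 12, "d"), qsm_default)
  expect_identical(p$depth, c(rep(1L, 12)))
  expect_identical(p$n_base, c(rep(1L, 5), 0L, 0L, rep(1L, 5)))
  expect_identical(p$n_bq_pass, p$n_base)  # BQ30 >= 10 wherever a base is
  expect_identical(p$n_mq_pass, p$depth)   # MQ60 counts over the deletion
  # and the independent SAM-scan oracle agrees
  o <- oracle_profile(fx$sam, "chrT", 0, 12, Y = 10L, Z = 20L)
  expect_equal(p[names(o)], o, ignore_attr = TRUE)
})

test_that("refskip (N) spans are not counted as coverage", {
  fx <- sam_to_bam(c(sam_header("chrT", 100),
                     sam_read("r1", 1, "4M3N4M")))
  p <- profile_region(fx$bam, region_row("chrT", 0, 11, "n"), qsm_default)
  expect_identical(p$depth, c(rep(1L, 4), rep(0L, 3), rep(1L, 4)))
  o <- oracle_profile(fx$sam, "chrT", 0, 11, Y = 10L, Z = 20L)
  expect_equal(p[names(o)], o, ignore_attr = TRUE)
})

test_that("soft clips and insertions consume query but not reference", {
  fx <- sam_to_bam(c(sam_header("chrT", 100),
                     # 3S then 4M at pos 5, qualities: low clip then high
                     paste("r1", 0, "chrT", 5, 60, "3S4M2I2M", "*", 0, 0,
                           strrep("A", 11),
                           paste0("###", strrep("I", 8)), sep = "\t")))
  p <- profile_region(fx$bam, region_row("chrT", 0, 15, "s"), qsm_default)
  o <- oracle_profile(fx$sam, "chrT", 0, 15, Y = 10L, Z = 20L)
  expect_equal(p[names(o)], o, ignore_attr = TRUE)
  expect_identical(sum(p$depth), 6L)  # 4M + 2M reference bases
  expect_identical(p$n_bq_pass, p$n_base)  # clipped low bases never counted
})

test_that("MAPQ 255 means unavailable and never passes a positive floor", {
  fx <- sam_to_bam(c(sam_header("chrT", 100),
                     sam_read("r1", 1, "10M", mapq = 255),
                     sam_read("r2", 1, "10M", mapq = 20)))
  p <- profile_region(fx$bam, region_row("chrT", 0, 10, "m"), qsm_default)
  expect_true(all(p$depth == 2L))
  expect_true(all(p$n_mq_pass == 1L))
  # but with Z = 0 the floor is vacuous and every read passes
  p0 <- profile_region(fx$bam, region_row("chrT", 0, 10, "m"),
                       parse_qsm("C0_B0(0)_M0(0)"))
  expect_true(all(p0$n_mq_pass == 2L))
})

test_that("half MQ-0 reads yield a mapping-quality pass fraction of 0.5", {
  r <- region_recipe("chrT", 50, 80, "pseudo", depth = 40,
                     mq_pass_frac = 0.5, mq_high = 60, mq_low = 0,
                     seed = 3)
  fx <- build_fixture(list(r), tempfile())
  p <- profile_region(fx$bam, region_row("chrT", 50, 80, "pseudo"),
                      qsm_default)
  expect_equal(mq_fraction(p), rep(0.5, 30))
})

test_that("read filter policy excludes flagged records and is recorded", {
  fx <- sam_to_bam(c(sam_header("chrT", 100),
                     sam_read("r1", 1, "10M", flag = 0L),
                     sam_read("r2", 1, "10M", flag = 1024L),   # duplicate
                     sam_read("r3", 1, "10M", flag = 256L),    # secondary
                     sam_read("r4", 1, "10M", flag = 2048L),   # supplementary
                     sam_read("r5", 1, "10M", flag = 512L)))   # qcfail
  reg <- region_row("chrT", 0, 10, "f")
  p <- profile_region(fx$bam, reg, qsm_default)
  expect_true(all(p$depth == 1L))
  p2 <- profile_region(fx$bam, reg, qsm_default,
                       read_filter_policy(exclude_duplicates = FALSE))
  expect_true(all(p2$depth == 2L))
  expect_match(attr(p2, "policy"), "exclude_duplicates=FALSE")
  o <- oracle_profile(fx$sam, "chrT", 0, 10, Y = 10L, Z = 20L,
                      exclude_flags = c(0x4, 0x100, 0x800, 0x200))
  expect_equal(p2[names(o)], o, ignore_attr = TRUE)
})

test_that("profiler equals the brute-force oracle on randomized fixtures", {
  recipes <- random_region_recipes(12, seed = 202)
  fx <- build_fixture(recipes, tempfile())
  bed <- load_bed(fx$bed)
  for (i in seq_len(nrow(bed))) {
    p <- profile_region(fx$bam, bed[i, ], qsm_default)
    o <- oracle_profile(fx$sam, bed$chrom[i], bed$start[i], bed$end[i],
                        Y = 10L, Z = 20L)
    expect_equal(p[names(o)], o, ignore_attr = TRUE)
  }
  # conservation across modules: total profile rows == total BED width
  expect_identical(sum(bed$width),
                   sum(vapply(seq_len(nrow(bed)), function(i)
                     nrow(profile_region(fx$bam, bed[i, ], qsm_default)),
                     0L)))
})

test_that("raising thresholds never increases pass counts, depth fixed", {
  recipes <- random_region_recipes(6, seed = 77)
  fx <- build_fixture(recipes, tempfile())
  bed <- load_bed(fx$bed)
  for (i in seq_len(nrow(bed))) {
    lo <- profile_region(fx$bam, bed[i, ], parse_qsm("C50_B5(85)_M10(95)"))
    hi <- profile_region(fx$bam, bed[i, ], parse_qsm("C50_B30(85)_M40(95)"))
    expect_identical(lo$depth, hi$depth)
    expect_identical(lo$n_base, hi$n_base)
    expect_true(all(hi$n_bq_pass <= lo$n_bq_pass))
    expect_true(all(hi$n_mq_pass <= lo$n_mq_pass))
    expect_true(all(lo$n_base <= lo$depth))
    expect_true(all(lo$n_bq_pass <= lo$n_base))
    expect_true(all(lo$n_mq_pass <= lo$depth))
  }
})

test_that("missing index and chromosome-dialect mismatches are named", {
  r <- region_recipe("chr10", 100, 120, "x", depth = 5, seed = 1)
  fx <- build_fixture(list(r), tempfile())
  expect_error(profile_region(fx$bam, region_row("10", 100, 120, "x"),
                              qsm_default),
               "dialect mismatch.*'10'.*'chr10'")
  expect_error(profile_region(fx$bam, region_row("chrZZ", 1, 5, "x"),
                              qsm_default),
               "absent from the BAM header")
  noidx <- tempfile(fileext = ".bam")
  file.copy(fx$bam, noidx)
  expect_error(profile_region(noidx, region_row("chr10", 100, 120, "x"),
                              qsm_default),
               "index not found.*\\.bai")
})
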