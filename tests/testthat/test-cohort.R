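test_that("the >1%-of-samples review rule triggers at the exact integer point", {
  # cohort of n samples in which one region fails the QSM in k samples
  min_trigger <- function(n) {
    for (k in 0:n) {
      evs <- lapply(seq_len(n), function(i)
        flags_table(pass_C = c(i > k, TRUE), names = c("hot", "cold")))
      ch <- summarize_cohort(evs)
      if ("hot" %in% ch$review_flagged) return(k)
    }
    NA_integer_
  }
  expect_identical(min_trigger(960), 10L)  # 9.6 is the exact 1% point
  expect_identical(min_trigger(100), 2L)
  expect_identical(min_trigger(1), 1L)     # any failure in a 1-sample cohort
  expect_identical(min_trigger(50), 1L)
})

test_that("the review percentage is a parameter", {
  evs <- lapply(1:20, function(i)
    flags_table(pass_C = c(i > 2, TRUE), names = c("hot", "cold")))
  expect_identical(summarize_cohort(evs)$review_flagged, "hot")       # 10% > 1%
  expect_identical(summarize_cohort(evs, review_percent = 10)$review_flagged,
                   character(0))                                      # 10% !> 10%
  expect_identical(summarize_cohort(evs, review_percent = 9.9)$review_flagged,
                   "hot")
})

test_that("median of per-sample pass counts uses the lower middle", {
  mk <- function(npass) flags_table(pass_C = seq_len(10) <= npass)
  ch <- summarize_cohort(lapply(c(7, 9, 10), mk))
  expect_identical(ch$median_pass, 9L)
  # even cohort: lower-middle order statistic, always an observed count
  ch2 <- summarize_cohort(lapply(c(7, 9, 10, 4), mk))
  expect_identical(ch2$median_pass, 7L)
  expect_identical(unname(ch2$per_sample_pass), c(7L, 9L, 10L, 4L))
})

test_that("per-region fail counts match per-sample flags exactly", {
  set.seed(12)
  n <- 100L
  evs <- lapply(seq_len(n), function(i)
    data.frame(region_name = sprintf("reg%02d", 1:8),
               pass_C = stats::runif(8) > 0.05,
               pass_B = stats::runif(8) > 0.03,
               pass_M = stats::runif(8) > 0.10,
               stringsAsFactors = FALSE))
  ch <- summarize_cohort(evs)
  prf <- ch$per_region_fail
  expect_true(all(prf$fail_C <= n & prf$fail_QSM <= n))
  # a QSM failure requires at least one metric failure...
  expect_true(all(prf$fail_QSM <= prf$fail_C + prf$fail_B + prf$fail_M))
  # ...and equals the count of samples with any metric failure
  any_fail <- Reduce(`+`, lapply(evs, function(t)
    as.integer(!(t$pass_C & t$pass_B & t$pass_M))))
  expect_identical(prf$fail_QSM, any_fail)
  expect_true(all(prf$fail_QSM >= pmax(prf$fail_C, prf$fail_B, prf$fail_M)))
  # adding an all-pass sample changes no counts and adds no review flags
  ch2 <- summarize_cohort(c(evs, list(flags_table(
    pass_C = rep(TRUE, 8), names = sprintf("reg%02d", 1:8)))))
  expect_identical(ch2$per_region_fail[names(prf)[1:5]], prf[1:5])
  expect_true(all(ch2$review_flagged %in% ch$review_flagged))
})

test_that("the fail table is ordered, tie-broken by name, with exact totals", {
  evs <- lapply(1:100, function(i)
    flags_table(pass_C = c(i > 2, TRUE, i > 2, TRUE),
                pass_M = c(TRUE, TRUE, TRUE, i > 5),
                names = c("B_reg", "zero", "A_reg", "M_reg")))
  ch <- summarize_cohort(evs)
  tab <- region_fail_table(ch)
  expect_identical(tab$region_name, c("M_reg", "A_reg", "B_reg", "zero",
                                      "TOTAL"))
  body <- tab[tab$region_name != "TOTAL", ]
  for (col in c("fail_C", "fail_B", "fail_M", "fail_QSM"))
    expect_identical(tab[[col]][tab$region_name == "TOTAL"],
                     sum(body[[col]]))
  expect_identical(body$fail_QSM, c(5L, 2L, 2L, 0L))
  expect_true(all(tab$review_flagged[tab$region_name %in%
                                       c("M_reg", "A_reg", "B_reg")]))
  # no-failure cohort: zero table, no flags
  ch0 <- summarize_cohort(lapply(1:10, function(i)
    flags_table(rep(TRUE, 3))))
  expect_true(all(region_fail_table(ch0)$fail_QSM == 0L))
  expect_length(ch0$review_flagged, 0)
})

test_that("mismatched region sets across samples are rejected", {
  a <- flags_table(c(TRUE, TRUE), names = c("r1", "r2"))
  b <- flags_table(c(TRUE, TRUE), names = c("r1", "r3"))
  expect_error(summarize_cohort(list(s1 = a, s2 = b)), "BED")
  expect_error(summarize_cohort(list()), "non-empty")
  expect_error(summarize_cohort(list(s1 = a, s1 = a)), "duplicate sample")
})

test_that("cohort aggregation works from full sample evaluations", {
  recipes <- list(
    region_recipe("chrT", 100, 130, "ok", depth = 60, seed = 1),
    region_recipe("chrT", 300, 330, "pseudo", depth = 60,
                  mq_pass_frac = 0.5, seed = 2))
  fx1 <- build_fixture(recipes, tempfile())
  # second sample: both regions healthy
  fx2 <- build_fixture(list(
    region_recipe("chrT", 100, 130, "ok", depth = 60, seed = 3),
    region_recipe("chrT", 300, 330, "pseudo", depth = 60, seed = 4)),
    tempfile())
  evs <- list(s1 = evaluate_sample(fx1$bam, fx1$bed, "C50_B10(85)_M20(95)"),
              s2 = evaluate_sample(fx2$bam, fx2$bed, "C50_B10(85)_M20(95)"))
  ch <- summarize_cohort(evs)
  expect_identical(ch$n_samples, 2L)
  expect_identical(ch$per_region_fail$fail_M[
    ch$per_region_fail$region_name == "pseudo"], 1L)
  expect_identical(ch$review_flagged, "pseudo")  # 1/2 = 50% > 1%
  expect_identical(unname(ch$per_sample_pass), c(1L, 2L))
  expect_identical(ch$median_pass, 1L)
})
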