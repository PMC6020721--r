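---
title: "QSM evaluation: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QSM evaluation: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsm)
```

## The quality model

A Quality Sequencing Minimum (QSM) is a declared floor on the three
metrics that determine whether targeted sequencing data can support a
clinical call:

* **C — depth of coverage.** The number of filtered reads whose alignment
  covers a reference position. Low depth is the classic cause of false
  negatives.
* **B — base quality.** The Phred-scaled probability that a base call is
  wrong, per base per read. The QSM requires that at least `P_Y`% of the
  base calls at a position reach Phred `Y`.
* **M — mapping quality.** The Phred-scaled probability that a read is
  aligned to the wrong locus, one score per read. The QSM requires that
  at least `P_Z`% of the reads covering a position reach Phred `Z`.
  Regions homologous to pseudogenes (the motivating examples are *PTEN*
  with *PTENP1* and *PMS2* with *PMS2CL*) attract mis-mapped reads and
  collapse this metric while C and B look healthy.

A test region — an opaque interval from a BED file; the package imposes
no granularity — **meets the QSM only if every single base** of the
region passes all three metrics. This all-bases rule is deliberately
unforgiving: a one-base coverage hole is exactly the kind of defect a
summary statistic (mean depth, fraction covered) hides. A region failing
any metric at any base is "QSM-flagged" for additional scrutiny; across a
cohort, regions flagged in more than a declared percentage of samples
(default 1%) are escalated for review.

The thresholds are parameters of the laboratory's assay, not of this
package. `C50_B10(85)_M20(95)` is the package-wide default in examples
and fixtures because it is the published calibration for a deep
(>1000× average) hybridisation-capture panel whose variant caller hard
filters reads at MQ < 20 and tolerates low-BQ bases when read overlap is
dense; a laboratory with 100× average depth would declare a much lower
`X`.

## Pileup conventions

The profiler (`profile_region()`) reads alignments through
Rsamtools/GenomicAlignments and reduces them to four counts per
reference position: `depth`, `n_base`, `n_bq_pass`, `n_mq_pass`. The
conventions, chosen to match standard pileup semantics:

* **Deletion spans count toward depth.** A read whose CIGAR carries a
  `D` over a position is aligned across it and attests to coverage, so it
  counts for C and for M's denominator (MQ is a per-read property). It
  presents no base call, so it is excluded from `n_base`, the denominator
  of the B fraction — base quality is a property of a base call.
* **Reference skips (`N`) do not count** anywhere: they assert the read
  has no alignment at the position.
* **MAPQ 255 means "unavailable"** per the SAM specification and never
  passes any `Z > 0`: unknown quality must not pass a quality floor.
  With `Z = 0` the floor is vacuous and every read passes.
* **No overlap-pair deduplication and no BAQ recalculation.** Both mates
  of an overlapping pair count separately — the B threshold's rationale
  explicitly leans on overlap depth — and qualities are taken as stored.
* **Read intake** excludes unmapped, secondary, supplementary,
  duplicate-marked and QC-fail records by default
  (`read_filter_policy()`), mirroring common variant-caller intake. Every
  switch is exposed because the QSM should reflect the caller actually
  used; the policy is echoed into every output header.

Coordinates are BED-native (0-based, half-open) internally; every
user-facing report prints 1-based inclusive positions. Overlapping BED
regions are legal and evaluated independently; the strand column is
ignored (all three metrics are strand-agnostic).

## Numerical choices

Percentage comparisons are decided in scaled-integer arithmetic:
a position passes B iff `10000 * n_bq_pass >= round(100 * P_Y) * n_base`
(and likewise for M with `depth` as denominator). This makes the
boundaries exact — 85 of 100 reads at `P_Y = 85` passes, 17 of 20 passes,
84 of 100 fails — with no floating-point artifacts. All thresholds are
inclusive (`>=`, "at least"). Percentages may carry up to two decimals;
the paper-style integer percentages are the common case.

Degenerate inputs: a position with `n_base = 0` (or `depth = 0` for M)
has pass fraction defined as 0 and fails any positive percentage — a
coverage gap therefore flags C, B and M together, since absent reads are
absent evidence for every metric. It still passes a percentage of 0, so
the vacuous QSM `C0_B0(0)_M0(0)` passes everything. Zero-width regions
are rejected at BED load; an empty profile is an error, not a pass.

The cohort review rule is likewise exact: a region is review-flagged iff
`100 * fail_count > review_percent * n_samples`, a strict inequality. At
`n = 960` and 1% the minimal trigger is 10 failures (9.6 is the exact 1%
point); at `n = 100` it is 2; a single-sample cohort escalates any
failure. The median of per-sample pass counts uses the lower-middle
order statistic for even cohorts, so the reported median is always an
observed count and the computation is deterministic.

Phred thresholds above 93 (the highest score encodable in Sanger FASTQ)
are rejected and values above 60 draw a warning; both guards exist to
catch transposed digits in hand-typed QSM strings, since no current tool
emits such scores.

## Grammar decisions

Tool-chain entries like `BWAv0.7.5a` concatenate name and version with a
literal `v`; the parser splits at the *last* `v` immediately followed by
a digit, which handles names containing `v` before letters and versions
like `0.7.5a`. Exception clauses follow the report-statement form
`{except PMS2 exons 12-15}`; italics asterisks are stripped and multiple
exceptions are comma-separated inside one brace pair. The
`C..._B...(...)_M...(...)` core is whitespace-free; whitespace is
tolerated only around ` using ` and the brace clause. Rendering then
parsing is an exact round trip (property-tested over random
specifications); the short style drops the tool chain, so only the full
style round-trips it.

In report statements, the canonical styles express "not met" solely
through exception clauses — the text still reads "This test met QSM ...
{except ...}", with the excluded regions named. Grouping of failing
regions under one display label ("PMS2 exons 12-15") is driven by a
user-supplied mapping rather than inferred from region names, since
naming conventions vary across laboratories. When failures exist without
a sanctioned exception the package adds a "did not meet" variant listing
them; it is marked non-canonical (`canonical = FALSE`, and
`statement_met: false` in the JSON summary) because a clinical report
should never silently omit an unsanctioned failure.

## What the synthetic fixtures emulate — and what they do not

`build_fixture()` realises `region_recipe()`s as valid coordinate-sorted
SAM/BAM: each recipe places `depth` reads fully spanning its region with
a few bases of seeded start/end jitter, a chosen fraction of reads at a
"high" base quality (rest low), a chosen fraction at a "high" mapping
quality (rest low, e.g. 0 for pseudogene-style collapse), and optional
per-read CIGAR overrides for deletion/insertion coverage cases. Because
placement and qualities are fully controlled, every per-base count has a
closed-form expectation, computed by the generator's own bookkeeping and
written alongside the data — this expectation table, plus an independent
brute-force per-column scan of the SAM text in the test suite, are the
two oracles the profiler is validated against.

The fixtures deliberately model *placement and quality structure only*:
uniform base identity, no substitution errors, no fragment-size or GC
model, no paired-end flags. Passing tests therefore demonstrate that
counting, thresholding, aggregation and reporting are exact on data with
known structure; they do not demonstrate robustness to artefacts of real
library preparation (strand bias, soft-clip pileups at structural
variants, chimeric pairs). On real BAMs those artefacts enter through
the counts themselves, so the evaluation semantics are unchanged, but
threshold calibration remains the laboratory's validation task.

Default study conditions used in tests and the acceptance script: worked
examples use 60 reads per region with 55/60 base-quality passes where a
near-boundary B fraction is wanted; pseudogene-style recipes set
`mq_pass_frac` at or below 0.5, mirroring the reported 52–99% low-MQ read
proportions over *PMS2* exons 12–15 qualitatively; the acceptance cohort
is 24 samples × 12 regions of width 60 — large enough to exercise the
review rule away from its degenerate edges while keeping a laptop-scale
runtime; randomized property fixtures use 50 recipes of widths 8–40 and
depths up to 90 so that the brute-force oracle stays fast.

## Workflow and exit codes

`run_sample()` returns (and the CLI `check` subcommand exits with) 0
when every region passes or all failures are sanctioned exceptions, 3
when unsanctioned QSM-flagged regions exist, and 2 on input errors —
malformed QSM, defective BED, missing BAM index (the error names the
expected `.bai` path), or a chromosome-name dialect mismatch ("chr10" vs
"10"), which is detected against the BAM header and reported with both
spellings rather than silently profiling zero coverage. The exit code is
a pure function of the evaluation results and the exception list, making
the tool usable as a pipeline QC gate. All outputs embed the full QSM
string, the read-filter policy and the package version in their headers,
applying the same transparency principle to this tool that the QSM
applies to sequencing tests.

## Known limitations

* CRAM is accepted only insofar as the underlying I/O layer resolves it
  transparently; only BAM+BAI is tested.
* The profiler holds one region's reads in memory at a time; regions of
  megabase scale with very deep coverage would need chunking.
* No per-region failing-base *count* is reported, only the flag and the
  leftmost failing position per metric — sufficient to locate a defect,
  not to size it.
* Exception grouping is label-driven; the package does not infer exon
  ranges from region names.
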