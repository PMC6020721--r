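# qsm — Quality Sequencing Minimum evaluation for targeted NGS panels

Clinical laboratories running targeted next-generation sequencing need to
state, consistently and transparently, how good the data behind each test
was. Three metrics carry that information: depth of coverage (how many
reads cover a base), base quality (was the base called correctly) and
mapping quality (was the read placed correctly). A **Quality Sequencing
Minimum (QSM)** packs a laboratory's declared minimum for all three into a
single machine-readable statement:

```
CX_BY(P_Y)_MZ(P_Z) [using tool1v<ver>_tool2v<ver>_...]
```

A region meets the QSM when **100% of its constituent bases** have

* depth of coverage ≥ `X` reads (metric **C**),
* Phred base quality ≥ `Y` in at least `P_Y`% of reads (metric **B**), and
* Phred mapping quality ≥ `Z` in at least `P_Z`% of reads (metric **M**).

For example, `C50_B10(85)_M20(95)` demands ≥50 reads per base, BQ ≥ 10 in
at least 85% of reads and MQ ≥ 20 in at least 95% of reads. The optional
`using` suffix records the exact tool chain (base calling, mapping,
variant calling) the thresholds were calibrated for. Everything the QSM
needs is already in a sample's BAM/BAI, so any pipeline can compute it.

This package, for bioinformaticians and clinical-pipeline engineers,
provides:

* a parser/renderer for QSM strings, including tool chains and
  `{except ...}` exception clauses (`parse_qsm()`, `render_qsm()`,
  `qsm_to_json()`);
* a per-base pileup profiler over BED test regions from indexed BAMs
  (`profile_region()`, with `bq_fraction()` / `mq_fraction()`), with
  configurable SAM-flag read filters (`read_filter_policy()`);
* region and sample evaluation with exact, inclusive threshold arithmetic
  (`evaluate_region()`, `evaluate_sample()`);
* cohort aggregation with the ">1% of samples" review rule
  (`summarize_cohort()`, `region_fail_table()`);
* report statements for genetic test reports (`make_statement()`);
* a synthetic SAM/BAM fixture generator with closed-form per-base
  expectations (`region_recipe()`, `build_fixture()`,
  `random_region_recipes()`);
* single-sample and cohort workflows with QC-gate exit codes
  (`run_sample()`, `run_cohort()`) and a command-line front end at
  `system.file("cli", "qsm.R", package = "qsm")` with subcommands
  `check`, `cohort`, `fixture` and `parse`.

## Worked example

Simulate one sample with a healthy region and a region whose mapping
quality has collapsed (as happens over genes with near-identical
pseudogenes), then evaluate it:

```r
library(qsm)

qsm <- parse_qsm("C50_B10(85)_M20(95)")
recipes <- list(
  region_recipe("chr7", 6026387, 6026447, "PMS2_ex12", depth = 60,
                mq_pass_frac = 0.40, seed = 2),
  region_recipe("chr17", 41245603, 41245663, "BRCA1_ex10", depth = 60,
                seed = 1))
fx <- build_fixture(recipes, "demo", qsm = qsm)

ev <- evaluate_sample(fx$bam, fx$bed, qsm)
ev
#> sample demo against QSM C50_B10(85)_M20(95)
#>   regions meeting QSM: 1/2 (C: 2, B: 2, M: 1)
#>   QSM-flagged: PMS2_ex12
```

Every base of `PMS2_ex12` is covered by 60 reads with good base calls,
but only 24/60 reads (40%) meet MQ ≥ 20 — below the required 95%, so the
region fails metric M and is QSM-flagged:

```r
head(profile_region(fx$bam, load_bed(fx$bed)[1, ], qsm), 3)
#>   chrom     pos depth n_base n_bq_pass n_mq_pass
#> 1  chr7 6026387    60     60        60        24
#> 2  chr7 6026388    60     60        60        24
#> 3  chr7 6026389    60     60        60        24
```

If the laboratory has validated that region by an orthogonal method, the
failure can be sanctioned as a report exception:

```r
make_statement(qsm, ev, "short",
               exception_labels = c(PMS2_ex12 = "PMS2 exon 12"))$text
#> This test met QSM C50_B10(85)_M20(95) {except PMS2 exon 12}
```

Across a cohort, `summarize_cohort()` counts per-region failures and
review-flags any region failing the QSM in more than 1% of samples (a
strict integer inequality: with 960 samples the minimal trigger is 10
failures), and reports the median number of passing regions per sample.

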