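# triocnv

Consensus post-processing of multi-caller copy-number variant (CNV) calls
from whole-exome sequencing (WES) of case-parent trios.

Read-depth CNV callers applied to WES data (GATK gCNV, ExomeDepth, CODEX,
cn.MOPS and kin) disagree substantially: call counts per sample can differ
by an order of magnitude and each tool carries its own false-positive
profile. A standard remedy is consensus calling: an event is considered
high-confidence only when at least two independent callers report it at
matching coordinates. `triocnv` implements that post-processing stage for
trio designs, from raw standardised call sets through to a prioritised
per-proband report:

1. **Call-set IO** — a BED-like tab-separated dialect for per-sample,
   per-tool CNV calls (0-based half-open intervals, DEL/DUP), trio
   manifests, and AnnotSV-style annotation tables.
2. **Consensus calling** — for every pair of callers, same-type calls are
   intersected under a *reciprocal-overlap* criterion: intervals `a`, `b`
   agree when the shared length `L = max(0, min(a.end, b.end) − max(a.start,
   b.start))` satisfies `L/|a| ≥ f` **and** `L/|b| ≥ f` (default `f = 0.5`).
   Intersection fragments of the same type are merged transitively
   (bookended fragments included) and merged regions supported by
   `≥ min_tools` distinct callers (default 2) are retained.
3. **Trio classification** — a proband consensus CNV is *de novo* when no
   same-type parental CNV passes the reciprocal criterion, otherwise
   inherited (maternal / paternal / both).
4. **Prioritisation** — ACMG class (1–5) and Exomiser phenotype score
   gates: keep classes {3, 4, 5} with score ≥ 0.5 (scores > 0.7 tiered
   "highly specific"), and join inheritance labels into a report table.
5. **Cohort summaries** — per-tool DEL/DUP counts, size-bin histograms,
   per-tool consensus overlap rates, and a paired Wilcoxon signed-rank test
   (exact under ties up to 25 pairs) for deletion/duplication bias.
6. **Synthetic cohorts** — a seeded simulator emulating four imperfect
   callers (per-size-bin sensitivity, breakpoint jitter, minimum detectable
   size, independent false positives) over trios with Mendelian ground
   truth, plus precision/recall evaluation against that truth.

Everything is tidyverse-native: functions take data frames and return
tibbles, fitted objects have `tidy()`/`glance()` methods, and `plot_*()`
functions return ggplots.

## Worked example

```r
library(triocnv)

# three callers report the same deletion with different breakpoints
calls <- tibble::tibble(
  chrom = "1", start = c(0, 40, 80), end = c(100, 140, 180),
  cnv_type = "DEL", sample_id = "S1", tool_id = c("A", "B", "C"))
call_consensus(calls)
#> # A tibble: 1 × 8
#>   chrom start   end cnv_type sample_id n_tools tools n_fragments
#> 1 1        40   140 DEL      S1              3 A,B,C           2
```

Pairs (A,B) and (B,C) each share 60 bp — 60% of both intervals, so both
pass `f = 0.5` — while (A,C) share only 20 bp (20%) and fail. The two
intersection fragments `[40,100)` and `[80,140)` overlap and merge into one
consensus deletion `[40,140)` supported by all three callers.

End-to-end on a simulated 26-trio cohort:

```r
res <- run_pipeline_end_to_end(simulation_params(), seed = 1)
glance(res)
#> # A tibble: 1 × 7
#>   n_trios n_raw_calls n_consensus consensus_precision consensus_recall
#> 1      26        4554        1000               0.998            0.973
#> # denovo_sensitivity 1, denovo_specificity 0.982
```

Of 4,554 raw caller calls, 1,000 consensus CNVs survive; 99.8% of them
correspond to a true simulated CNV (vs ~68% for each caller alone, the
cost being ~3% recall), and every simulated de novo event is recovered and
labelled de novo.

The bundled example annotation tables
(`inst/extdata/ofc_denovo_*.tsv`, transcribed report tables from a
syndromic orofacial-cleft trio study) demonstrate the prioritisation gates:

```r
ann <- read_annotations(system.file("extdata", "ofc_denovo_known_genes.tsv",
                                    package = "triocnv"))
kept <- filter_priority(ann)
nrow(kept)                        #> 10  (all rows pass: score >= 0.5, ACMG 3-5)
dplyr::n_distinct(kept$sample_id) #> 9   (one proband carries two CNVs)
sum(kept$tier == "highly specific") #> 4 (Exomiser score > 0.7)
```

## Documentation

The methods vignette (`vignettes/consensus-cnv-workflow.Rmd`) describes the
consensus model and its parameters, the trio classification and
prioritisation rules, the simulator's generative model and its limits, and
the package's numerical conventions.
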