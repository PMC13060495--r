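---
title: "Consensus CNV calling and de novo classification in case-parent trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus CNV calling and de novo classification in case-parent trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triocnv)
```

## The problem

Copy-number variants called from whole-exome read depth are noisy: exome
capture covers the genome sparsely and unevenly, so segmentation-based
callers disagree on which events exist and where their breakpoints lie.
When several callers are run on the same samples, requiring agreement
between at least two of them trades a little sensitivity for a large gain
in precision, because each caller's artefacts are largely tool-specific
while true events are seen by all sufficiently sensitive tools. In a
case-parent trio design the surviving high-confidence calls can then be
split into inherited events (also present in a parent) and candidate
*de novo* events (present only in the affected child), which carry most of
the diagnostic weight in congenital disorders.

`triocnv` implements this post-processing chain. It deliberately starts
*after* the callers: raw read-depth modelling, segmentation and
copy-number genotyping belong to the callers themselves, and annotation
scores (ACMG class, Exomiser phenotype score) are consumed as external-tool
outputs, never recomputed.

## Coordinate conventions

All intervals are 0-based half-open `[start, end)`, the BED convention, so
the size of an event is exactly `end - start`. Chromosome names are stored
verbatim (no "chr" stripping on input or output) but *compared* after
normalisation (strip a leading `chr`, upper-case), so `chr12` and `12`
match. Sorted outputs use natural chromosome order: numeric chromosomes
first, then X, Y, M. Input coordinates may carry thousands separators
(`18,528,750`), which some downstream-table exports produce; they are
stripped on parse. Loaded records are never "corrected": an annotation row
that places a gene on an unexpected chromosome is kept verbatim, because a
parser that second-guesses its input destroys the audit trail.

## The consensus model

For one sample, let each tool contribute a set of typed intervals (DEL or
DUP). The consensus recipe has three stages, exposed individually and as
`call_consensus()`:

1. **Pairwise intersection** (`intersect_pairwise()`). For every unordered
   pair of distinct tools and every pair of same-type calls, compute the
   shared length `L`. The pair passes at fraction `f` when `L >= f * |a|`
   and `L >= f * |b|` — the *reciprocal* overlap criterion, inclusive at
   the boundary ("at least"). Each passing pair emits a fragment whose
   interval is the *intersection region*. Deletions never pair with
   duplications, and calls never pair across samples.
2. **Same-type merging** (`merge_fragments()`). Fragments of one sample,
   chromosome and type that overlap — or lie within `merge_gap` bp, with
   the default 0 also merging bookended fragments, mirroring the usual
   interval-merge convention — are merged transitively into a region
   spanning their union. The region's supporting-tool set is the union of
   its fragments' tool pairs.
3. **Support filtering** (`filter_support()`). Regions supported by at
   least `min_tools` *distinct* tools are retained.

### Parameters

| parameter   | default | units | role |
|-------------|---------|-------|------|
| `f`         | 0.5     | fraction | reciprocal-overlap threshold; 0.5 is the conventional choice for CNV concordance analyses — strict enough to reject incidental overlap, loose enough to tolerate caller breakpoint error |
| `min_tools` | 2       | tools | minimum distinct supporting callers; 2 is the weakest agreement requirement that eliminates tool-private artefacts |
| `merge_gap` | 0       | bp    | maximum gap between same-type fragments that still merge; 0 merges touching fragments only |

### Design choices the procedure description leaves open

Several details are not fixed by the recipe above; the package resolves
them as follows, and each is covered by tests:

* **Fragment coordinates are the intersection region**, not either source
  interval: the agreement evidence is the shared region, and the
  subsequent merge then reconstructs the consensus span from shared
  regions only. This is the conservative reading.
* **Within-tool duplicates are collapsed first.** If one caller fragments
  an event into overlapping segments, those are unioned per type before
  pairing (`collapse_within_tool()`), so a single tool can never act as
  two supporters of the same region. The collapse can be disabled
  (`collapse = FALSE`), in which case each tool's same-type calls are
  assumed disjoint.
* **Support is counted from merged pair labels**: fragments from pairs
  (A,B) and (B,C) merging into one region yield support 3, since all three
  tools contributed evidence to the region. The alternative —
  re-intersecting merged regions against raw calls — gives the same result
  whenever calls are collapsed per tool, which the previous point ensures.
* **Ties and ordering**: all outputs are sorted by (chromosome natural
  order, start, end, sample, type, tool), making every stage deterministic
  given its input set.

The native implementation uses sorted interval sweeps (a first-fit
level decomposition reduces arbitrary interval sets to disjoint sorted
ones). The test suite checks it against an independent brute-force
reference — all-pairs enumeration plus repeated-scan merging — on hundreds
of random instances, along with the structural invariants: fragments are
contained in both sources, fragment counts are non-increasing in `f`,
consensus counts non-increasing in `min_tools`, per-sample same-type
consensus regions are disjoint, and replaying consensus output through the
pipeline reproduces it (idempotence).

## Trio classification

`classify_trio()` labels each proband consensus CNV by comparing it
against each parent's call set with the same machinery: a parental CNV of
the same type passing reciprocal overlap at `f` makes the call inherited
(maternal, paternal, or both); otherwise it is de novo. Three decisions
deserve note:

* **Parental sets default to the parents' consensus calls**, matching the
  symmetric treatment of all trio members. Raw per-tool parental calls can
  be supplied instead for a more conservative de novo definition (any
  single-tool parental evidence cancels de novo status); both are ordinary
  tibbles to the function.
* **The matching threshold reuses `f`** rather than introducing a second
  knob; nothing in the procedure suggests a different stringency for
  inheritance matching.
* **Sub-threshold parental overlap does not demote a call** from de novo.
  The `parental_matches` list-column is empty exactly for de novo calls,
  so borderline cases can be audited by re-running with a lower `f`.

An opposite-type parental event at the same locus never rescues a call
from de novo status: a deletion and a duplication are different variants.

## Prioritisation gates

Annotation records (coordinates, type, ACMG class 1–5, Exomiser score in
[0, 1], gene content) pass `filter_priority()` when the score is **at
least** `exomiser_min` (default 0.5) and the ACMG class is in `acmg_keep`
(default {3, 4, 5}: VUS, likely pathogenic, pathogenic — classes 1–2 are
benign calls that do not belong in a diagnostic report). Records with a
missing score fail the gate: a phenotype-driven gate cannot pass a record
with no phenotype evidence, though such records survive *parsing* so users
can re-examine them. Kept records are tiered "highly specific" when the
score **strictly exceeds** 0.7, otherwise "consistent". The boundary
conventions (inclusive at 0.5, strict at 0.7) follow the natural-language
readings "at least 0.5" and "greater than 0.7"; where wording conflicts,
the inclusive methods-style statement wins, which only matters for records
scoring exactly 0.5.

`build_report()` joins gated records to inheritance labels on (sample,
chromosome, type) by exact coordinates first, then by reciprocal overlap
at `f` — annotation coordinates sometimes differ slightly from consensus
coordinates after region-level annotation — and emits the conventional
report layout with `size = end - start`.

## The synthetic cohort generator

Controlled-access patient data cannot ship with a package, so the
simulator provides the test bed: trios with known CNV truth observed
through imperfect callers. Defaults (26 trios) match the scale of a
realistic WES trio cohort study.

The generative model, per trio:

* Each parent draws `Poisson(12)` true CNVs, placed uniformly on a
  two-chromosome 50 + 50 Mb synthetic genome, sizes log-uniform on
  [500 bp, 6 Mb], DEL with probability 0.5. Twelve consensus-grade CNVs
  per genome scaled to a 100 Mb model genome is in line with per-sample
  consensus yields in WES cohorts; the log-uniform size law reproduces the
  heavy right tail of CNV size distributions.
* Each parental CNV transmits to the proband with probability 0.5 at
  identical coordinates; the proband adds `Poisson(1)` de novo CNVs
  present in neither parent.
* Truth CNVs are rejection-sampled to be pairwise disjoint *within a
  trio*, so inheritance bookkeeping and truth matching are unambiguous.
* Each of four tool profiles then observes every individual's truth:
  detection with per-size-bin sensitivity, breakpoint jitter, a minimum
  detectable size (the conservative profile's 1 kb floor reproduces the
  qualitative caller contrast of a tool blind to sub-kb events), and
  `Poisson(fp_per_sample)` false positives placed independently per tool —
  the independence that makes two-tool consensus informative. A
  `jitter_sd` of 200–500 bp reflects exon-spacing-limited breakpoint
  resolution; per event the jitter sd is capped at 10% of the true size,
  since segment boundaries of a small detected event track the event
  itself — without that cap, 500-bp events would carry breakpoint noise
  larger than themselves, which no read-depth caller produces for events
  it detects at all.

Default tool profiles (sensitivity, FP/sample, jitter sd, min size):
0.85/3/300/0, 0.95/8/500/0, 0.80/4/400/0, 0.70/1/200/1000 — a spread from
"sensitive but noisy" to "conservative and size-limited", chosen on
plausibility; no published per-tool operating characteristics were fitted.

**What the simulator does not model**: exome target structure (events are
placed uniformly, not on exons), GC/depth-driven *correlated* artefacts
between tools (a `rho` for shared false positives is a natural extension;
with correlated errors consensus precision gains shrink), mosaicism,
multi-allelic copy states, sex chromosomes, and genotyping error in
parents beyond detection failure. Passing tests therefore demonstrate the
*algorithmic* correctness of consensus/trio/summary logic and its
statistical behaviour under independent errors — not calibrated
performance on real WES data.

`evaluate_calls()` scores any call set against truth by greedy one-to-one
matching in decreasing reciprocal-overlap order (same type, `>= f` both
ways), so a truth event claimed by two overlapping calls counts once.
`denovo_confusion()` scores de novo labelling on truth-matched proband
consensus calls; unmatched de-novo-labelled calls count as false
positives.

## Statistical notes

The deletion/duplication bias test (`deldup_signed_rank()`) is a paired
Wilcoxon signed-rank test on per-sample (DEL, DUP) count pairs. Zero
differences are discarded (classic convention; Pratt's zero-rank method is
available), absolute differences are ranked with mid-ranks on ties, and
`W` is the positive-rank sum. For up to 25 nonzero pairs the two-sided
p-value is exact *including ties*: the null distribution of `2W` (doubling
makes mid-rank sums integral) is built by generating-function convolution
over the doubled ranks, and `p = min(1, 2 min(P(W <= w), P(W >= w)))`.
Beyond 25 pairs the tie-corrected normal approximation without continuity
correction is used. The exact path is validated against full sign
enumeration for up to 10 pairs and against the standard reference
implementation on tie-free inputs; all-zero differences yield a degenerate
result with `p = 1` rather than an error.

Reported percentages (overlap rates, demographic fractions) are rounded
half *up* to one decimal — the convention of printed reports — rather than
R's round-half-even.

## Problem sizes and determinism

All simulations are deterministic given their seed. The test suite runs at
deliberately moderate scales — random consensus instances of up to 100
calls across 4 tools for oracle equivalence, cohorts of 2–26 trios for
pipeline properties, and 100 seeded replicates of the 26-trio cohort for
the consensus-dominance experiment — sizes at which the brute-force
oracles remain exact and the full suite runs in minutes. The acceptance
script reruns the same computations from scratch with a user-supplied
seed.

## Known limitations

* Consensus requires two tools by construction; a cohort run with one
  caller yields an empty consensus rather than falling back to raw calls.
* Support counting is set-based: a tool supporting two *disjoint* parts of
  a merged region still counts once, and no per-fragment quality
  aggregation is attempted (caller scores are passed through, not used).
* The inheritance classifier is interval-based only; it cannot distinguish
  a true de novo event from a parental event missed by every caller, which
  is why the conservative `raw` parental-set option exists.
* The signed-rank normal approximation under Pratt zero handling uses the
  standard tie-corrected moments, which is approximate when many zeros are
  down-weighted; the exact path is unaffected.
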