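---
title: "Screening exon-array data for fusion-gene breakpoints: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening exon-array data for fusion-gene breakpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusescreen)
```

## The screening model

A gene fusion joins the 5′ portion of one gene to the 3′ portion of
another. The fused fragment is transcribed from the partner gene's
promoter, so within the partner gene the exon-level expression of the
rearranged sample shows a step: one side of the breakpoint at the level
driven by the active promoter, the other at the gene's (often low) native
level. On an exon array each gene is a *transcript cluster* of probe sets
laid along the transcript, so this step is observable as an intragenic
discontinuity — if probe-set intensities can be made comparable.

They cannot be compared directly. Amplification and labeling efficiency
differ per RNA region and each probe set has its own hybridization
properties, so intensity and dynamic range vary greatly between probe sets
of one gene. Intensities *are* comparable across samples at a fixed probe
set, because those biases are shared. `screen()` therefore converts each
probe set's intensities into fractional ranks of the `N` samples and works
entirely in rank space:

1. Keep probe sets with hybridization target `unique` (cross-hybridization
   control), evidence level `core` (probe sets on known exon sequence),
   and intensity ≥ `min_intensity` in at least one sample (floor against
   all-background probe sets). Keep clusters retaining at least
   `min_cluster_probesets` eligible probe sets.
2. Rank the samples at each probe set, ascending, ties averaged.
3. For every cut point `k` splitting the cluster's ordered probe sets into
   5′ and 3′ terminal groups of at least `min_group_size` each, and for
   every sample, compute the sample's mean rank per group.
4. A cut qualifies when the absolute mean-rank difference is at least
   `rank_diff_fraction * N` **and** at least one group's rank SD is at
   most `max_group_rank_sd`. Any sample with a qualifying cut in a cluster
   is a breakpoint candidate there.

Averaging ranks over terminal groups absorbs single-probe-set rank flips
caused by alternative splicing or residual cross-hybridization; the SD
guard rejects samples whose ranks inside a group are themselves erratic,
which is the signature of quantification noise rather than a coherent
step. Using the absolute difference makes detection independent of the
direction of the expression change (5′ or 3′ activation), which matters
because either partner can contribute either end.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `median_target` | 100 | intensity | per-array linear scaling target applied before filtering |
| `min_intensity` | 30 | intensity (post-scaling) | floor, `>=`, in at least one sample |
| `min_cluster_probesets` | 8 | probe sets | minimum eligible probe sets per scanned cluster |
| `min_group_size` | 4 | probe sets | minimum per terminal group; with 8-probe-set clusters exactly one cut (k = 4) is admissible |
| `rank_diff_fraction` | 0.70 | fraction of N | qualifying bound on the mean-rank difference, `>=`, no rounding (N = 17 gives 11.9) |
| `max_group_rank_sd` | 2.0 | rank units | ceiling on min(SD5′, SD3′), `<=` |

The defaults are the published operating point for 17-sample cell-line
panels; `screen_params()` validates the joint constraints (e.g.
`min_cluster_probesets >= 2 * min_group_size`).

## Numerical and procedural choices

Several details are not fixed by the screen's published description; the
package pins them as follows, and the test suite asserts each one.

- **Ranking direction**: ascending (lowest intensity → rank 1). Detection
  uses the absolute difference, so the choice only affects reported mean
  ranks, not candidates.
- **Ties**: fractional (average) ranks, so each probe set's ranks always
  sum to N(N+1)/2 — a conservation law the tests check on every scored
  cluster.
- **SD denominator**: sample SD (n − 1). Both thresholds are inclusive
  (`>=` for the difference, `<=` for the SD), mirroring "or more" / "or
  lower" phrasing.
- **Ranking pool**: the examined sample is ranked together with all other
  samples in one joint pool; there is no leave-one-out re-ranking.
- **Best cut among several qualifying cuts**: maximum rank difference,
  then smaller min(SD5′, SD3′), then smaller cut index. One breakpoint per
  (cluster, sample) is reported, with all qualifying cuts retained in a
  list-column.
- **Transcript order**: genomic start ascending on `+` clusters,
  descending on `-`; ties on start broken by probe-set ID so the index is
  a pure function of its input. Clusters mixing chromosome or strand are
  rejected as annotation integrity errors.
- **Coordinates** are 1-based inclusive; annotation enum tokens are
  case-insensitive on input and canonical lowercase internally.
- **Serialization**: candidate TSVs write numeric fields with 6
  significant digits, which makes write → read → write round trips
  byte-identical.
- **Degenerate inputs**: an empty matrix yields an empty candidate table;
  missing values are rejected at ingestion; a zero-median sample is an
  error naming the sample; on log-scale profile plots, zero intensities
  are clamped to half the smallest positive value in the cluster, with a
  warning.

Two invariants worth stating explicitly because the tests rely on them:
the screen's output is bitwise invariant under any strictly increasing
per-probe-set transform of the intensities (once the intensity floor has
been applied), and mirroring transcript orientation (strand flip) mirrors
every reported cut `k → n − k` with identical statistics, 5′/3′ roles
exchanged.

## The alternative z-score scorer

For comparison the package includes the standardized-intensity approach
used in earlier exon-array fusion screens: z-score each probe-set row
across samples, then compare the examined sample's 5′ and 3′ z-values at a
cut with a two-sample t-test (`lin_score_cluster()`). Welch's
unequal-variance form is used, since group variances of z-values have no
reason to be equal. This scorer retains magnitude information — useful for
judging effect size — but is correspondingly sensitive to outlier
intensities, which is exactly what the rank conversion buys robustness
against. Zero-variance rows are dropped with a warning; a two-sided
p-value and the Welch t are returned, and `lin_screen()` tabulates the
minimum-p cut per (cluster, sample) for concordance checks.

## Candidate triage

The published evaluation of screen hits was partly manual; `triage()`
makes the three exclusion rules explicit, applied in fixed order with
first-match verdicts so drop counts are reproducible:

1. **Isoform-explained** (`drop_isoform`): the candidate's higher-expressed
   side covers at least `match_fraction` (default 0.90) of a registered
   isoform's probe sets while the lower side is disjoint from that isoform
   — the apparent step coincides with an annotated isoform boundary.
2. **Multi-gene cluster** (`drop_multigene`): the cluster overlaps ≥ 2
   annotated genes; steps there usually mark the boundary between the
   co-clustered genes.
3. **Reference-similar** (`drop_reference_similar`): some designated
   reference sample's signed mean-rank difference at the candidate's best
   cut has the same sign as, and at least `similarity_fraction` (default
   0.5) of the magnitude of, the examined sample's.

Both similarity thresholds operationalize judgments that were originally
visual; they are surfaced as `triage_params()` so users can tighten or
relax them. The final visual-inspection step of candidate selection is
deliberately *not* automated — `plot_cluster_profile()` supports it by
drawing per-sample intensity lines in transcript order with the examined
sample highlighted, the breakpoint marked, and the per-probe-set
annotation letters (C/e/f, U/S/M) along the plot edges.

## The simulator

`simulate_dataset()` generates summarized probe-set × sample matrices with

```
intensity(p, s) = affinity(p) · expression(s, cluster(p)) · noise(p, s)
```

- `affinity(p)` ~ log-normal (`affinity_log_mean = log(100)`,
  `affinity_log_sd = 1`): probe sets of one gene differ in intensity by
  orders of magnitude, as real probe sets do.
- `expression(s, c)` ~ log-normal (`expression_log_sd = 0.5`): each
  sample's expression of each gene, shared across the gene's probe sets —
  this is what makes null rank vectors *correlated* along a cluster.
- `noise(p, s)`: multiplicative log-normal with mean 1 and coefficient of
  variation `noise_cv` (default 0.15).

A fusion event in sample *s* at cut *k* does two things: the sample's
native expression of the cluster is re-drawn from the low tail of the
expression distribution (quantile uniform in `[0, 0.15]`), and the fused
side's probe sets are multiplied by `fold_change` (default 8). The
low-tail baseline encodes the biology that makes these fusions visible in
the first place: the partner fragment is transcribed from the *other*
gene's promoter precisely because its own promoter is weak in that sample.
Without it, the un-fused side's mean rank would be uniform over 1..N and
no parameter setting could reach high sensitivity at the 0.7 · N
criterion; with it, the examined sample separates from the references on
both sides of the cut, which is the published profile shape. Events with
`fold_change = 1` are inert by contract and leave the dataset untouched.

Automatically placed events are restricted to cuts that leave at least
`min_group_size` *observable* probe sets on each side — label-eligible
(core, unique) and above the intensity floor on the normalized baseline
matrix. A fusion whose breakpoint falls in a region the array's filters
cannot interrogate is undetectable by construction and tells us nothing
about the statistic; explicitly supplied events are validated only for
geometric sanity, so undetectable events can still be constructed
deliberately (the `tall_like` fixture does, near the group-size boundary).
Truth cut indices count *all* probe sets of the cluster;
`align_truth_cuts()`/`summarize_recovery()` map them into the eligible
ordering before comparing against reported cuts.

What the simulator does **not** emulate: probe-level summarization,
background/GC effects, correlated cross-hybridization between specific
probe sets, partial (subclonal) fusions, or intensity saturation. Passing
the recovery and null-control tests therefore demonstrates correctness of
the statistic and its implementation under the stated generative model,
not performance on any particular real dataset, where summarization
artifacts and reference-panel composition matter. Stock fixtures
(`make_fixture()`) use a tighter affinity spread (`affinity_log_sd = 0.5`)
so that no fixture probe set falls below the default intensity floor and
the advertised cluster geometry is stable across the fixture's seed.

## Problem sizes used in the test suite

The suite's acceptance-level checks run at the following sizes, chosen to
match the 17-sample validation geometry while keeping the default test run
fast: oracle equivalence against a first-principles enumerator on 100
random clusters of ≤ 12 probe sets × ≤ 8 samples; parameter recovery on
210 injected 8-fold events (N = 17, noise CV 0.15), asserting ≥ 95%
sensitivity with the reported cut within ±1 eligible probe set of truth;
false-positive control on 1000 event-free clusters (≤ 1% of
(cluster, sample) pairs flagged, under both the correlated and an i.i.d.
noise null); and the two triage narratives (20 candidates → 15 keepers
with 4 isoform-explained and 1 reference-similar; 23 → 11 with 9
isoform-explained and 3 multi-gene). `scripts/acceptance.R` recomputes all
of these from scratch at an arbitrary seed.

## Limitations

- The method detects *expression* discontinuities; fusions that do not
  change expression between exon groups are invisible to it, and breakpoint
  placement is limited to probe-set resolution — genomic DNA breakpoints
  cannot be localized.
- Genes whose usable terminal group would contain fewer than
  `min_group_size` eligible probe sets (short genes, or breakpoints very
  close to a transcript end) cannot be scanned; this reproduces the known
  failure to detect some real fusion partners whose flanking probe-set
  count is three or fewer.
- Results depend on the reference panel: the rank of the examined sample
  is only meaningful relative to the other arrays in the pool, so
  reference samples should show moderate expression variance for the gene
  in question.
- Probe-set summarization is out of scope; the package ingests summarized
  matrices and applies only the per-array median-to-100 linear scaling.
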