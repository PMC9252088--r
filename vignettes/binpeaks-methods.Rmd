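---
title: "Bin-based binomial peak calling: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-based binomial peak calling: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binpeaks)
```

## The statistical model

CUT&Tag and related tethered-enzyme assays produce paired-end fragment
libraries whose background is extremely sparse: most of the genome
carries near-zero coverage, and true binding sites stand out as local
pileups ranging from a few hundred bp (H3K4me3-like promoter marks)
to tens of kb (H3K27me3-like repressive domains). `binpeaks` detects
those pileups with a deliberately global null:

1. **Binning.** Each chromosome is covered by bins of width `step`
   whose starts sit on a grid spaced `slide` bp apart. With the
   defaults (`step = 100`, `slide = 50`) every interior position lies
   in exactly two bins, which halves the chance that a narrow pileup is
   split across a bin boundary. We interpret `slide` as the *offset
   between consecutive bin starts*: for the defaults the offset and the
   bin overlap coincide at 50 bp, and in broad mode (5000/1000) the
   offset reading is the one that yields a dense tiling of domains.
2. **Counting and normalization.** A fragment increments every bin it
   overlaps by >= 1 bp. Counts are scaled to counts per million (CPM)
   using the library fragment depth — not the sum of bin counts, which
   double-counts under overlapping bins.
3. **Control scaling.** With an IgG/input library on the same grid,
   each sample bin is damped by the control's relative CPM:
   `count * (1 - cpm_control / cpm_sample)` where the sample CPM
   exceeds the control CPM, and 0 otherwise. The comparison is made on
   the CPM scale because raw counts from libraries of different depth
   are not comparable. The equality case is assigned to the zero
   branch: equal normalized signal is no evidence of enrichment. An
   empty control bin leaves the sample count unchanged, and a sample
   scaled against itself is zeroed everywhere.
4. **Binomial test.** Bin counts are modelled as X ~ Binomial(n, p)
   with `n` the library depth and `p` the mean count of non-zero bins
   divided by `n` — a genome-wide estimate dominated by background
   bins, since enriched bins are a tiny minority. Bins with counts
   strictly greater than `minreads` receive the exact upper tail
   P(X >= x); Benjamini–Hochberg correction is applied over exactly
   that tested family (testing bins that can never pass `minreads`
   would only deflate power), and bins with adjusted p <= `pthresh`
   are retained.
5. **Merging.** Retained bins merge into a peak when they overlap or
   when the gap between them is at most `mdist` bp; bins on different
   chromosomes never merge. Peaks narrower than `minwidth` are
   discarded.

The pipeline is fully deterministic: identical inputs and parameters
produce byte-identical BED output and manifests.

### Parameters

| Parameter  | Default | Units | Role |
|------------|---------|-------|------|
| `step`     | 100 (5000 broad) | bp | bin width; sets the resolution of the test |
| `slide`    | 50 (1000 broad)  | bp | spacing of bin starts; `< step` gives overlapping bins |
| `minreads` | 15      | fragments | minimum bin count (strict `>`) to enter testing; guards the tail test against the near-empty majority of bins |
| `pthresh`  | 0.05    | —     | adjusted-p cutoff (`<=`) |
| `mdist`    | 150     | bp    | maximum gap between significant bins merged into one peak; raise to 1000–3000 for broad marks |
| `minwidth` | 150     | bp    | minimum emitted peak width |

Two threshold conventions deserve explicit statement. `minreads` is a
strict inequality (a bin with exactly 15 counts is not tested) and
significance is inclusive (adjusted p exactly at the cutoff passes);
the boundary cases have measure zero in practice but the conventions
are fixed and tested. Filtering is on *BH-adjusted* p-values; an
unadjusted-p variant can be emulated by setting `pthresh` after
inspecting the per-bin table returned by `test_bins()`, but adjusted
filtering is the package's default and only documented behavior.

### Numerical choices

- Control-scaled counts are real-valued, while the binomial test needs
  integer successes; counts are rounded half-away-from-zero before both
  `minreads` filtering and model estimation.
- `estimate_binomial_model()` refuses all-zero coverage ("no signal"),
  but `call_peaks()` short-circuits earlier: when no bin exceeds
  `minreads` (including the self-control case) it returns an empty
  peak set without fitting a null.
- The per-peak BED score is `-log10(min adjusted p)` capped at 3100,
  for narrowPeak-style compatibility; an adjusted p of exactly zero
  maps to the cap.
- Tail probabilities use `pbinom(x - 1, n, p, lower.tail = FALSE)`,
  exact to double precision; the test suite verifies them against
  brute-force summation over an exhaustive grid for n <= 50.

## Benchmarking machinery

`high_confidence()` merges the union of replicate peak sets into
disjoint blocks (chains of >= 1 bp overlaps) and keeps blocks to which
at least `min_support` distinct replicates contribute. Overlap of
>= 1 bp is the membership criterion throughout the benchmark module —
the interval-intersection semantics of standard genome-arithmetic
tooling.

`prepare_standard()` filters a scored reference peak set at
-log10 p strictly greater than 10 and gap-merges survivors within
1000 bp. `rank_counts()` scores each consensus interval by its
fragment count, and `roc_pr()` sweeps thresholds over the unique
scores, descending, with a sentinel above the maximum so the sweep is
anchored at the all-negative end; predicted-positive means
score >= threshold. The confusion-matrix universe is the ranked
interval set itself (a true negative is an interval below threshold
and absent from the standard), ROC is TPR versus FPR, PR is precision
versus recall, and both areas use the trapezoid rule. With tied,
uninformative scores the ROC collapses to the two anchor points and
the area is 0.5 by construction. Degenerate inputs — an empty
standard, or a universe with no negatives — yield a curve flagged
`degenerate` with `NA` area rather than a division by zero; precision
at the empty sentinel threshold is reported as 1 by convention.

## The synthetic-data generator

`simulate_fragments()` draws fragment midpoints from a Poisson
process: uniform background at `background_rate` fragments/kb plus,
inside each ground-truth region, extra intensity at
`(fold - 1) * background_rate` per kb. Broad regions use uniform extra
density; narrow regions use a triangular density peaked at the region
center, so that center-resolution behavior of the caller can be
examined; mixed regions superpose the two in equal parts. Fragment
lengths are normal (mean 200, sd 50 bp) truncated to [10, 700] bp,
mirroring the usual paired-end insert bounds. The control channel is
an independent background process (default expected depth: half the
sample's) plus `control_leak = 0.02` of each region's enriched
intensity, emulating faint IgG signal rather than an identically-zero
control. When `depth` is given, all intensities are rescaled so the
expected library size equals it; in the degenerate zero-background
case the depth is spread over regions proportional to `fold * width`.
Everything is deterministic per seed, and the caller's RNG state is
left untouched.

The generator emulates the features the caller's model cares about —
sparse background, localized and domain-scale enrichment, a weak
correlated control — and deliberately omits sequence content, GC and
mappability bias, PCR duplicates, chromatin contact artifacts and
irregular fragment-size mixtures. Passing the validation studies below
therefore demonstrates correctness of the algorithm under its own
model assumptions, not performance on any particular real dataset.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` re-run four studies, sized
so the full suite completes in well under a minute per study:

- **Narrow recovery** — a 2 x 5 Mb genome with 20 narrow truth peaks
  (600–1000 bp) at fold 16 over a 2 fragments/kb background, total
  depth 1e5, ten independent simulations; the caller at default
  parameters is required to reach mean recall and precision >= 0.9 at
  50% reciprocal coverage. Observed values are 1.0.
- **Broad integrity** — a 1 Mb genome with one 20-kb domain at fold 8
  over a 1 fragment/kb background (domain-scale marks sit on very
  sparse background), called with `broad = TRUE, mdist = 3000`; at
  least 9 of 10 seeds must yield exactly one peak covering >= 95% of
  the domain.
- **Oracle equivalence** — binomial tails against brute-force
  summation (every x for n <= 50 at four success rates), BH against an
  independent step-up implementation (1000 random vectors), gap-merge
  against graph connected components (500 random instances), and the
  control-scaling formula on a hand grid covering every branch.
- **Benchmark machinery** — hand-enumerated consensus blocks; a
  perfectly separating ranking giving AUROC exactly 1; the tied
  two-point diagonal giving area 0.5; and, in the acceptance script, a
  two-replicate simulated study in which strong sites (fold 16) belong
  to the standard and weak sites (fold 6) do not.

```{r example, eval = FALSE}
sizes <- tibble::tibble(chrom = "chr1", size = 1000000L)
cfg <- sim_config(sizes,
  truth = tibble::tibble(
    chrom = "chr1", start = 400000, end = 420000,
    shape = "broad", fold = 8
  ),
  background_rate = 1
)
sim <- simulate_fragments(cfg, seed = 1)
fit <- call_peaks(sim$sample, sizes,
  control = sim$control, broad = TRUE, mdist = 3000
)
autoplot(fit) # or: plot_simulation(sim, fit = fit)
```

## Known limitations

- The null is global: a single (n, p) for the whole genome. Local
  background variation (copy-number changes, accessibility hotspots)
  is only partially absorbed by control scaling; callers with dynamic
  local backgrounds may behave differently there.
- "Reads" versus "fragments": the package counts each properly-paired
  fragment once, spanning both mates. A convention that counted read
  ends instead would double `n` and change bin counts; the fragment
  interpretation matches the pileup quantity the model describes, but
  is a divergence risk against tools that count ends.
- BAM fragment reconstruction requires proper pairs; single-end data
  must be supplied as pre-extracted intervals.
- The benchmark universe is the ranked consensus set, so reported
  specificity depends on how many consensus intervals fall outside the
  standard; it is not a genome-wide FPR.
- Replicate-aware joint calling, spike-in normalization and duplicate
  removal are out of scope; perform them upstream if needed.
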