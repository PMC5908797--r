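---
title: "Modelling stem-loop RNA recognition from in vitro selection data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stem-loop RNA recognition from in vitro selection data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrescan)
library(dplyr)
```

## The problem

Most RNA-binding proteins recognize short single-stranded sequence motifs.
A smaller class — exemplified by the TRIM-NHL protein LIN41/TRIM71 — instead
recognizes an RNA *shape*: a small hairpin ("stem-loop") with exactly three
nucleotides in the loop, read out mainly through the loop bases (positions
I, II, III) and the base pair that closes the loop (stem position 1, the
−1/+1 pair). `lrescan` implements the computational pipeline by which such a
specificity can be discovered and modelled from RNAcompete-style in vitro
selection data, in which an RBP is incubated with a designed pool of
30–41-nt RNA oligos and per-oligo binding is read off a two-channel array:

1. **Preference profiling** — does the protein prefer *sequence* or
   *structure*? K-mer enrichment in the bound fraction is computed twice,
   once over the RNA sequences (7-mers) and once over the dot-bracket
   strings of the folded pool (11-mers), and each table is summarized by
   the mean Z-score of its top ten k-mers.
2. **Tri-loop evidence** — structure 11-mer enrichment against pool
   occurrence, classified by hairpin loop size.
3. **The LRE model** — a 2688-pattern lookup table scoring every
   combination of closing pair (6) × loop triplet (64) × binned −1/+1
   pairing probability (7), from which binding patterns are selected and
   graded.
4. **Transcriptome scanning** — predicted sites with region (5′UTR / CDS /
   3′UTR) and strength (minimal / weak / medium / strong) assignments, and
   per-transcript site-count features.
5. **RIP regression** — per-gene immunoprecipitation enrichment regressed
   on the site features, with coefficient standard errors.
6. **Binding isotherms** — the ligand-depletion (quadratic) fluorescence
   polarization model and its least-squares fit.

Every input the pipeline consumes can be generated synthetically by seeded
generators, so the full analysis is exercised end to end without external
data.

## The folding engine

All structure quantities derive from a pluggable folding contract:
minimum-free-energy (MFE) dot-bracket structures and McCaskill-style
partition-function base-pair probabilities.

The builtin engine (the default, used by all tests) is a nearest-neighbor
dynamic program with a simplified parameter set: a Watson–Crick + GU
stacking table, hairpin/bulge/interior-loop initiation penalties with a
Jacobson–Stockmayer size extrapolation, a linear multiloop model
(a = 3.4, b = 0.4, c = 0 kcal/mol), an AU/GU hairpin-closure penalty, a
minimum hairpin loop of 3 nt, and interior loops capped at 30 unpaired
bases. It is not intended to reproduce any published engine's free energies
— tests assert structure topology and probability invariants, never
energies. Where ViennaRNA is installed, `engine = "vienna"` delegates to
`RNAfold`, and the test suite uses it as an independent cross-check on
designed hairpin fixtures: for perfect ≥5-bp stems in an unstructured
background both engines must produce the same pair set.

Pair probability matrices satisfy, by construction: symmetry, entries in
[0, 1], per-base sums ≤ 1, zeros for non-canonical pairs and for loops
shorter than 3. The **distance-4 profile** `v[i] = p[i, i+4]` is the
probability that base *i* is the 5′ half of a tri-loop's closing pair; it
is the structural feature the whole model is built on.

Long transcripts are folded in sliding windows (`window = 70`, maximum pair
span = window, step 1 by default), averaging `p[i, i+4]` over all windows
containing the pair. The windowed-folding window and span are package
defaults, configurable; sequences shorter than the window reduce exactly to
the global computation.

## The preference metric

The bound fraction is the top 2% of oligos by binding score
(`ceiling(n * 0.02)` members; ties broken lexicographically by oligo id so
the result is deterministic). For each k-mer,

```
enrichment = log2(fg + 8) − log2(all × 0.02 + 8)
```

with `fg` the bound-fraction count and `all` the whole-pool count (scaled
to a size-matched background). The pseudo-count of 8 suppresses spurious
enrichment at low counts. Enrichments are standardized to Z-scores using
the sample standard deviation (n − 1; at these table sizes the choice of
n vs n − 1 is immaterial, but the tests are exact so the convention is
fixed).

One design decision deserves emphasis: the k-mer **universe** over which
the Z-transform runs. The dot-bracket window length 11 exists to make the
number of structure combinations comparable to the 16,384 sequence 7-mers.
Restricting the structure universe to windows observed in the pool would
make it shrink with pool size (about 2,100 at a 10,000-oligo pool), which
systematically depresses structure Z-scores relative to sequence Z-scores:
the enriched windows then inflate their own table's standard deviation, so
the top-10 Z is capped near `sqrt(universe / enriched windows)` regardless
of signal strength. `preference_profile()` therefore standardizes structure
enrichments over all 16,907 *embeddable* 11-mers (those containing none of
`()`, `(.)`, `(..)` — windows that can occur inside a valid structure) and
sequence enrichments over all 16,384 7-mers, restoring the intended
comparability at any pool size. `enrichment_vs_occurrence()` keeps the
observed-only table, since it plots occurrence; its enrichment values are
identical either way.

## The stem-loop (LRE) model

Patterns combine a closing pair from {AU, UA, GC, CG, GU, UG}, a loop
triplet, and a pairing bin: `log2(p + 1e-4)` placed into seven equal-width
bins spanning `[log2(1e-4), 0]`. The bin edges are a package decision (only
"seven bins, log2 scale" is inherent to the model); this choice spans the
pseudo-count floor (p = 0 → bin 1) to certainty (p = 1 → bin 7) and is
monotone in p. Note bin 7 covers p ≳ 0.27 — the top seventh of the log2
range is wide on the probability scale.

Scores are mean binding enrichments of all oligos containing a pattern,
with each oligo counted once per pattern however often the pattern recurs
in it, after **clipping**: enrichments strictly inside (−2, 2) are set to
zero (boundary values kept — a literal reading of "between −2 and 2";
boundary floats are vanishingly rare). Clipping exists because the pool is
dominated by small enrichments, so any pool-wide sequence bias (the
AAA/CCC artifact seen on real arrays) would otherwise dominate the
per-pattern means; discarding the small values suppresses the bias while
keeping the extent of strong binding. A property test verifies the
mechanism: adding +0.5 to every enrichment of a null pool changes no
recovered score. Patterns supported by fewer than 20 oligos get a missing
score rather than a noisy one.

Pattern selection mirrors the discovered specificity: U–A closing pairs
with bin ≥ 4 and score ≥ 0.1; C–G with bin 7 and score ≥ 0.1; all other
pairs contribute nothing. Strengths use twofold thresholds
0.225 / 0.45 / 0.9 / 1.8 with left-closed intervals (a score of exactly 1.8
is "strong"), and "minimal" serves downstream as a close-to-no-binding
control.

When recovery of planted weights is evaluated (see the generators below),
the comparison runs over supported U–A patterns at bin 7, where planted
perfect elements concentrate; patterns at low bins are populated by chance
occurrences whose enrichment is independent of the planted weight, so
including them only measures dilution, not recovery.

## Scanning and regression

Transcripts are folded as full spliced sequences (structure does not
respect annotation boundaries) and sites are assigned to 5′UTR / CDS /
3′UTR by the transcript coordinate of loop position II — the loop is the
recognized element, so its center decides boundary cases. Sites below the
lowest strength threshold are not emitted. Coordinates are 1-based
inclusive internally; BED output is 0-based half-open covering stem
positions −1 through +1 (5 nt), with score `1000 × min(score/1.8, 1)`.

RIP expression is transformed `y = log2(x + 8)`, quantile-normalized across
samples (via limma's rank-mean transform — the same transform as
preprocessCore's `normalize.quantiles`), replicates averaged after
normalization, enrichment = mean(IP) − mean(input), and non-expressed genes
(log2 input mean < 5) removed before comparison. The regression is ordinary
least squares with an intercept on the 12 raw count predictors
(region × strength); "minimal" columns enter as predictors and act as
controls — the model reports their coefficients rather than excluding them,
which keeps the design full and the control interpretable. Aliased columns
are dropped and reported. `model_correlation()` is the Pearson correlation
of observed and fitted enrichment.

## The binding isotherm

Fluorescence polarization titrations are fitted to the ligand-depletion
(quadratic) isotherm
`Y = B + A(K + L + X − sqrt((K + L + X)² − 4LX))/(2L)` with the labeled RNA
concentration L fixed by the assay (0.1 µM default; K and X in µM). The
implementation evaluates the algebraically identical form
`B + 2AX/(S + sqrt(S² − 4LX))`, which avoids catastrophic cancellation for
X ≫ K + L. Replicates are averaged per concentration before fitting
(mean-fit). Initialization is B = min(Y), A = max(Y) − min(Y), K = X at
half amplitude, with deterministic K-scaled restarts (×1, ×½, ×2, ×¼, ×4);
the best converged fit by residual sum of squares wins, so the procedure is
reproducible without a seed. Flat titrations return A = 0 with K flagged
unidentifiable instead of a spurious estimate.

## What the synthetic generators emulate

All generators are pure functions of (config, seed) — one `withr`
seeded scope per call, no global state — and their outputs round-trip
through the package's own FASTA/GFF3/TSV readers.

**Oligo pools.** 30–41-nt oligos, uniform lengths. A configurable fraction
(default 0.05 — in a random-sequence pool only a few percent of oligos
present any given structural element, and the small fraction keeps the
bound fraction element-dominated while the pool background stays realistic)
carries a planted element. For the structure binder this is a designed
tri-loop stem-loop: the closing pair and loop come from the pattern table;
the stem *grows outward from the loop* — three perfect Watson–Crick pairs
adjacent to the closing pair (keeping the −1/+1 pairing probability high),
then 1–3 further pairs each either stacked directly or preceded by a small
bulge (1–3 nt) or internal loop, GC-biased so the designed fold dominates
the thermodynamic ensemble, wrapped in a non-pairable A/C flank so the
surrounding sequence cannot coaxially extend the helix. The growth walk
produces a continuum of stem geometries rather than a fixed menu: real
bound pools contain stem-loops of every geometry, and a generator with only
a handful of element shapes leaves each shape's stem fingerprint common
enough to contaminate window-level enrichment statistics. For the sequence
binder the element is the 6-mer 5′-UUGUUG-3′. Binding scores are the
planted effect (pattern weight, or a fixed per-motif effect for any oligo
containing the motif) plus Gaussian noise; the default weight table gives
U-A-closed triplets with a purine at position III a strong effect (3 log2
units) and others a residual 0.5.

**Two-channel arrays.** Input intensities are lognormal (log2 mean 10,
sd 1.5); pulldown = input × 2^score with multiplicative log2-scale noise;
a configurable artifact fraction becomes low-efficiency probes whose input
is forced below the median-6 (log2) reliability cutoff and whose pulldown
is uncorrelated with binding. The array literature gives no noise model for
this assay; lognormal multiplicative noise is an assumption, stated and
configurable. Intensities are written in linear scale, as raw exports are.

**Transcriptomes.** Transcripts segmented 5′UTR → CDS → 3′UTR with planted
elements built on perfect 6-bp GC-rich stems, in a background drawn from
{A, C} — an alphabet admitting no canonical pair — so the planted hairpin
is the only stable fold and any reasonable engine pairs its −1/+1 flanks.
This background is deliberately unrealistic (no competing structure, no G/U
content); it isolates scanner correctness from folding-engine differences.

**RIP.** Simulated directly at the gene-enrichment level:
intercept + features·coefficients + Gaussian noise. Sequencing reads,
library-size effects and alignment are out of scope.

## What passing tests do and do not show

The suite demonstrates that the pipeline's statistics behave as the
analysis assumes: structure binders separate from sequence binders on the
preference plane; tri-loop windows dominate the top of the structure
enrichment table; planted pattern weights are recovered (Spearman ρ ≈ 0.87
over supported bin-7 U–A patterns at 20,000 oligos, noise 0.5); planted
transcript sites are recovered at 100% recall with correct region and
strength; regression coefficients land within 3 SE in ≥ 19/20 seeded runs.

Two behaviors of the desk-scale simulation differ quantitatively from what
a 241,000-oligo assay shows, and are worth understanding:

* Among the top-30 enriched structure 11-mers, typically 20–25 (not all
  30) contain a complete tri-loop; the rest are truncated-helix windows of
  the planted elements. At small pool sizes each specific stem-fingerprint
  window retains enough share of the bound fraction to rank; an organic
  pool's geometry continuum dilutes them further.
* The mean enrichment of 4/5/6-loop 11-mers is slightly negative
  (≈ −0.2) rather than 0. A null binder gives ≈ +0.02, so this is real
  conditioning: an oligo bound through a ~15–20-nt element within 30–41 nt
  has most of its 11-nt windows overlapping the element, structurally
  depleting every other loop class in the bound fraction (bound oligos
  carry ~6× fewer 4–6-nt loops than the pool average).

Neither affects the model-building path, which works at the oligo level,
not the window level.

## Problem sizes and numerical conventions

The shipped analyses use pools of 10,000 oligos for preference profiling,
20,000 for model recovery, 8 synthetic transcripts (80 + 200 + 120 nt) for
scanner validation, 2,000 genes × 20 seeds for regression recovery, and
12-concentration titrations in triplicate for isotherm fits — sizes chosen
so a complete run finishes on a laptop in a few minutes while every
statistic is comfortably away from its small-sample regime (except where
the point is to study that regime, as above).

Conventions fixed so that tests can be exact: medians of even counts are
the mean of the central pair; the low-median filter removes strictly below
threshold; bound fractions use the ceiling and id-lexicographic
tie-breaks; Z-scores use n − 1; clipping keeps boundary values; strength
intervals are left-closed; loess enrichment uses degree 1, span 0.3, on
log2 scale (the assay literature states no parameters; these are robust
defaults for ~10⁴–10⁵ points and configurable).

## Known limitations

* The builtin energy parameters are simplified; absolute pairing
  probabilities differ from published engines (topology-level agreement is
  tested, energies are not comparable).
* Windowed folding subsamples windows when `step > 1`; the default step of
  1 matches the every-window average of standard local-folding tools.
* The transcriptome generator's A/C background makes scanner recall a
  correctness check, not a sensitivity estimate on real transcriptomes.
* Real-array spatial effects, dye bias beyond a scalar, and read-level RIP
  simulation are out of scope.
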