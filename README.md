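# lrescan

Model the RNA-binding specificity of stem-loop binding proteins from
RNAcompete-style in vitro selection data.

Most RNA-binding proteins recognize short single-stranded sequence motifs;
LIN41/TRIM71-family proteins instead recognize a *shape*: a small hairpin
with exactly three loop nucleotides (a tri-loop stem-loop), read out through
the loop bases (positions I, II, III) and the loop-closing base pair (stem
position 1, the −1/+1 pair). `lrescan` implements the complete analysis by
which such a specificity is discovered and modelled from pools of 30–41-nt
RNA oligos with per-oligo binding readouts:

* **Folding backend** — minimum-free-energy dot-bracket structures and
  McCaskill base-pair probabilities from a builtin nearest-neighbor engine
  (ViennaRNA optional via `engine = "vienna"`); sliding-window local
  folding for transcript-length RNA. The key structural feature is the
  distance-4 pairing profile `v[i] = p(i, i+4)`, the probability that base
  *i* closes a tri-loop.
* **Preference profiling** — enrichment of sequence 7-mers versus structure
  (dot-bracket) 11-mers in the top 2% bound fraction,
  `log2(fg + 8) − log2(all/50 + 8)`, summarized per experiment as the mean
  Z of the top 10 k-mers on each side.
* **Stem-loop binding model** — 2688 patterns (6 closing pairs × 64 loop
  triplets × 7 pairing-probability bins on the log2 scale), each scored as
  the mean clipped binding enrichment (values in (−2, 2) set to 0) of the
  oligos containing it, with a 20-oligo support requirement; selection
  rules (U–A: bin ≥ 4, score ≥ 0.1; C–G: bin 7, score ≥ 0.1) and strength
  grades at twofold thresholds 0.225/0.45/0.9/1.8.
* **Transcriptome scanning** — predicted sites over 5′UTR/CDS/3′UTR with
  strength grades, BED/TSV export, and per-transcript (region × strength)
  feature matrices.
* **Array preprocessing** — compendium median input reference, low-median
  probe filter (log2 < 6), artifact filters, quantile normalization, and
  loess-residual log2 binding enrichments.
* **RIP regression** — per-gene IP enrichment (`log2(x+8)`, quantile
  normalization, input filter) regressed on site features by OLS, with
  tidy/glance/autoplot methods.
* **Binding isotherms** — the ligand-depletion (quadratic) fluorescence
  polarization model `Y = B + A(K+L+X − √((K+L+X)² − 4LX))/(2L)` and a
  multi-start nonlinear least-squares fit for the dissociation constant K.
* **Synthetic data** — seeded generators for every input: oligo pools with
  planted stem-loop elements or a planted ssRNA motif (5′-UUGUUG-3′),
  two-channel intensities with low-efficiency probe artifacts,
  transcriptomes with planted sites of known strength, and linear RIP
  responses.

## Worked example

```r
library(lrescan)
library(dplyr)

# a 13-mer that folds into the recognized element: a tri-loop closed by U-A
fold_mfe("GGAGUCCAACUCC")
#> [1] "(((((...)))))"

# simulate a structure-binding protein on a 10,000-oligo pool and ask:
# does it prefer sequence or structure?
cfg    <- generator_config(seed = 101, n_oligos = 10000, binder_kind = "structure")
pool   <- generate_oligo_pool(cfg)
scores <- simulate_binding_scores(pool, cfg)
preference_profile(pool, scores)
#> # A tibble: 1 × 2
#>   seq_top10_z struct_top10_z
#>         <dbl>          <dbl>
#> 1        6.32           18.0
```

A structure binder produces a far higher top-10 Z over dot-bracket 11-mers
(18.0) than over sequence 7-mers (6.3): its binding is explained by what
the RNA folds into, not what it reads. Fitting the 2688-pattern model to
the same pool recovers the planted specificity:

```r
model <- fit_lre_model(pool, rename(scores, enrichment = score))
model
#> Stem-loop binding model: 2688 patterns (6 pairs x 64 triplets x 7 bins)
#>   scored: 1272; missing (support < 20): 1416
#>   top patterns:
#>     UA:AAA:7     score 1.357 (support 20)
#>     UA:GUA:3     score 0.411 (support 30)
#>     ...
```

The top pattern is a U–A-closed tri-loop at the highest pairing bin —
binding requires both the right bases and the formed hairpin. Predicted
sites on transcripts come from the same patterns via windowed folding:

```r
sites <- tidyr::crossing(transcript = 1:4, region = c("CDS", "3UTR")) %>%
  mutate(pattern = "UA:CAA")
tx <- generate_transcriptome(4, sites = sites, seed = 7)
patterns <- enumerate_patterns() %>%
  filter(pair == "UA", bin >= 4, triplet == "CAA") %>%
  mutate(score = 1.0)
scan_transcriptome(tx, patterns = patterns)
#> # A tibble: 8 × 9
#>   transcript_id   pos region pair  triplet   bin pattern  score strength
#> 1 tx_0001         371 CDS    UA    CAA         7 UA:CAA:7     1 medium
#> 2 tx_0001         542 3UTR   UA    CAA         7 UA:CAA:7     1 medium
#> ...
```

All 8 planted sites are recovered with the correct region and a "medium"
strength (score 1.0 falls in [0.9, 1.8)). Finally, a binding titration:

```r
X <- c(0, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 1.3, 2, 4, 8, 16)   # protein, uM
fit <- fit_isotherm(tibble(concentration = X,
                           polarization = fp_isotherm(X, 50, 120, 1.3, 0.1)))
fit
#> Binding isotherm fit (L = 0.1 uM, ligand-depletion form)
#>   term  estimate std.error
#> 1 B         50    7.82e-15
#> 2 A        120    1.52e-14
#> 3 K          1.3  6.17e-16
```

The dissociation constant K = 1.3 µM is recovered exactly from a noiseless
curve (and to within a few percent from triplicate measurements with 2 mP
noise).

See the vignette (`vignettes/stemloop-binding-model.Rmd`) for the model's
assumptions, parameter meanings, and the design of the synthetic
generators.

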