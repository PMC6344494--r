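# strataDiv

Stage-binned diversity analysis for fossil occurrence data: stratigraphic
ranges, turnover rates, coverage-standardized (shareholder quorum) richness,
and sampling-bias diagnostics, with a synthetic fossil-record generator that
makes every step testable against a known truth.

## The problem

Global fossil occurrence compilations — one row per reported occurrence of a
taxon in one sample of one literature reference — are the raw material for
deep-time diversity curves. Raw per-stage richness from such data confounds
biology with sampling: stages with more published references yield more taxa,
short stages preserve fewer fossils, and gaps inside a taxon's range
("Lazarus" intervals) smear real or apparent extinctions backwards in time
(the Signor–Lipps effect). The package targets this problem for ordered
chronostratigraphic stage scales, with defaults for the Wuchiapingian to
Ladinian (late Permian to Middle Triassic) interval — the setting of the
debate over whether land plants suffered an end-Permian mass extinction —
but every component accepts an arbitrary stage scale.

## What it computes

From a validated, filtered occurrence table, taxa are collapsed to
stratigraphic ranges and every taxon present in a bin is classified into the
four basic types: single-interval taxa (`n_single`), bottom-boundary
crossers going extinct (`n_bot`), top-boundary crossers originating
(`n_top`), and range-through taxa (`n_thru`). From these:

- **Sampled-in-bin (SIB) diversity**: taxa actually reported from the bin.
- **Total (range-through) diversity**: `n_single + n_bot + n_top + n_thru`,
  inferring presence between first and last occurrence;
  `Lazarus count = total − SIB`.
- **Normalized diversity** (mean standing diversity):
  `n_thru + ½(n_bot + n_top + w·n_single)`, with `w = 1` by default.
- **Origination / extinction / turnover** counts (boundary crossers only,
  single-bin taxa excluded) and per-Myr rates (counts / stage duration).
- **Good's coverage** `u = 1 − n₁/N`, where `n₁` is the number of taxa with
  a single (reference-merged) occurrence and `N` the total occurrences.
- **Shareholder quorum subsampling (SQS) by reference**: references are
  drawn without replacement, up to 5 samples per reference, a taxon's
  repeats within one reference merged; richness is recorded when the running
  coverage reaches the quorum (default 0.4), over 500 trials, summarized as
  the median and 95% interval — richness compared at equal coverage rather
  than equal effort.
- **Spearman rank diagnostics** (`r_s`, two-sided *p*; strong if
  `|r_s| > 0.6`, significant if `p < 0.05`) between per-stage entry counts
  and diversity series, plus mean-centre/1σ scaling for overlaying trends.

The synthetic generator simulates a discrete-time birth–death history with
lognormal abundances and a literature-like preservation process
(references → samples → abundance-weighted occurrence draws), so recovery of
a known truth can be measured; three presets encode canonical bias
situations (`uniform-richness-uneven-sampling`, `sudden-extinction`,
`induan-gap`).

## Worked example

A record with constant true richness (60 genera) but a five-fold sampling
gradient across bins:

```r
library(strataDiv)
sim <- simulateScenario("uniform-richness-uneven-sampling", seed = 42)
rec <- applySelectionFilters(sim$records, rankLevel = "genus")
tab <- computeStageTable(rec, buildTaxonRanges(rec, "genus"))
data.frame(stage = tab$stage, sib = tab$sib, entries = tab$n_entries,
           u = round(tab$coverage_u, 2))
#>           stage sib entries    u
#> 1 Wuchiapingian  25      40 0.59
#> 2 Changhsingian  31      71 0.81
#> 3        Induan  35     102 0.88
#> 4     Olenekian  42     136 0.86
#> 5       Anisian  45     166 0.91
#> 6      Ladinian  51     199 0.93
```

Raw SIB richness doubles from 25 to 51 purely because sampling effort (the
`entries` column) increases — the truth is flat at 60. Coverage-standardized
richness is not fooled:

```r
sqs(rec, "genus", sqsConfig(quorum = 0.4, trials = 100, seed = 42))
#>           stage quorum median_richness ci_lower ci_upper n_recorded n_failed_trials
#> 1 Wuchiapingian    0.4              17      6.0     25.0        119               0
#> 2 Changhsingian    0.4              16      6.6     24.8        105               0
#> 3        Induan    0.4              15      6.0     23.0        112               0
#> 4     Olenekian    0.4              16      6.0     26.1        119               0
#> 5       Anisian    0.4              17      8.0     26.3        109               0
#> 6      Ladinian    0.4              18      7.0     28.0        122               0
```

The medians (15–18 genera at coverage 0.4) are flat across the gradient,
with overlapping 95% intervals. The effort–richness confounding itself is
flagged by the diagnostics:

```r
spearmanTrend(as.numeric(entriesPerStage(rec)), tab$sib)
#> Spearman r_s = 1.000 (n = 6), p = 0.002778, strong, significant
```

The `induan-gap` preset (constant richness, one severely under-sampled
short bin) reproduces the classic artefact pattern — the gap bin shows a
collapse in SIB richness and the maximum Lazarus proportion while total
diversity is carried across it by range-through inference, and spurious
extinctions appear in the bin *before* the gap:

```r
sim <- simulateScenario("induan-gap", seed = 42)
rec <- applySelectionFilters(sim$records, rankLevel = "genus")
tab <- computeStageTable(rec, buildTaxonRanges(rec, "genus"))
tab[, c("stage", "sib", "total", "lazarus_proportion", "extinctions")]
#>           stage sib total lazarus_proportion extinctions
#> 1 Wuchiapingian  36    47              0.234           1
#> 2 Changhsingian  32    57              0.439           2
#> 3        Induan   4    43              0.907           1
#> 4     Olenekian  37    64              0.422           6
#> 5       Anisian  38    59              0.356          11
#> 6      Ladinian  38    53              0.283          17
```

(True extinction in this history is zero everywhere; the counts above are
pure sampling artefacts.)

A full pipeline run — read, normalize with synonymy/family tables, filter,
all indices, SQS, correlations, CSV export with a manifest — is one call:

```r
cfg <- analysisConfig("occurrences.csv", synonymy = "synonyms.csv",
                      ranks = c("genus", "species"), seed = 1)
bundle <- runAnalysis(cfg)
exportBundle(bundle, "results/")
```

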