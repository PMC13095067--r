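# CardioPheno

Quantitative phenotyping of laminopathy cardiomyocyte models in R.

Mutations in *LMNA* (A-type lamins) cause dilated cardiomyopathy, and
patient-derived hiPSC-cardiomyocytes show a characteristic triad of
phenotypes: repositioned chromosome territories inside the nucleus,
disturbed contraction and calcium handling, and chromosome-biased
differential gene expression. CardioPheno implements the quantitative
analyses used to measure all three, together with seeded synthetic-data
generators that carry exact ground truth, so every stage of the analysis is
testable end to end without microscope or sequencing data.

It is aimed at cell-biology and stem-cell labs who have nuclear masks and
probe images (chromosome painting / FISH), video-edge contraction or
ratiometric calcium recordings, and DESeq2-style differential-expression
tables — and want reproducible, scriptable versions of the usual
point-and-click quantifications.

## What it computes

**Radial territory profiling.** Every binarized nuclear mask is partitioned
into N = 10 concentric bins on the normalized Euclidean
distance-to-boundary transform r = 1 − D/D_max (bin 1 deepest, bin 10 at
the boundary; bins 1–5 are the nuclear center, 6–10 the periphery), either
as equal-width rings or as equal-area deciles of r. Mean probe fluorescence
per bin is min–max normalized with extrema pooled across both groups per
probe,

  v_norm = (v − v_min) / (v_max − v_min),

yielding a group × bin heatmap matrix in [0, 1]. Groups are compared by
two-way ANOVA (group × bin, with interaction) plus per-bin contrasts under
Šídák adjustment. A peripherality index, Σ(bins 6–10) / Σ(bins 1–10),
summarizes radial position per nucleus.

**Nuclear morphometrics.** Area, perimeter (Kulpa-corrected chain code),
circularity 4πA/P², solidity A/A_hull, and maximal Feret diameter.

**Contraction and calcium trace metrics.** Prominence-based beat
segmentation with threshold-based rise onset; contraction time
(onset → peak), relaxation time (peak → subsequent displacement minimum);
per-trace means and the beat-to-beat SD as the heterogeneity index. For
ratiometric calcium traces: diastolic ratio and diastolic time, the
interval from the transient peak to the interpolated return to 90 % of
baseline. Force–calcium curves measured under stepwise external calcium
(0.3 → 3.0 mmol/L) are fitted with the Hill model
F = F_max·c^h / (EC50^h + c^h) by bounded least squares.

**DEGs per chromosome.** Differential-expression tables are filtered at
padj < 0.05 and |log2FC| > 0.5, tallied per chromosome (DEG percentage of
the chromosome's genes, share of all DEGs, ECM-flagged subset), and tested
for enrichment against the genome-wide DEG rate with exact binomial tests
and Benjamini–Hochberg adjustment.

**Synthetic data with ground truth.** Elliptical nuclei with territory
blobs placed at a controlled normalized radius (Poisson + Gaussian camera
noise, each switchable to zero), paced beat traces (63 frames/s, 25 s, 1 Hz
by default) with known onset/peak/amplitude per beat, Hill dose–response
curves, and DE tables with per-chromosome enrichment multipliers.

## Worked example

```r
library(CardioPheno)

ctrl <- simulateTerritoryCohort(20, sceneParams(territoryRadialMu = 0.5),
                                seed = 1, groupLabel = "corrected")
mut  <- simulateTerritoryCohort(20, sceneParams(territoryRadialMu = 0.7),
                                seed = 2, groupLabel = "mutant")
pm <- normalizeProfiles(c(ctrl$profiles, mut$profiles))
pm
#> ProfileMatrix probe probe, scope global, 40 nuclei, 2 groups
#>            bin1  bin2  bin3  bin4  bin5  bin6  bin7  bin8  bin9 bin10
#> corrected 0.071 0.249 0.571 0.763 0.784 0.732 0.593 0.370 0.147 0.063
#> mutant    0.046 0.050 0.082 0.212 0.471 0.615 0.633 0.589 0.482 0.324
```

The mutant group's territory signal is shifted toward the peripheral bins.
The two-way ANOVA makes that assertable:

```r
anovaTable(compareRadialDistributions(pm))
#>        term df         F             p
#> 1     group  1  49.59464  8.911732e-12
#> 2       bin  9 131.46353 6.377985e-111
#> 3 group:bin  9  66.77258  8.586094e-73
```

The `group:bin` interaction is the radial-repositioning signal; per-bin
Šídák-adjusted p-values are in `perBinStats()`. Contraction and calcium:

```r
sim <- simulateBeatTrace(traceParams(amplitudeCv = 0.2, seed = 4))
summarizeTrace(detectBeats(sim$trace))
#>   n_beats amplitude_mean amplitude_sd contraction_time_mean ...
#> 1      25      0.9758058    0.1951414             0.1866667 ...

d <- simulateCalciumResponse(ec50 = 1.1, hill = 2, fmax = 1,
                             noiseSd = 0.03, seed = 9)
fitCalciumResponse(d$concentration, d$force)
#> Hill fit: EC50 1.119 mmol/L, h 2.01, Fmax 1.017, RMS residual 0.0254
```

The amplitude SD (0.195 against a mean of 0.976) is the heterogeneity
index, recovering the simulated 20 % beat-to-beat variability; the EC50
comes back within 2 % of the simulated 1.1 mmol/L at 3 % noise.

The whole synthetic analysis also runs as one pipeline with a manifest and
markdown report:

```r
runPipeline(defaultRunConfig(seed = 1), "run1")
```

or from a shell via `inst/scripts/cardiopheno.R` (subcommands `run`,
`report`, `config`).

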