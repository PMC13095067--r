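---
title: "CardioPheno: models, parameters and design choices"
author: "CardioPheno authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CardioPheno: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CardioPheno)
```

CardioPheno quantifies three phenotypes of laminopathy cardiomyocyte
models: the radial position of painted chromosome territories in the
nucleus, contraction/calcium dynamics of paced cardiomyocytes, and
chromosome-level structure in differential gene expression. This vignette
explains each model, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the design decisions taken where the
underlying procedures are conventionally under-specified.

## Radial binning of nuclear masks

For a binarized nucleus, each foreground pixel gets the exact Euclidean
distance $D$ to the nearest background pixel (the image border counts as
background; background adjacency is 4-connected), rescaled to a
normalized radius

$$r = 1 - D / D_{\max} \in [0, 1),$$

so the deepest pixel has $r = 0$ and boundary pixels approach 1. Ten bins
are indexed center (1) to periphery (10), matching the convention that
bins 1–5 are the nuclear center and 6–10 the periphery.

Two bin geometries are provided because erosion-ring practice varies and
the underlying imaging protocols rarely state which was used:

* **equal_width** (default): $\mathrm{bin} = \min(\lfloor r N\rfloor + 1, N)$ —
  rings of equal normalized radial width, the closest analogue of
  iterative-erosion shells.
* **equal_area**: bin thresholds are the empirical $N$-quantiles of $r$
  over the foreground, so bins hold equal pixel counts up to *tie blocks*
  (pixels with identical $r$ — common on a discrete grid — always stay in
  one bin; the balance criterion is therefore "equal within the largest
  tie block", not exactly equal).

Both modes satisfy a strict partition invariant (per-bin pixel counts sum
to the mask area) and both are checked against an independent brute-force
implementation (direct nearest-background search, direct decile split) in
the test suite.

The distance transform itself is EBImage's exact Euclidean `distmap`;
padding the mask with a one-pixel background frame makes the image border
behave as background deterministically.

## Intensity profiles and normalization

Per nucleus, the profile is the mean probe intensity per bin. For the
heatmap matrix, per-bin means are min–max normalized with the minimum and
maximum pooled over *all profiles of both groups for one probe* (the
"global" scope): the pooled minimum maps to 0 and the pooled maximum to 1,
and the group rows are means of the normalized per-nucleus profiles.
This global pooling is the default because cross-image pooling of the
probe maximum is the stated practice for this assay; the wording of such
normalizations is ambiguous about whether extrema are per-bin or global,
so a "per_bin" scope is available as an option. When all pooled values are
equal, the normalization is degenerate; the matrix is set to zero and a
flag is raised (and surfaced by the pipeline report) rather than dividing
by zero.

Normalization is invariant under positive affine transforms of the raw
intensities ($v \mapsto av + b$, $a > 0$), which the tests verify
numerically — gain and offset of the camera therefore cannot change the
heatmap.

The **peripherality index**, $\sum_{k=6}^{10} v_k / \sum_{k=1}^{10} v_k$,
summarizes a profile in one number (0.5 = uniform, 1 = fully peripheral).
It is the quantity used to verify that the analysis recovers the
generator's ground-truth radial position.

## Group comparison

Normalized per-nucleus profiles are compared by two-way ANOVA with factors
group and bin (bin categorical, nucleus as replicate) including the
group:bin interaction — the interaction is the radial-repositioning
signal, since a pure group main effect is mostly removed by the min–max
normalization. Per-bin group differences use Welch t tests with Šídák
adjustment over the 10 bins ($p_{\mathrm{adj}} = 1 - (1-p)^{10}$); the
per-bin display convention (mean ± SEM with per-bin significance) follows
the field's figure style, which does not name its correction — Šídák is
the choice here and is recorded in the output.

The profiles of one nucleus across bins are not independent, so the ANOVA
is the descriptive omnibus it is in common practice rather than a
fully-specified mixed model; the simulation tests confirm that, under the
null, the Šídák-adjusted per-bin false-positive rate stays below
nominal (≤ 0.05, tested against a 0.07 ceiling over 200 replicates with
8 nuclei per group), and that a territory shift from $\mu_r = 0.4$ to
$0.7$ with 30 nuclei per group is detected via the interaction in
essentially every run (100 replicates).

## Nuclear shape descriptors

Area is the pixel count times the squared pixel size. The perimeter is a
chain-code length with Kulpa's corrected weights (0.9481 per axial step,
$0.9481\sqrt2$ per diagonal step) on the traced boundary — a raw chain
code overestimates smooth boundaries by several percent, which would push
the circularity $4\pi A/P^2$ of a disk visibly below 1; with the
correction a radius-50 disk scores ≈ 1.01. Solidity divides the mask area
by the pixel-counted filled convex hull, so it is exactly ≤ 1 and equals 1
for convex rasters. The maximal (Feret) diameter is the largest pairwise
distance between convex-hull corner points of the mask, which reproduces a
rectangle's diagonal exactly.

## Beat segmentation and contractile metrics

Traces are uniformly sampled displacement (or calcium-ratio) recordings
under electrical pacing; the defaults mirror the acquisition this package
targets: 63 frames/s, 25 s, 1 Hz pacing.

Peaks are local maxima filtered by topographic prominence
(`minProminence`, default 0.3 of the 5th–95th percentile excursion) with a
refractory interval (default half the pacing period). Per beat:

* **trough**: the last minimum before the peak — the sample adjacent to
  the upstroke;
* **baseline**: median of a short window (15 % of the median inter-beat
  interval, ≥ 3 samples) ending at the trough — a local, drift-robust
  estimate;
* **onset**: the last sample at or below baseline + `onsetFraction` × beat
  amplitude before the upstroke crosses that threshold. `onsetFraction`
  defaults to 0.10; the threshold-based rise onset of the original
  video-edge scripts is not published, so the value is declared,
  configurable, and echoed in the output;
* **end of relaxation**: the *first* minimum reached after the peak. The
  first-versus-last distinction matters: the pre-peak trough must sit next
  to the upstroke (for onset and baseline), while the relaxation endpoint
  must be the moment the displacement first bottoms out, not the end of
  the diastolic plateau.

Contraction time is (peak − onset)/framerate and relaxation time
(end − peak)/framerate, kept on the sample grid to match frame-indexed
definitions; only the calcium 90 %-return crossing below is interpolated.
All thresholds are fractional, so segmentation is invariant to positive
rescaling and additive offsets — verified property-style in the tests.

Per-trace summaries average each metric over beats, and the beat-to-beat
sample SD is the **heterogeneity index** (an irregularity proxy): zero for
identical beats, and recovering the generator's amplitude CV within 20 %
in simulation.

## Calcium metrics and EC50

For ratiometric traces, the diastolic ratio is the mean of the
per-transient baseline windows. Per transient, the diastolic time runs
from the ratio peak to the first crossing of
baseline + 0.10 × (peak − baseline) — i.e. 90 % of the way back to the
diastolic level — with linear interpolation between samples; an
exponential decay with time constant $\tau$ therefore gives
$\tau\ln 10$ analytically, which the tests require to within one frame
period. Transients that never return before the next onset are excluded
with a machine-readable warning.

Force–calcium curves over the stepwise 0.3–3.0 mmol/L protocol are fitted
with the Hill model $F = F_{\max} c^h / (EC_{50}^h + c^h)$ using bounded
Levenberg–Marquardt least squares (minpack.lm), with
$EC_{50} \in [0.1\,\min c,\ 10\,\max c]$ and $h \in (0, 8]$; a fitted
EC50 outside the measured range is flagged rather than silently trusted.
Noiseless curves on the 10-step grid are recovered to better than 1 %;
at 5 % of $F_{\max}$ Gaussian noise the median EC50 error stays below
10 % over 200 replicates.

## DEG chromosome summaries

DEGs are genes with adjusted p strictly below 0.05 and |log2FC| strictly
above 0.5 — strict inequalities are adopted since threshold statements of
this kind rarely specify the boundary, and both fold-change directions
count, as in the usual volcano-plot reading. Rows with missing statistics
are dropped and counted. Per chromosome the summary reports the DEG
percentage of that chromosome's genes (default reading) *and* the DEG
share of all DEGs, since bar charts of "DEGs per chromosome" admit both
normalizations. Enrichment per chromosome is an exact two-sided binomial
test of the chromosome's DEG count against the genome-wide rate,
BH-adjusted; a chromosome sitting exactly at the genome-wide rate yields
p = 1. Gene-to-chromosome mapping is taken from the input table — no
annotation database is consulted.

## Synthetic data: what it emulates, what it does not

The generators define the conditions under which the analysis is
validated:

* **Scenes** (`sceneParams()`): one elliptical nucleus per 80 × 80 field,
  semi-axes 30 × 22 px at 0.2 µm/px (a ≈ 12 × 9 µm nucleus — desk-scale
  rather than the ~0.066 µm/px of super-resolution acquisitions, a
  deliberate choice for speed since the analysis is resolution-invariant).
  The territory is a compact blob grown from a seed point placed at a
  target normalized radius along a random angle and clipped to the mask,
  occupying 8 % of the nuclear area by default; its ground-truth mean
  radius is computed from the pre-noise pixel set and is provably
  invariant to the noise parameters. The camera model is
  Poisson(photon signal, after a σ = 0.8 px optical blur) plus Gaussian
  read noise (SD 5) over a constant offset (100 counts), photon scale 200;
  acquisition noise for this assay is unpublished, so these defaults are
  chosen for testability, not camera realism, and both noise terms switch
  off exactly for noiseless tests. Not emulated: 3-D nuclei (the analysis
  is 2-D), chromatin texture, realistic PSFs, segmentation errors —
  passing tests therefore validate the *quantification*, not mask quality
  on real images.
* **Beat traces** (`traceParams()`): sums of per-beat pulses (linear rise
  0.2 s, exponential decay 0.15 s) at jittered 1 Hz pacing times, 63
  frames/s for 25 s, baseline plus Gaussian noise; per-beat onset, peak
  and amplitude are returned as ground truth in closed form. Overlapping
  beats (rise + 5 × decay beyond the period) are flagged, not rejected.
  Not emulated: drift, ectopic beats, motion artefacts.
* **DE tables** (`degSimParams()`): 1000 genes for each of chromosomes
  1–22 and X (a uniform simplification; real chromosomes differ several-
  fold in gene count, which only rescales per-chromosome power), baseline
  DEG probability 0.02 with per-chromosome multipliers, true-DEG
  |log2FC| ~ Normal(1.5, 0.4) with random sign and padj ~ Beta(1, 19),
  null padj ~ Uniform(0, 1) — closed forms that make filter recall
  computable exactly. ECM flags: 30 % of true DEGs, 2 % background.

A single integer seed feeds independent named RNG substreams per output
(mask perturbation, territory placement, noise, traces, calcium, DEG), so
identical seeds give bit-identical outputs and changing, say, the noise
level never moves the territory.

## Numerical choices and degenerate inputs

* Ties in equal-area binning stay together (thresholds are order
  statistics; assignment uses strict comparison against them).
* Empty masks, multi-component masks, shape mismatches, traces with
  non-uniform sampling, DEG tables with duplicate genes or out-of-range
  padj are rejected with specific errors.
* A constant trace yields zero beats (not an error); zero beats yield an
  explicit empty summary.
* All-equal forces yield a failed Hill fit with NA estimates, never a
  crash.
* Degenerate normalization returns zeros plus a flag.
* Sub-sample interpolation is used only for the calcium 90 %-return
  crossing; displacement timings stay on the sample grid.

## Pipeline

`runPipeline()` executes simulate → profile → beats → calcium → degs →
compare → report inside one run directory, with a JSON manifest recording
the configuration, seed, per-stage output files with MD5 digests, and
machine-readable warnings (degenerate normalization, excluded transients,
overlapping beats). Reruns with the same config are bit-identical except
for the manifest timestamp. The markdown report regenerates
idempotently and marks absent stages instead of failing. Problem sizes
used by the validation runs: 100 random masks (≤ 64 × 64) for the binning
oracle; 30 noiseless nuclei per point on the 0.1–0.9 radius grid; 200
null and 100 power replicates for the ANOVA; 200 replicates each for EC50
noise recovery and DEG-enrichment recovery; an 8-nuclei/3-trace/150-genes-
per-chromosome end-to-end run, twice, for determinism.

## Known limitations

* The ANOVA treats bins within a nucleus as independent replicates, as in
  common figure-legend practice; a mixed model with nucleus as a random
  effect would be the stricter alternative.
* Equal-width binning of strongly concave nuclei can place thin bins in
  lobes; the brute-force oracle covers random blobby masks, but extreme
  shapes (e.g. ring-shaped masks) are outside the generator's scope.
* EC50 fits on non-monotone data may converge to a boundary; the
  `ec50InRange` flag and residual should be inspected before comparing
  groups.
* The DEG module consumes a finished differential-expression table; it
  neither recomputes differential expression nor handles gene-level
  filtering upstream of it.
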