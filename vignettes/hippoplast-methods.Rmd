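---
title: "Models and conventions behind hippoplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind hippoplast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hippoplast pairs three analysis stages — spine morphometry, behavioral
scoring, and TPA proteomics — with seeded generators that plant the
ground truth those stages must recover. This vignette explains the
models, the parameters that matter, the numerical choices, and what the
synthetic validation does and does not establish about real data.

## Spine morphometry

### The shape model

A dendritic spine is summarized by two scalars: the curvilinear length
$L$ along its skeleton from the dendrite surface to the tip, and the
head width $W$, the largest diameter of the spine outside its basal
third. Their ratio $R = L/W$ is scale-free and orders spine shapes from
stubby and mushroom (compact, mature, $R < 2$) through thin and
long-thin to filopodia-like (elongated, immature, $R > 2$). Only the
$R = 2$ boundary between mature and immature compartments carries a
quantitative convention; the unit-wide class bins
(stubby $[0,1)$, mushroom $[1,2)$, thin $[2,3)$, long-thin $[3,4)$,
filopodia $[4,\infty)$) follow the qualitative ordering and are a
design choice of this package: they respect the compartment boundary
and divide each compartment evenly. Class labels are reported for
convenience; all statistics operate on the continuous ratio.

### The rendering model

`render_scene()` draws, in a 2-D plane (projected confocal imaging at
0.07 µm/pixel is the emulated regime; no z-stacks), a dendrite tube of
configurable radius along a polyline, plus spines: a neck tapering
linearly from the neck diameter at the base to the head diameter, and a
circular head whose far edge is the spine tip, so the planted length is
exactly the base-to-tip arc length. The binary structure at
`photon_scale` counts is blurred with an isotropic Gaussian PSF
(default $\sigma$ = 0.1 µm, a reasonable lateral width for a 1.4-NA
confocal at ~570 nm), then Poisson photon noise, a constant background
and Gaussian read noise are applied. Defaults
(`photon_scale = 500`, `background = 10`, `read_noise_sd = 2`) give a
peak SNR around 20, chosen for testability: the labeling density and
SNR of real DiI material are not standardized, so these are explicit,
adjustable assumptions rather than fidelity claims.

What the generator does *not* emulate: out-of-focus haze from
neighboring structures, spine occlusion and overlap, axial projection
foreshortening (a spine pointing out of the plane renders shorter in
projection; here all spines lie in the plane), dye granularity, and
detector fixed-pattern effects. Passing the recovery suites therefore
shows the measurement chain is unbiased on well-separated, in-plane
spines at moderate SNR — not that it handles crowded or out-of-plane
real material.

### Dendrite core

`define_dendrite_core()` smooths the image (default 2 px Gaussian),
finds the brightest-ridge path between user anchors by Dijkstra search
on inverted intensity (8-connected, igraph), refines each path point to
the intensity centroid of its perpendicular profile, and smooths the
centerline with cubic smoothing splines before measuring arc length.
Anchors whose local smoothed intensity falls below the Otsu threshold
are rejected as background. On noise-free tubes the traced length is
within 0.5 % of truth for straight and quarter-circle paths; the test
suite enforces 2 %.

### Skeleton fit

The spine skeleton is the curve from the ROI base point into the ROI
along which sampled fluorescence is maximal. The objective is the
*mean* interpolated intensity along the curve minus a curvature penalty
$\lambda \sum \theta_j^2$ (squared turning angles, scaled by the ROI
peak intensity; $\lambda = 0.05$ by default). Mean rather than
integrated intensity is deliberate: a total-intensity objective rewards
arbitrarily long curves and has no interior optimum, contradicting the
notion of a skeleton. The search is deterministic: candidate tips are
the ROI pixels most geodesically distant from the base (top 3, spaced
at least 4 px apart); for each, a 5-control-point polyline initialized
along the within-ROI geodesic path is optimized by Nelder–Mead over its
interior points; the best objective wins, ties break toward the shorter
curve. Finally the distal endpoint is refined to the arc position where
the axial intensity falls to half of the head plateau above background,
which decouples the measured length from how far the ROI mask extends
into the PSF skirt. The refined half-plateau endpoint is also what
makes the measurement robust to mask dilation or erosion by a pixel or
two.

### Head width and the basal exclusion

Head width scans arc positions $s \in (L/3, L]$ and takes the maximum
full width at half maximum, above background, of the intensity profile
perpendicular to the skeleton. FWHM was chosen over a thresholded mask
width because it is stable under PSF broadening: for a disk of diameter
$W \gg \sigma$, the blurred half-maximum crossings sit at the disk
edge. For narrow necks ($W \approx 3\sigma$) FWHM overestimates by
~10 %, which is why the recovery tolerance for width (15 %) is looser
than for length (10 %). The basal exclusion is applied in arc length of
the fitted skeleton ($s \le L/3$), not Euclidean distance from the
dendrite, so strongly bent spines exclude the intended third of their
extent. Background for both the FWHM and the endpoint refinement is the
image median, which is accurate whenever structures occupy a minority
of pixels — true for all rendered scenes and typical dendrite fields.

ROIs are taken as given (ground-truth masks in the synthetic studies,
or externally drawn masks for real images), matching a semi-automatic
workflow; automatic spine detection is out of scope.

### Measured performance

Problem sizes were chosen so the full validation stays comfortable on a
single core: the recovery suite renders 200 spines spanning all five
classes (PSF 0.1 µm, photon scale 500) and requires the median relative
error ≤ 10 % for length and ≤ 15 % for width, with ≥ 80 % correct class
assignment away from bin boundaries; observed medians are ~2–3 % and
accuracy ~95 %. Rendering at 0.07 vs 0.035 µm/pixel changes the
measured ratio by ~3 %, supporting the scale-free claim.

## Group statistics

The KS statistic is reported in the convention $D$ (max ECDF
deviation), $ks = D\sqrt{n_1 n_2/(n_1+n_2)}$, and $p$. The asymptotic
$p$ uses the Kolmogorov series
$Q(\lambda) = 2\sum_{k\ge1} (-1)^{k-1} e^{-2k^2\lambda^2}$, truncated
when a term drops below $10^{-12}$; no small-sample continuity
correction is applied by default since the study's software is
unspecified. The exact $p$ is the permutation tail probability of $D$
over all $\binom{n_1+n_2}{n_1}$ relabelings, computed by a lattice-path
dynamic program over blocks of tied pooled values (so ties are handled
exactly), feasible up to $n_1 n_2 \le 10^4$. Reported $p$-values are
floored at $10^{-6}$ — the convention used when quoting vanishingly
small probabilities — with the raw value retained programmatically.

Stratified comparisons split both samples at a ratio threshold
(default 2). Values exactly at the threshold go to the *below* stratum
by default; the side is configurable because no convention fixes it,
and with continuous ratios the choice is immaterial.

The $t$-test is Student's pooled-variance unpaired test
($df = n_1+n_2-2$), deliberately not Welch's. CV is $100\,s/\bar x$
with the $n-1$ denominator.

## Behavior scoring

The scoring rules: a sample counts toward an object when the nose is
within `proximity_cm` (2 cm) of the object footprint boundary *and* the
nose–body heading vector points within `heading_deg` (45°) of the
object center *and* the climbing flag is off; counting accumulates
chronologically and stops when the total reaches `criterion_s` (20 s);
an animal that never reaches the criterion within the session is
excluded. Two readings deserve flags:

* The protocol phrase "at least 2 cm from the object" is implemented as
  *within* 2 cm — the standard proximity rule and the only reading
  consistent with simultaneously facing the object. This is prominent
  and configurable.
* Latency is the time of the first counted sample, not of the first
  bout exceeding some minimum duration (unspecified in the protocol;
  the simpler rule is used).

The 45° heading cone is likewise a convention choice (unstated in the
protocol) and configurable. Climbing is a boolean channel in the
trajectory: paw detection from video is out of scope, so the generator
plants the "all four paws on the object" state directly.

The generator embeds planned bouts in a wandering trajectory that is
pushed outside the proximity band between bouts, making accidental
exploration impossible; during bouts the nose is inside the band with
heading jitter at 40 % of the cone. The ground-truth summary applies
the same accumulation rule to the plan on the sample grid, and the
round-trip suite requires the geometric scorer to reproduce it within
one sample interval over 50 seeded sessions. This validates the rule
implementation, not pose tracking: real scoring error is dominated by
upstream nose/body detection, which is out of scope. NOR and NOL
sessions differ only in metadata (interval, object roles); the scorer
is shared.

## Proteomics

TPA converts raw intensities to concentrations,
$c_{is} = I_{is}/(M_i \sum_j I_{js})$, so each sample's concentrations
satisfy $\sum_i c_{is} M_i = 1$ exactly — the test suite asserts this to
$10^{-12}$. Missing intensities are explicit `NA` (never zero), which
makes the ≥ 60 % group-presence filter well defined; the filter retains
a protein when at least one group reaches the fraction ("min valid in
at least one group"), preserving group-specific proteins in a
comparative design; an "every group" mode is available. The
unique-peptide filter (≥ 2) and presence filter commute.

Differential abundance: fold change is the ratio of group mean
concentrations (not log-means, matching the mean-abundance-ratio
convention of the heatmap display); significance is a pooled $t$ on log
concentrations with missing values excluded (no imputation, since the
original imputation settings are unknown); FDR is Benjamini–Hochberg,
chosen over permutation-based FDR because it is deterministic and fully
specified. A call is `up` when fold ≥ 1.2 and $q \le 0.05$, `down` when
fold ≤ 1/1.2 and $q \le 0.05$, else `ns`; every tested protein gets
exactly one label.

**Known power limitation.** With $n = 5$ per group and a between-sample
CV of 20 %, the pooled-$t$ noncentrality at a 1.5-fold change is
$\log 1.5 / (\sqrt{\log 1.04}\,\sqrt{2/5}) \approx 3.24$ ($df = 8$),
and BH at FDR 0.05 over ~1000 proteins with 10 % true effects settles
at a per-test threshold near $5\times10^{-4}$: the chain then recovers
only ~5–10 % of 1.5-fold effects (it recovers ~80 % at 2-fold, and
realized FDR stays below 0.05 throughout). This is a property of the
method at these design parameters, not an implementation artifact;
detecting modest folds reliably at $n = 5$ requires variance moderation
or relaxed error control, both outside this package's conventions.

The generator plants log-normal intensities (per-protein baseline,
sdlog 1.5 across proteins; within-protein between-sample noise matching
`sample_cv`), an exact count of effect proteins scaled by their fold in
one designated group (up or down), per-group MCAR missingness, and
unique-peptide counts with a configurable single-peptide fraction. It
does not emulate intensity-dependent missingness, shared-peptide
inference ambiguity, or batch effects.

## The end-to-end study

`run_study()` wires the stages into a four-group design (Y-CTR, Y-BAY,
O-CTR, O-BAY; five proteomic replicates per group, nine behavioral
animals per group by default). Group defaults encode the study
conditions: young controls carry an immature-rich mixture, aged
controls a mature-rich one; treated young animals shift mature with
density halved (1.02 → 0.54 spines/µm); treated old animals keep
density (1.05 vs 1.08 spines/µm) while their immature compartment grows
more filopodia-like. Dendrite core lengths per scene are jittered
(lognormal, sdlog 0.08) so per-scene densities scatter around the
planted group density the way per-cell dendrite segments do. The
default 60 spines per group keeps a full run around a minute; the
determinism check runs a 12-spine configuration twice and compares
MD5 checksums.

Every stage seed derives deterministically from the global seed and a
stage label (polynomial string hash folded into the 31-bit seed range),
so stages can be rerun independently and nothing depends on call order.
Wall-clock timings are written only to `run.log`, which is excluded
from the checksummed manifest precisely so that repeated runs are
bit-identical.

## Numerical conventions

* Pixel centers sit at $(i-0.5)\cdot\text{pixel size}$ µm, origin top
  left; all lengths are reported in µm.
* Image interpolation is bilinear; profiles are sampled at quarter-pixel
  steps.
* Nelder–Mead (maxit 300, reltol $10^{-7}$) keeps the skeleton fit
  deterministic; multi-start ties break toward the shorter curve.
* Degenerate inputs error loudly and early: empty samples, zero pooled
  variance, zero-mean CV, all-absent proteomic samples (named in the
  error), spines outside the image (indexed in the error), anchors on
  background.
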