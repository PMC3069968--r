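---
title: "Models and methods behind ischemri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ischemri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ischemri)
```

`ischemri` analyses serial quantitative MRI of experimental stroke in the
mouse: perfusion (CASL CBF), diffusion (ADC), and relaxometry (T1, T2)
acquired at an early (1–2 h) and a late (24 h) timepoint after middle
cerebral artery occlusion, summarized over atlas-defined cortical and
subcortical regions of the MCA territory and tested voxelwise. Because
no raw animal data are distributed with studies of this kind, the
package ships a digital phantom that forward-simulates every
acquisition from known ground truth; every analysis stage is then
validated by parameter recovery. This vignette documents the models,
the tunable parameters and their defaults, the numerical choices, and
what the synthetic validation does and does not demonstrate.

## Signal models and their inverses

**Inversion recovery (T1).** The simulator and fit share the magnitude
model $|S_0\,(1 - 2\beta e^{-TI/T_1})|$ over eight inversion times
(0.02–10 s), with $\beta$ the inversion-pulse efficiency. The recovery
delay in the emulated protocol is 10 s — more than five times any brain
T1 at high field — so the saturation term of a finite-TR experiment is
omitted; it would not be identifiable from these data anyway. Fitting is
two-stage, as is standard in relaxometry when an adiabatic inversion is
slightly imperfect: a 3-parameter fit per voxel estimates
$(S_0, \beta, T_1)$, the converged $\beta$ values are averaged over the
brain (typical recovered values 0.95–0.97 for a true 0.96), and a
2-parameter refit with $\beta$ frozen produces the lower-variance T1 map
that the CBF computation consumes. The absolute-value model is fitted
directly rather than polarity-restoring the data first: magnitude
reconstruction is what a scanner delivers, and the fit then needs no
sign heuristic.

**CPMG (T2).** Monoexponential decay $S_0 e^{-TE/T_2}$ over the first 20
of 32 echoes (echo spacing 4.2 ms). Truncating the echo train is the
usual guard against stimulated-echo and noise-floor contamination in
late echoes; here it also mirrors the emulated protocol. T2 maps are in
milliseconds throughout — the infarct segmentation threshold is defined
on that scale and the segmentation refuses maps whose brain median is
outside 1–500 ms.

**Diffusion (ADC).** One $b = 0$ image and three repetitions at
$b = 800\ \mathrm{s/mm^2}$. The repetitions are averaged in signal space
*before* the log — matching acquisition-side averaging and lower in
variance than averaging per-repetition ADCs — and
$\mathrm{ADC} = -\tfrac{1}{b}\ln(SI_b/SI_0)$. For $b = 800$ the
prefactor is the familiar $-0.00125$; the implementation keeps the
general $-1/b$ form so other b-values remain correct. Voxels with a
non-positive signal ratio are masked out rather than clamped.

**CASL (CBF).** The quantification is the single-compartment
steady-state form
$$f = \frac{\lambda\,(M_{\mathrm{ctrl}} - M_{\mathrm{lbl}})}
           {2\alpha\,T_1\,M_{\mathrm{ctrl}}},\qquad
  \mathrm{CBF} = 6000 f\ \ \mathrm{ml/100\,g/min},$$
with labelling efficiency $\alpha = 0.7$ and partition coefficient
$\lambda = 0.90$ mL/g. This is the variant consistent with exactly those
two constants and requiring no timing parameters (labelling duration,
post-label delay) beyond them; transit-time effects are deliberately
outside the model, in the simulator as well as in the inverse, so the
pair is self-consistent. The $T_1$ entering the equation is the voxel's
own fitted tissue T1 from the 2-parameter map — the only T1 measured in
this protocol; a slab-average alternative can be substituted by passing
a constant map. The phantom's forward model is the algebraic inverse,
$M_{\mathrm{lbl}} = M_{\mathrm{ctrl}}(1 - 2\alpha f T_1/\lambda)$, and
flows high enough to drive $M_{\mathrm{lbl}}$ negative are rejected as
unphysical.

The CASL protocol object carries `casl_averages` (default 16): a single
label/control pair carries a ~1–3% signal difference, far below a usable
per-voxel contrast at any realistic SNR, and real perfusion protocols
accumulate many pair averages over their multi-minute acquisition. The
simulated pair therefore carries frame noise reduced by
$\sqrt{16}$.

## Phantom geometry and the subject model

The atlas is a single 1.5 mm coronal slab at bregma, 64×64 over an
18 mm field of view: an elliptical brain with a deep-grey core, two
ventricles (CSF), mirror-symmetric hemispheres about the central
sagittal midline, a cortical ROI spanning the lateral sector of the
ipsilateral (right) cortex — the centre of the MCA territory — and a
subcortical ROI (the ipsilateral deep grey, standing for caudoputamen +
pyramidal tract). A 13-slice whole-brain stack is not simulated by
default: all ROI statistics and all validation targets live on the
slab, and the array code is slice-count agnostic should a stack be
needed. Brain, CSF, hemisphere and ROI masks are phantom outputs,
standing in for the manual brain extraction and CSF removal of a real
study; when a series is deliberately misaligned, the pipeline instead
derives a brain mask by signal thresholding and registers the subject
to a synthetic structural template of the atlas.

Healthy tissue values (cortex / subcortex / CSF): T1 1.8 / 1.7 / 4.0 s,
T2 30 / 31 / 160 ms, ADC 7.9 / 7.8 / 24 ×10⁻⁴ mm²/s, CBF 148.4 / 120 /
0 ml/100 g/min. The healthy cortical CBF is pinned by the encoded
study's own numbers: its early-reperfusion arm reports ipsilateral
cortical CBF 28.2 ml/100 g/min with an ipsi/contralateral ratio of
0.19, giving 148.4 for the contralateral side. (The same study's 24 h
pair implies ~197 — the two printed pairs are mutually inconsistent —
and the 1 h-derived value is adopted because the ratio cell validated
here is the 1 h one.)

**Outcome cells as ground truth.** `table1_fixture()` encodes the
study's group × ROI × timepoint outcome table (CBF, ADC, qT2,
probability of infarction; mean ± SEM) as phantom truth: within the
affected MCA territory each ROI carries its cell value uniformly, and
tissue elsewhere carries healthy values. The truth infarct mask is the
affected region where true T2 exceeds the 34 ms threshold. A
consequence worth stating: the probability-of-infarction cells of the
treated arm (e.g. 34.5% cortical infarction alongside a *normal* 29 ms
mean cortical T2) cannot be reproduced by any phantom in which infarct
is a binary T2-elevated state — inverting the mixture gives a "lesion"
T2 *below* the healthy value. Real lesions there are thin, partial and
heterogeneous. The package therefore treats partial-extent lesion
geometry (below) as a separate phantom mode for validating the
segmentation machinery, and validates the probability pipeline
quantitatively on the consistent cells (control arm at 24 h, where the
lesion covers the full deep territory and the expected probability is
exactly 100%).

**Lesion geometry.** In sector mode a lesion of extent fraction $e$ of
the territory is grown as a contiguous region from a deep subcortical
seed outward, so partial lesions cover the subcortex before the
cortical mantle — the cortico-subcortical gradient of infarct
probability seen in group probability maps. $e$ can be fixed or drawn
per subject from a Beta distribution.

**Between-subject variability.** Each subject draws one standard-normal
$z$ per quantity, shared across ROIs and timepoints (an animal is its
own repeated measure). T2 and ADC cells vary additively
($\mu + z\,\mathrm{SD}$); CBF varies through a shared multiplicative
perfusion factor per quantity cell ($\mu(1 + z\,\mathrm{SD}/\mu)$), with
healthy tissue scaled by the same factor. The multiplicative form is
what the data demand: the encoded study's CBF SEMs are a near-constant
~12–14% of their means across cells, and its ipsi/contralateral ratios
carry far less variance than the absolute values — both signatures of a
global perfusion factor that cancels in the ratio.

The fixture encodes the between-subject SD of each cell *at the printed
SEM scale*, not at SEM·√N. This is a deliberate calibration: the
package's validation contract is that a regenerated N = 10 cohort mean
lands within one printed SEM of the cell value with high probability,
which fixes the admissible cohort-mean dispersion. It understates real
animal variability by ~√10; consequences are that recovery tests are
sharp, and that the ANOVA power property below is comfortably rather
than marginally met. Nothing in the quantification depends on this
scale.

**Noise** is additive Gaussian per frame (not Rician), with SNR defined
as brain-mean $S_0$ over the noise SD, default 40. All fitted
quantities here are estimated from high-SNR magnitude data where the
Gaussian approximation is adequate and keeps the round-trip tests
unbiased; a Rician floor would matter only in the late CPMG echoes of
CSF-like voxels, which the 20-echo truncation already avoids.

## Numerical choices

All voxelwise fits run through one vectorized Levenberg–Marquardt loop
(`fit_voxels_lm`): residuals and Jacobians are voxel × frame matrices,
the damped normal equations are solved in closed form per voxel
(parameters ≤ 3), and per-voxel damping adapts independently.
Convergence is a relative parameter change below 1e-8 (cap 200
iterations); this reproduces closed-form solutions to well beyond six
significant digits on noiseless data. Initialization: T2 and ADC from
the log-linear closed form (voxels with non-positive intensities fall
back to a heuristic start and skip the log step); T1 from
$S_0 = \max|S|$ and $T_1 = TI_{\min\text{signal}}/\ln 2$,
$\beta_0 = 0.95$. Degenerate voxels — flat or zero signal across
frames, or T2 at its upper bound — are flagged non-converged and
removed from the validity mask; output masks only ever shrink.

Registration is rigid in-plane (one rotation about the grid centre, two
translations; the "six degrees of freedom" of a volume protocol reduce
to three on a single slab, and no scaling or shear is fitted because
phantom and atlas share the voxel grid). The metric is normalized
cross-correlation — appropriate for the mono-modal, same-contrast
registration performed here and fully deterministic — optimized
coarse-to-fine (4×, 2×, 1× block-averaged) with an exhaustive coarse
grid (±16°, ±6 voxels) followed by Nelder–Mead refinement with fixed
iteration caps. Median recovery error over random perturbations within
±15°/±5 voxels is below 0.1 voxel and 0.5°. Interpolation is bilinear
for continuous maps and nearest-neighbour (label-preserving) for masks;
out-of-view voxels become NA and drop out of validity masks.

Segmentation uses the strictly-greater rule (infarct ⇔ T2 > threshold):
the printed threshold itself is non-lesion, matching the display
convention in which the lower bound of the colour scale is the
segmentation threshold. No connected-component or minimum-size filter
is applied by default (none is part of the method definition); a
`min_cluster` option exists for exploratory use. Probability maps are
computed over each subject's validity-masked segmentation on the
common atlas grid, so their values are exact multiples of 1/N.

For the ROI statistics, the 2×2 mixed-design ANOVA is computed from the
classical sums-of-squares decomposition (GROUP tested against subjects
within groups, df (1, N−2); TIME and GROUP×TIME against the
within-subject residual) — with two within-subject levels sphericity is
moot. The implementation is cross-checked in the test suite against an
independent `stats::aov` subject-stratum oracle to 1e-10 relative F
error, including unbalanced group sizes. Voxelwise inference follows
the max-statistic permutation framework: one-sample t per voxel on
per-subject difference maps of contralaterally normalized CBF (ROI
ANOVAs, in contrast, consume absolute CBF — both are wired explicitly),
null built by sign-flipping subject difference maps — exhaustively
(2^N) for N ≤ 12, else 10,000 seeded random flips — and each voxel's
corrected p is the fraction of permutations whose image-wide maximum
meets its statistic. Exhaustive p values are exact rationals k/2^N and
bit-reproducible. Both one-sided directions (late > early and
early > late) are always computed. No variance smoothing or
cluster-based enhancement is applied. The within-group paired design is
the implemented default; an unpaired two-cohort contrast is available
through `group_compare`.

## Validation scale and what it shows

The study-level recovery suite regenerates each headline cell from a
fresh cohort (N = 10; N = 4 for the early arm) at SNR 40 on the 64×64
slab — about 20 s per full set on one CPU — and requires the recovered
cohort mean within one printed SEM. The ANOVA power property
(GROUP×TIME interaction detected in ≥ 90% of 200 regenerated cortical
CBF cohorts) is evaluated on ROI-level cohort draws from the phantom's
subject model: at these ROI sizes measurement noise contributes < 1.5
ml/100 g/min to a cortical ROI mean against between-subject SDs of
3–8, so image-level regeneration changes nothing but the runtime; a
single image-level cohort is still carried through the full pipeline in
the test suite as a spot check. The family-wise error of the
permutation test is verified empirically at ≤ 0.07 over 500 pure-noise
regenerations (its exact exhaustive level at α = 0.05 with N = 8 is
12/256 ≈ 0.047).

What passing these tests shows: the forward models and their inverses
are mutually consistent to machine precision; the pipeline's cohort
summaries are unbiased at realistic SNR; the statistical components
have their nominal size and the designed power under the phantom's
subject model. What they do not show: robustness to motion, B0/B1
inhomogeneity, partial-volume and transit-time effects, Rician floors,
or anatomies beyond the compartment geometry — none of which the
phantom emulates. Bloch-simulation-level realism, multi-compartment
relaxometry, IVIM/tensor diffusion and nonlinear registration are out
of scope by design.

## Session info

```{r}
sessionInfo()
```
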