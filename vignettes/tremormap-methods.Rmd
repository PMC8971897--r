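---
title: "Methods: sweet-spot mapping and fiber filtering for dual-lead thalamic DBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweet-spot mapping and fiber filtering for dual-lead thalamic DBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep brain stimulation (DBS) of the ventral thalamus suppresses medically
refractory tremor, including the severe postural and action tremor of
multiple sclerosis (MS). When two unilateral leads are implanted — one
targeting the ventralis intermedius (VIM), one the ventralis oralis
posterior (VOp) — three connectomic questions arise:

1. **Where** is the stimulation sweet spot, i.e. which voxels, when inside
   the volume of tissue activated (VTA), predict tremor improvement?
2. **Which cortical connections** of the stimulated tissue carry the
   benefit (structural connectivity regression)?
3. **Which individual fiber tracts** discriminate good from poor
   responders (discriminative fiber filtering)?

`tremormap` implements the full analysis chain for these questions, plus a
synthetic phantom cohort with planted ground truth so that every stage is
testable by parameter recovery rather than by eyeballing.

## Electric field and VTA model

The stimulation field is modelled by analytic point-source superposition in
an infinite, homogeneous, isotropic medium of conductivity
$\sigma = 0.14\ \mathrm{S/m}$:

$$\mathbf{E}(\mathbf{v}) \;=\; \sum_c \frac{I_c\,(\mathbf{v}-\mathbf{p}_c)}
{4\pi\sigma\,\lVert \mathbf{v}-\mathbf{p}_c \rVert^3},$$

where $\mathbf{p}_c$ are the active contact centers and $I_c$ the signed
currents (cathodes negative; voltage-mode amplitudes are converted through a
configurable 1 kΩ impedance). The VTA is the set of voxels whose center
field magnitude reaches the activation threshold of
$0.2\ \mathrm{V/mm}$. A finite-element solver adds nothing in this setting:
the medium is already assumed homogeneous and isotropic, and the analytic
model has a closed-form oracle — a monopolar cathode of current $I$
activates a ball of radius

$$r^\* = \sqrt{\frac{|I|}{4\pi\sigma E_{thr}}}\;(\approx 1.69\ \mathrm{mm\ at\ 1\ mA}),$$

against which the implementation is tested at several grid resolutions.
Numerical choices: the singularity inside a contact is capped at the value
on the contact surface (radius 0.635 mm by default; the field magnitude is
continued into the center), fields are evaluated at voxel centers with no
partial-volume handling, and pulse width/frequency are carried as metadata
but do not enter the amplitude-driven field model.

## Sweet-spot mapping

Per subject, the binary (aggregate VIM ∪ VOp) VTA is multiplied by the
percent TRS motor improvement, giving a weighted map that is negative for
subjects who worsened. The voxel-wise **mean effect** divides by the full
cohort size N everywhere (non-covering subjects contribute zeros); dividing
by the per-voxel coverage count is available as a flag but is not the
default, because the separate 40% coverage mask already handles sparsely
covered voxels.

Inference is a one-sample, one-sided (improvement > 0) sign-flip
permutation test with threshold-free cluster enhancement (TFCE):

* the per-voxel sample variance image is Gaussian-smoothed with
  $\sigma = 2.5$ mm (converted to voxels through the affine) before forming
  $t(v) = \bar{x}(v)\,/\sqrt{s^2_{smooth}(v)/N}$ — the standard
  small-sample variance regularisation; voxels whose smoothed variance is
  still zero get $t = 0$;
* TFCE integrates $e_h(v)^{E} h^{H}\,\mathrm{d}h$ over 100 equal threshold
  steps in $(0, \max t]$ with $E = 0.5$, $H = 2$, 26-connectivity — the
  de-facto standard exponents, exposed as parameters;
* each permutation flips every subject's map by an independent sign and
  records the maximum TFCE over the analysis domain (the union of subject
  coverage; outside it every map is zero and $p = 1$);
* when $2^N$ does not exceed the permutation budget (with $N = 11$,
  $2^{11} = 2048 < 5000$) all sign patterns are enumerated exactly,
  otherwise a seeded Monte-Carlo sample is drawn;
* corrected p-values use $(1 + b)/(P + 1)$, which cannot reach zero; in the
  exact path the identity flip is one of the $P$, making the convention
  slightly conservative.

The significance mask ($p_{FWE} < 0.05$) is intersected with the cohort
coverage mask — voxels inside at least $\lceil 0.4N \rceil$ VTAs (5 of 11;
the ceiling is evaluated with a $10^{-9}$ slack so that exact products such
as $0.4 \times 5 = 2$ are not pushed upward by binary rounding) — and the
mean effect restricted to this final mask yields the improvement-weighted
sweet spot. Its intensity-weighted centre of gravity (COG) is reported in
world mm. If the weighted map contains negative values the COG falls back
to the binary mask; an empty mask yields NA with a warning.

The TFCE/permutation engine is implemented in C++ (incremental union-find
over sorted voxels) because the null calibration alone evaluates on the
order of $10^5$ smoothed t maps; it is validated against an independent
brute-force R implementation (threshold loop + flood fill) to $10^{-6}$
relative, and the exact-enumeration path against a full $2^N$ oracle.

## Structural connectivity

The default connectivity path mirrors normative-connectome practice: one
shared cohort tractogram, with per-subject "seeding" realised as selection
of the streamlines that intersect the subject's VTA. Intersection testing
sub-samples every segment at half the smallest voxel size, so a streamline
cannot skip a voxel between stored vertices. Connectivity to an ROI is the
fraction of the subject's selected streamlines that touch the ROI
(pass-through **or** termination by default; endpoint-only counting is a
flag). ROIs with zero connectivity in every subject are discarded;
per-subject zeros for retained ROIs are kept. Improvement is regressed on
each retained ROI's connectivity by ordinary least squares with a pointwise
95% confidence band, and Spearman's rank correlation (average ranks on
ties) is reported alongside.

A deterministic direction-field tracker is also provided (bidirectional
fixed-step integration, nearest-voxel principal direction, 45° angular
stop, support-image threshold, 10–200 mm length gates, uniformly seeded
voxels); it exists so that tracking-based workflows and their stopping
rules are exercised — straight-field, sharp-bend and constant-curvature
oracles — while the bundle-selection path remains the default. The
200 000-seed default is interpreted as seed *attempts*, with fractions
normalised by the retained total.

## Discriminative fiber filtering

For every streamline of the shared tractogram, a binary traversal matrix
records which subject VTAs it crosses (same half-voxel sub-sampling).
Fibers traversing fewer than 20% or more than 80% of the N VTAs are
excluded — the bounds are inclusive and compared as exact fractions without
rounding, so at $N = 11$ the retained traversal counts are 3…8. Each
remaining fiber gets a two-sample pooled-variance Student t comparing
improvement between traversed and non-traversed subjects (Welch available
as a flag; the pooled form follows the fiber-filtering literature). Fibers
whose split leaves a group smaller than two are kept with $t = 0$ and a
flag, so fiber counts are stable across noise realisations. Positive-t
fibers form the favorable tractogram; a two-cohort comparison summarises
per-ROI endpoint fractions of each cohort's favorable set and their
overlap.

## The synthetic cohort and its planted truth

The phantom is a 48 mm cube at 1 mm isotropic resolution, bilaterally
symmetric about $x = 0$, with a thalamus-like ellipsoid per hemisphere
split at a coronal border into posterior VIM and anterior VOp, and six
disjoint cortical boxes (SMA, PMC, PSC, SSC on the superior convexity, PVC
posterior, TL inferior). Because the phantom is exactly symmetric, the
right-to-left folding of right-sided subjects is an exact mirror flip
across $x = 0$ — the rigid stand-in for the non-linear template warp used
with real data — and all analysis happens in the left hemisphere.

Each of the N = 11 subjects (2 right-sided) receives a vertical VIM lead
and a vertical VOp lead whose deepest contacts land on the respective
nucleus centroids plus 0.4 mm isotropic Gaussian placement jitter. The
active contact is the deepest, monopolar cathodal. Currents are drawn
uniformly per lead: 3.4–3.6 mA for the VOp lead and 0.5–4.5 mA for the VIM
lead. This asymmetry is deliberate: the near-constant VOp field saturates
the sweet-spot overlap term (below), while the wide VIM range spreads the
unfavorable-pathway recruitment across subjects — the two axes of
variation that the sweet-spot and fiber-filtering stages respectively must
recover. Three-month outcomes use only the randomised initial-target lead;
six-month outcomes use the dual-lead aggregate VTA, mirroring the
staged-programming design of the clinical cohort.

The shared tractogram contains a favorable bundle (300 streamlines from
inside VOp to the SMA box), an unfavorable bundle (300 from inside VIM to
the PMC box) and 400 background fibers that avoid both nuclei. Streamlines
are smooth quadratic arcs displaced by one rigid Gaussian offset each
(1 mm SD for the bundles), so zero-jitter bundles provably traverse their
waypoint nucleus.

Outcomes follow the planted linear model

$$\mathrm{improvement}_i = \beta_0 + \beta_G\,O_i + \beta_{SMA}\,C_i(SMA)
 - \beta_{PMC}\,C_i(PMC) + \varepsilon_i,\qquad
 \varepsilon_i \sim \mathcal{N}(0, \sigma_n^2),$$

with $O_i$ the fractional overlap of the subject's VTA with a planted
sphere of radius 2.5 mm at (−10, 1.5, 0) mm — inside VOp, just anterior to
the VIM border, encoding the conclusion that anterior (VOp-side)
stimulation is optimal — and $C_i(\cdot)$ the connectivity fractions.
Defaults are $\beta_0 = -100$, $\beta_G = 150$ (the dominant coefficient),
$\beta_{SMA} = 120$, $\beta_{PMC} = 145$, $\sigma_n = 10$. The study-scale
cohort cannot constrain these effect sizes; they are calibration choices,
fixed once so that the simulated 6-month improvement distribution has mean
≈ 30% and SD ≈ 30% and that the three recovery properties below hold at
realistic signal-to-noise. Because every subject's VOp VTA essentially
contains the sphere, $\beta_G$ contributes a large mean but little
between-subject variance; the subject ordering is carried by the bundle
terms. The full truth record (sphere, bundle specification, coefficients,
per-subject overlap and connectivity terms) is serialised to JSON and
replays the noiseless outcomes exactly.

What the generator emulates: jittered dual-lead geometry, current-dependent
VTA size, hemispheric folding, bundle-mediated outcomes, zero-connectivity
ROIs (PVC, TL), negative responders. What it does not: MS lesions,
diffusion signal formation, registration error, disease progression,
per-patient impedances, and any non-linear outcome structure. Passing
recovery tests therefore demonstrates correctness of the analysis chain
under its own assumptions, not clinical validity on real data.

## Verification strategy and problem sizes

The test suite checks, at sizes chosen to keep the default run in minutes:

* closed-form oracles — monopolar VTA radius (0.25–0.5 mm grids),
  single-voxel TFCE integral, textbook one-sample and pooled two-sample t
  values;
* independent-implementation oracles — brute-force TFCE on random
  $10^3$-voxel maps ($10^{-6}$ relative), full $2^3$ sign-flip enumeration
  on $4^3$ grids, Monte-Carlo vs exact $2^{12}$ p-values within three
  binomial standard errors, OLS via normal equations, Spearman via manual
  average ranks, `stats::t.test` over hundreds of random splits;
* calibration — 200 null cohorts (improvements i.i.d. standard normal,
  512 permutations, 2 mm phantom) keep the family-wise false-positive rate
  within three binomial standard errors of the nominal 0.05;
* parameter recovery on the planted cohort (fixed generator seed 42,
  $\sigma_n = 5$ for the recovery runs) — sweet-spot COG within two voxels
  of the planted center, positive SMA and negative PMC slopes, and ≥ 90%
  of positive-t output fibers carrying the generator's favorable label;
* round-trips — NIfTI volumes ($10^{-5}$), TRK streamline coordinates
  ($10^{-3}$ mm, float32 storage), JSON configs, and bit-identical
  regeneration under a fixed seed.

`scripts/acceptance.R` re-runs the same computations end-to-end from a
fresh seed and writes the resulting quantities as JSON.

## Known limitations

* The analytic field model ignores tissue heterogeneity, anisotropy and
  electrode encapsulation; it is exchangeable wherever a finite-element
  field is available, since only the thresholded field enters the pipeline.
* The mirror flip is exact only for symmetric spaces; real asymmetric
  templates require a non-linear warp outside this package's scope.
* TFCE exponents and the variance-smoothing convention follow the cited
  tools' defaults; other choices change absolute TFCE scores (inference is
  invariant to monotone rescaling of the max statistic only within a
  permutation scheme).
* With N = 11, exact enumeration caps the attainable FWE p-value at
  1/2049; reported sub-threshold p-values should not be over-read.
* Spearman p-values accompany the regressions for completeness but are not
  used as decision gates anywhere in the pipeline.
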