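---
title: "Proxy-based needle-insertion force rendering: model, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proxy-based needle-insertion force rendering: model, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctforce)
```

## The problem

Training simulators for percutaneous liver punctures (PTC/PTCD) must
render the axial force a physician feels while advancing a needle from
the skin, through fat and fascia, into the liver and finally a dilated
bile duct. Rendering from a *fully* hand-segmented CT is accurate but
expensive to prepare; rendering from a *partially* segmented patient —
only fascia, liver, vessels and bile ducts are delineated, everything
else classified on the fly from CT intensity — is cheap but risks force
errors wherever the implicit classification disagrees with a careful
manual segmentation. `punctforce` implements both the rendering model
and the apparatus to quantify exactly that risk.

## The force model

Every tissue label carries a haptic tuple $(T_N, R, k)$: the cut-force
threshold in N a surface withstands before being pierced, the sustained
friction force in N of the shaft inside the tissue, and a stiffness in
N/mm. The defaults (`default_tissue_table()`) are an expert-tuned set:
skin $(0.7, 0.7, 0.8)$, fat/soft tissue $(0.7, 0.7, 1.0)$, fascia
$(2.5, 1.0, 1.0)$, liver $(0.3, 0.9, 1.2)$, hepatic vessels
$(1.05, 0.75, 1.1)$, bile ducts $(1.2, 0.5, 1.0)$, bone
$(\infty, 3.0, 2.0)$, air $(0, 0, 0)$. Two properties are deliberate:
skin has $R = T_N$ (the needle enters through a small incision, so no
force drop follows the skin cut), and the liver has the lowest finite
$T_N$ while $R > T_N$ — its capsule yields easily but dragging the shaft
through parenchyma costs more, so the force steps *up* after the cut.
Because of the liver row, $R \le T_N$ is documented as typical, not
enforced.

Rendering is proxy-based. The tip position $x$ advances along the
planned path; a proxy $p$ interacts with tissue surfaces:

* **Phase 1 — pre-puncture.** At a surface whose $T_N$ exceeds the
  current force, the proxy is pinned there and the force follows the
  second-degree polynomial $f(d) = a_2 d^2 + a_1 d + a_0$ of the
  proxy–tip displacement $d$. $a_0$ is the force level at which the ramp
  starts; $a_1 \in [0, k]$ is free; $a_2 = k(k - a_1)/|T_N - a_0|$. This
  family is anchored to the linear spring: whatever $a_1$, $f$ reaches
  $T_N$ at the same displacement $(T_N - a_0)/k$ where a plain Hooke
  spring of stiffness $k$ would, so the puncture *position* is a model
  invariant and $a_1$ only shapes the feel of the ramp. The default
  `a1_fraction = 0.5` (i.e. $a_1 = k/2$) gives a visibly progressive
  ramp; results that matter (peak positions, peak heights, sustain
  levels) are insensitive to it, which the test suite checks.
* **Phase 2 — post-puncture.** When $f$ exceeds $T_N$ the surface is
  cut. The rendered sample at the cut carries the trigger force $T_N$ —
  the puncture peak — and the proxy is released to $R/k$ behind the tip,
  so the following sample is already at the sustain level $R$ of the
  tissue now at the tip. Phase 2 is thus instantaneous at sampling
  resolution but the peak force is exact: an insertion through the
  default stack peaks at exactly 2.5 N at the fascia, not at
  $2.5 - O(\text{step})$.
* **Phase 3 — pass.** The proxy is dragged at the maximum spring length
  $l_{max} = R/k$ behind the tip; the Hooke force $k\,|p - x|$ then
  renders the constant friction $R$.
* **Phase 4 — transition.** At a surface *softer* than the current force
  ($T_N \le$ sustained force) the cut is immediate and the force drops
  (or, entering the liver, steps) to the new $R$ with no peak. Exiting
  the body decays to 0. Bone is impenetrable: the ramp is linear with
  slope $k$ (the non-linear anchor degenerates as $T_N \to \infty$),
  clamps at the 22 N device ceiling, and the tip is refused beyond the
  clamp depth. Retraction uses phase 3 only — every membrane on the path
  has already been cut — so it renders friction with no peaks.

One boundary rule matters for thin sheets: while the proxy is pinned
(phase 1), tissue changes at the *tip* do not interrupt the ramp — the
cut condition is owned by the pinned surface; the sustain level after
the cut comes from the tissue at the tip.

## Tissue at the tip: masks first, then the transfer function

At every sample the segmentation mask wins if it labels the voxel;
otherwise CT intensity is classified by ordered thresholds
$t_0 < t_1 < t_2^- \le t_2^+$ into air $(-\infty, t_0)$, skin
$[t_0, t_1)$, fat/soft $[t_1, \cdot)$ and bone, with half-open intervals
for deterministic boundary behaviour. The bone threshold is
state-dependent: $t_2^-$ (sensitive) before the needle has passed the
fascia, $t_2^+$ (specific) after it, where dense enhancing tissue would
otherwise be mistaken for bone. Air encountered *inside* the body is
flagged as a risk structure (an air cavity must not be punctured), as is
any risk-role tissue (bone, vessels). The thresholds are patient-specific
in practice and never universal constants; the package defaults
($-500, 50, 200, 400$ HU) merely anchor the synthetic phantoms, which
generate their intensities relative to whatever set is configured — no
result depends on HU realism.

## Path planning

Candidates run from every exposed skin voxel (skin with an air
6-neighbour) to every voxel of the target centerline. The centerline of
the tubular bile-duct mask is extracted by a deterministic
principal-axis skeleton: each 6-connected component is projected on its
first principal axis, binned at one-voxel resolution, and each bin
collapsed to the voxel nearest its centroid; compact components collapse
to a single centroid voxel. This is tailored to elongated tubes (an
already 1-voxel tube maps to itself); it is not a general curved-object
topological thinning, which no installed dependency provides and the
straight-tube phantoms do not need.

Each candidate is scored $Q = \sum_i \alpha_i C_i$ with
$\alpha_i = 1/2$: $C_1 = \infty$ if a risk structure is crossed before
the target (else 0), $C_2 = \infty$ beyond the 90 mm insertion limit
(else 0), $C_3$ the minimal distance to a risk structure along the path
(from a Euclidean distance transform of the risk mask, clipped at
`d_cap` = 10 mm and normalised), and $C_4$ the count of target voxels
along the shaft (capped at `n_cap` = 10, normalised). Higher $Q$ is
better; $Q = \infty$ flags infeasibility; accepted paths additionally
need $Q \ge 0.4$. The caps are design choices where the criteria are
stated only as "normalised": they keep both soft criteria bounded,
monotone and data-independent. Ties between equal-quality candidates
break towards the smallest $(z, y, x)$ target voxel, so planning is
fully deterministic. On the default phantom the planner accepts ≈3,250
paths, all through the intercostal window — the rib avoidance emerges
from the constraints, it is not coded.

## Error metrics

Two renderings of the same path are compared sample-wise: RMSE; the
maximum absolute error (abbreviated MAE throughout, following the
convention of the evaluation it implements — the *maximum*, not mean);
and the percentage of exactly identical forces (%Fc), with "identical"
meaning within $10^{-9}$ N — bit-level noise only, since the comparison
is same-engine, different-segmentation. Border lags are measured per
structure: the $i$-th entry crossing of a structure in one rendering is
matched with the $i$-th in the other; the mean and maximum absolute
depth differences give per-path MSD and HSD; crossings present under
only one segmentation are excluded from the distances and reported as a
count, keeping the discrepancy visible without inventing pairings. MAE
outliers are flagged one-sidedly above mean $+ 2.7\sigma$ (sample
standard deviation). Weber fractions
$\mathrm{JND}\% = 100\,((S + \Delta S) - S)/S$ convert errors into
perceptual terms; the formula is implemented as printed, so the 18.1%
hand-arm force fraction on the 0.8 N average counter force gives a
0.145 N threshold, and a 2 mm lag on a 28 mm reference distance gives
7.14% (not a rounded 8%).

## The synthetic phantoms

`layered_phantom()` emulates a desk-scale lower thorax/upper abdomen:
128×128×160 voxels at 0.9 mm isotropic; air to 5 mm, 2.7 mm skin,
fat/soft tissue, a fascia sheet at 25 mm, liver to 110 mm with a 6 mm
bile-duct tube at 60 mm depth and two vessel tubes, and two rib-like
bone slabs flanking a 20 mm intercostal window. Geometry choices worth
recording:

* **Fascia thickness 4.5 mm, liver directly under the fascia.** The
  fascia failure mode this phantom must reproduce is two *misaligned
  pre-puncture ramps inside the sheet*: with a band above the fascia
  misclassified as liver, one rendering peaks at 2.5 N while the other
  still sits at the band's 0.9 N sustain — a 1.6 N systematic maximum.
  That requires the sheet to contain both renderings' puncture events:
  thickness greater than the pre-puncture displacement (1.8 mm for
  soft→fascia) plus the largest modelled detection offset (2 mm). A
  thinner sheet would instead let the delayed peak fall beyond the
  reference's sheet exit and measure a sheet-exit artefact.
* **Intensity noise.** Per-class Gaussian draws with means strictly
  inside their threshold intervals and a 10 HU standard deviation: the
  smallest margin to a threshold is 50 HU = 5σ, so noise-induced
  misclassification has probability below $10^{-6}$ and any
  ref/test discrepancy comes from the *injected* perturbations alone.
* **Perturbations.** Surface offsets delay the *entry* surface of a
  structure in the test model (skin offsets act on the intensity volume,
  since skin is transfer-function territory; fascia offsets act on the
  partial labels); `misclassify_band()` relabels a band proximal to a
  structure's surface. Both are local by construction: voxels outside
  the stated band are bit-identical. Offsets quantise to the 0.9 mm
  grid, so "+2 mm" realises as 1.8 mm; the failure-mode quantities are
  invariant to this (a plateau-versus-zero or peak-versus-sustain
  difference, not a lag integral).
* **Two-fascia variant.** `two_fascia_phantom()` inserts a second sheet
  at 40 mm with soft tissue between, reproducing the double-peak force
  pattern and, under band misclassification, the misaligned-peak failure
  mode.

What the phantoms do *not* emulate: partial-volume effects, intensity
inhomogeneity and histogram differences between patients, curved or
breathing anatomy, segmentation errors with curved geometry, needle
bending and non-axial force components. Passing tests on these phantoms
therefore validate the rendering and evaluation machinery and the
stated failure modes — not clinical-grade force accuracy on real CTs.

## Numerical and design notes

* Sampling: 1,000 force samples per path regardless of length (90 mm
  worst case → 0.09 mm spacing, ≥10× oversampling of sub-millimetre
  voxels; a warning — not an error — fires below 10×, with 1% headroom so
  the canonical 90 mm/1,000 configuration itself counts as 10×).
  Label/intensity lookups are nearest-voxel: labels are categorical, and
  the classifier thresholds a single voxel at the tip, so interpolation
  would invent tissue.
* The pass-phase friction is direction-symmetric; retraction differs
  from insertion only by the absence of cuts.
* The engine is allocation-free per sample and fully deterministic:
  identical inputs give bit-identical signals, and the complete default
  pipeline (phantom → ≈3,250 paths planned → 6,500 renderings →
  evaluation) runs in about a minute on one CPU; the test suite runs the
  whole of it as a property check.
* Events at sampling resolution: surfaces are detected at the first
  sample inside a new tissue and cuts at the first sample at or past the
  threshold crossing, so event positions are accurate to two sample
  steps against a 20× oversampled brute-force proxy simulation, while
  forces away from events agree to machine precision.
* Ray walks use steps of half the smallest voxel spacing (no diagonal
  voxel skipping); the risk-clearance distance comes from a separable
  (Felzenszwalb) Euclidean distance transform honouring anisotropic
  spacing.

## Known limitations

Curved trajectories, tissue deformation and breathing motion, 3D force
components, bevel-tip micro-events, and real-time device coupling are
out of scope: the engine works in the undeformed image along straight
paths. The centerline extractor assumes elongated or compact targets;
strongly curved tubes would need true 3D thinning. The transfer
function's canonical codes tie intensity classification to the default
tissue vocabulary; fully labelled (mask-only) models are free to use any
code scheme, which the planner's relabeling-invariance test exercises.
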