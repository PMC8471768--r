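---
title: "Particle-filter centerline tracking: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle-filter centerline tracking: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The tracking model

Coronary arteries in contrast-enhanced cardiac CT are thin, bright, elongated
tree structures. `vesselpf` recovers their centerlines as a chain of estimates
$\hat{x}_0, \hat{x}_1, \dots$ produced by a sequential importance resampling
(SIR) particle filter. The state of a particle is a position $x$ (world mm)
and a unit heading $d$; the image is a stationary observation shared by all
steps.

Each step has the classic two phases:

* **Prediction.** Every particle spawns `successor_count` candidate states on
  the sphere of radius `step_size` around it, with headings drawn over the
  forward hemisphere (details under *Proposal* below).
* **Update.** Each candidate is weighted by
  $w \propto w_\text{parent}\; p(Y \mid x)\; p(x \mid x_\text{parent})$,
  where $p(Y \mid x)$ is a vesselness probability measured on the candidate's
  2D tangent patch and the transition prior factorises into a
  direction-change term and a patch-similarity term. Weights are normalised
  and the population is reduced back to `n_particles` equal-weight particles
  by systematic resampling (chosen for its low variance; the resampling
  scheme is not otherwise prescribed by the method).

The centerline estimate advances by the step length along the
weight-averaged candidate heading, anchored at the weighted parent mean —
algebraically the posterior-weighted mean successor position. Anchoring the
update at the particle cloud, rather than dead-reckoning from the previous
estimate, matters in curved vessels: the cloud is held on the lumen by the
likelihood, while an unanchored integral of mean headings accumulates
lateral drift with no restoring force. Both readings are consistent with the
weighted-direction-sum form of the state update; the anchored one is the
minimum-mean-square-error point estimate.

## The tangent-patch observation

The observation at a candidate is a 32 × 32 pixel patch resampled (trilinear)
on the plane through the candidate position orthogonal to its heading, with
in-plane pitch `patch_spacing` (default 0.25 mm/pixel, an 8 mm field of view
that spans the thickest proximal vessels with context). When the heading is
aligned with the vessel, the lumen appears as a centred, near-circular bright
disc; misaligned patches show elongated or irregular shapes. This is what
makes a patch classifier an orientation-aware vesselness measure. Samples
falling outside the volume take the volume's minimum intensity, so tracking
near borders degrades gracefully.

## The likelihood

Two interchangeable likelihood models implement the same contract
(a probability in $[0,1]$ per patch):

* **Patch CNN** (`build_patch_cnn()`, `train_likelihood()`): three 3 × 3
  same-padded convolution layers of 32, 64, 128 channels, each followed by
  ReLU and 2 × 2 max pooling, then fully connected layers of 512, 256 and 2
  units with a softmax head. Kernel size, stride, padding and pooling are not
  prescribed by the architecture's published outline; the values here are the
  minimal conventional completion of the stated channel/unit counts, frozen
  so the parameter count (1,273,602) is well defined. Patches are
  standardised to zero mean and unit variance before the network, removing
  dependence on absolute intensity calibration. Training uses cross-entropy,
  mini-batches of 128, Adam at $10^{-3}$, up to 20 epochs with early stopping
  on validation accuracy. The in-vessel softmax component is used verbatim as
  the filter likelihood. The network is implemented in vectorised R on BLAS
  matrix kernels (im2col convolutions); it is deliberately small enough to
  train on a desk machine.

  Training patches (`sample_training_patches()`) are drawn uniformly in
  arclength along a reference vessel, with azimuth noise $U[0, 2\pi)$ and
  polar tilt $N(0, 15^\circ)$ on the patch normal. In-vessel patches have
  centroids displaced inside the lumen; out-of-vessel patches mix
  near-wall displacements of 1–3 radii (hard negatives), far-background
  draws out to 10 radii (so the classifier is calibrated on the empty
  patches the tracker queries when a hypothesis leaves the vessel — a
  classifier never shown background extrapolates unreliably there), and a
  15% share of *longitudinal decoys*: in-lumen centroids with normals
  tilted 60–90°, labelled out-of-vessel because the patch shows a slab,
  not a cross-section. The decoys give the phantom-trained classifier the
  alignment sensitivity the stopping rule depends on; on patient CT the
  same sensitivity arises naturally because longitudinal views contain
  surrounding anatomy. Every non-decoy label is verified against the true
  nearest-centerline distance rather than assumed from the draw.

* **Analytic oracle** (`oracle_likelihood()`): available whenever ground
  truth is known (phantom runs), the logistic of the signed wall distance,
  $\mathrm{logit}^{-1}\!\big(-s\,(\text{dist} - r)\big)$ with sharpness
  $s = 6$/mm — a 10–90% transition of ≈ 0.7 mm, about twice the phantom's
  partial-volume blur. When the patch orientation is supplied the oracle is
  additionally alignment-sensitive through a $\cos^8$ factor on the angle to
  the local ground-truth tangent (≈ 0.5 at 30°, roughly two standard
  deviations of the tilt noise used to train the classifier, 0 at 90°). This
  mirrors the essential behaviour of the patch classifier — misaligned
  patches are non-circular and score low — and is load-bearing: with a
  direction-blind oracle, sideways candidates at a vessel's distal end keep
  the summed likelihood high and the filter turns around instead of
  stopping.

## The transition prior

The prior factorises as
$p(x_{t+1}\mid x_t) = p(d_{t+1}\mid d_t)\; p(\Phi_{t+1}\mid \Phi_t)$.

**Direction term.** A histogram over the angle between consecutive unit
headings, learned from reference centerlines resampled at the tracking step
size (so the statistics match the per-step geometry). Binning is 36 bins of
5° over [0°, 180°]; empty bins are floored at $10^{-4}$ and renormalised, so
unseen sharp turns are strongly penalised but never impossible. The prior is
learned from root-to-distal *paths* of the reference trees
(`tree_paths()`), the form in which reference vessels are annotated; a path
that crosses a bifurcation contributes that turn, giving the histogram a
small genuine tail at large angles.

**Patch term.** Consecutive tangent patches of a vessel have similar
intensity distributions. Patches are reduced to normalised histograms
(32 bins over a per-volume 1st–99th percentile range, fixed for the run so
histograms are comparable), compared by Jensen–Shannon divergence with
base-2 logarithms — the base is forced by requiring the range $[0,1]$ — and
mapped through the cubic smoothstep $w(x) = 2x^3 - 3x^2 + 1$ on $[0,1]$
(0 outside) after scaling by `lambda_scale` (default 6). A divergence of
$1/\lambda$ or more zeroes the prior.

## Proposal distribution

The proposal is a 50/50 mixture: half the candidates draw their polar angle
from the learned direction histogram (truncated to the forward cap,
uniform-in-cosine within a bin), half uniformly over the forward hemisphere;
azimuths are uniform. Every candidate's weight carries the exact importance
factor $p_\text{prior}/q$, so the prior is neither double-counted (for
prior-guided draws) nor ignored (for exploratory draws). The design was
genuinely open, and the naive alternative — a purely uniform cap proposal
with the prior only in the weight — is statistically untenable here: a
realistic concentrated prior puts ~85% of its mass in a 5° bin that covers
0.4% of the cap, so almost all uniform candidates carry negligible weight
and the effective sample size collapses to a handful. The mixture keeps the
effective sample size in the hundreds while the uniform half retains full
forward coverage, which bifurcation detection depends on. The exported
`sample_successors()` keeps the plain uniform-cap behaviour.

## Bifurcation detection (majority/minority clustering)

At a branching site the vesselness field has two lobes. The "important"
candidates — those the classifier itself calls in-vessel (likelihood ≥ 0.5,
its decision boundary) — from the last three steps are pooled and clustered
with DBSCAN (`eps = 0.75 * step_size`, `min_pts = 4`). Clustering operates
on the candidates' one-step look-ahead points $x + \gamma d$: at the carina
the two limb lumens still overlap spatially, but the headings split
immediately, so the look-ahead points separate one step's length down each
limb without any extra metric parameter. If at least two clusters emerge,
the two heaviest (by summed posterior weight) are kept. Each cluster's limb
direction is the vesselness-weighted mean heading of its members — inside
the branch cluster the posterior weights are dominated by the
direction-change prior and would drag the estimated direction towards the
main vessel — and a bifurcation is declared when the angle between the limb
directions exceeds `branch_angle` (default 50°). The heavier cluster (the
majority) continues the main vessel — the filter resamples from its members
of the current step — and the minority seeds a branch. Because the branch
population only separates from the main lumen once it is beyond it, the raw
minority centroid sits a couple of millimetres down the branch; the emitted
seed is therefore the back-projection of the centroid along the minority
axis to its closest approach to the tracked path (the carina estimate),
advanced 1.5 steps into the branch, with the minority direction.

Several details here were settled empirically during design, each against a
measured failure mode. Selecting important samples by posterior weight
cannot work: the direction prior suppresses branch-lobe weights by orders
of magnitude, so a top-mass rule only ever sees the main lobe. Clustering
raw candidate positions detects branches several millimetres late, because
the limb lumens overlap at the carina. Single-step clustering is fragile —
a freshly opened branch contributes only a handful of well-aligned
candidates per step, hence the 3-step pooling and the core threshold of 4.
The angle vertex question disappears with heading-based limb directions,
and the 50° threshold then retains a real margin on a 60° branch.

Detection idles for the first 3 steps of an ostium track and the first 6 of
a branch-seeded track (the pooled window must fully clear the junction the
track emerged from), and for 3 steps after each firing (one anatomical
bifurcation fires once). When assembling a tree, a branch seed is dropped
as a duplicate when its forward ray (0, 1 and 2 steps along its direction)
comes within `eps` of an already-tracked, finely resampled centerline — a
duplicate rides an existing vessel, a genuine branch dives away from every
tracked curve.

## Stopping

The stopping statistic $\tau$ is the plain sum of all candidate likelihoods
at a step. Deep inside a vessel most candidates score near 1 and $\tau$ is
in the hundreds; past the distal end it collapses towards zero. Tracking
stops when $\tau$ falls below `stop_threshold` (default 5), when the
estimate leaves the volume, or at `max_steps` (default 500, a pure safety
bound). If every candidate weight vanishes the step reports a degenerate
stop rather than dividing by zero.

# Parameters

| parameter | default | unit | why |
|---|---|---|---|
| `n_particles` | 200 | — | published operating point |
| `step_size` | 1.0 | mm | ≈ 3 voxels of typical coronary CT spacing; not printed by the method, chosen once |
| `lambda_scale` | 6 | — | published operating point |
| `branch_angle` | 50 | degrees | published operating point |
| `stop_threshold` | 5 | — | published operating point |
| `patch_pixels` | 32 | px | fixed by the classifier input |
| `patch_spacing` | 0.25 | mm/px | 8 mm field of view covers 2.5 mm-radius proximal vessels with context |
| `successor_count` | 5 | — | candidate fan-out per particle; the successor indexing implies several per particle without stating a count |
| `histogram_bins` | 32 | — | patch histogram resolution |
| `dbscan_eps` | 0.75·step | mm | clusters must separate at one step's scale |
| `dbscan_min_pts` | 4 | — | smallest credible lobe |
| `important_mass_fraction` | 0.8 | — | fallback weight-mass rule when likelihoods are absent |
| `proposal_prior_fraction` | 0.5 | — | exploitation/exploration split of the mixture proposal |
| `max_steps` | 500 | — | safety bound |

# The phantom generator

`generate_phantom()` builds CT-like volumes with known ground truth: bright
tubular trees (straight, planar-arc, or helical parents, linear radius
tapers, optional children at specified arclength fractions and angles) on a
darker background, rasterised by a signed-distance sweep (a voxel is
in-vessel iff it is within the local radius of the centerline — the sweep of
a sphere, so tube ends are rounded), with Gaussian per-voxel noise and a
Gaussian partial-volume blur. Defaults: vessel 400 ± 30 and background
50 ± 30 on an HU-like scale with 0.4 mm blur — mimicking contrast-enhanced
lumen against myocardium/fat without claiming calibration — on a
96³ × 0.35 mm grid. Radii span the 2.5 mm→0.8 mm range of proximal-to-distal
coronaries. All randomness flows from one seed through two named substreams
(geometry, noise), so geometry can be held fixed while noise varies.

`default_phantom_suite()` fixes ten canonical cases (straight, curved,
helix, taper, a tube ending mid-volume, Y-bifurcations at 60° and 90°, a
two-bifurcation tree, low contrast, high noise) used throughout the test
suite; the problem sizes — ten volumes of 96³ voxels, vessels of 14–30 mm,
10,000 training patches — are the package's desk-scale study conditions.

What the phantoms deliberately do **not** emulate: cardiac motion and
stair-step artifacts, calcified plaque and stenoses, contrast
inhomogeneity along the vessel, neighbouring bright structures (aorta,
chambers, veins), and anatomically realistic tortuosity distributions.
Passing the phantom suite therefore demonstrates the internal correctness
of the filter, the priors, the bifurcation logic and the metrics — not
clinical-grade performance on patient CT, which additionally depends on
training data breadth and artifact robustness.

# Numerical choices

* World millimetres are the universal unit; voxel indices exist only inside
  interpolation. Centerline text is 4-column `x y z r` without header
  (3-column accepted on read for method output).
* Radii are linearly interpolated in arclength wherever centerlines are
  resampled (one shared resampler).
* Evaluation resamples both curves to 0.03 mm arclength spacing,
  approximating the continuous-curve convention of the benchmark;
  correspondence is point-to-nearest-point, matching the "at least one of
  the points" marking rule. The average-inside distance is the plain mean
  (the squared-mean variant sits behind a flag): the printed formula of the
  benchmark description suggests squares, but its prose and the magnitude of
  reported values (≈ one voxel) require plain distances.
* The overlap of the clinically relevant part (OT) restricts the reference
  to the span from the first to the last point with radius ≥ 1.5 mm and is
  flagged undefined when no such point exists, as is the accuracy when no
  method point is a true positive.
* Jensen–Shannon terms with $P(x)=0$ contribute zero; histograms clamp
  out-of-range intensities into the end bins.
* Frame construction orthogonalises the canonical axis least aligned with
  the normal (deterministic, continuous except at the documented axis
  switch).
* Ties in max pooling resolve to the first window element; training is
  deterministic given the seed and a fixed BLAS thread count.

# Known limitations

* The estimate can cut slightly inside very tight curves (it is a one-step
  posterior mean, not a smoothed trajectory); no centerline refinement or
  post-smoothing is applied.
* Stopping inherits the method's local character: a long occluded segment
  reads as a vessel end. Nothing global rescues early termination.
* Bifurcation angles at or below `branch_angle` are not detected by
  construction; angles near the threshold detect with seed-dependent
  latency of a step or two. Near-orthogonal branches sit at the sampling
  limit of the one-step forward proposal — candidates reach at most one
  step's length into such a branch, and only from particles crossing the
  carina on the branch side — so occasional misses occur there depending
  on where the particle cloud happens to cross.
* The likelihood-≥ 0.5 important-sample rule presumes a calibrated
  classifier; a poorly calibrated CNN shifts the effective selection
  threshold. Calibration on phantoms depends on the negative-sampling mix
  (near-wall, far background, longitudinal decoys) described above.
* Training and priors here are phantom-derived; applying the tracker to
  patient CT requires retraining the CNN and re-learning the angle
  histogram from clinical references.
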