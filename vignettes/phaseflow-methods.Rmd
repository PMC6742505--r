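---
title: "Phase unwrapping, uncertainty and EPI distortion correction with phaseflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase unwrapping, uncertainty and EPI distortion correction with phaseflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phaseflow corrects susceptibility-induced geometric and intensity
distortions in echo-planar MR images (EPI). It combines the two standard
correction families — B0 fieldmap estimation from dual-echo phase, and
deformable registration to an undistorted structural image — through a
per-voxel *confidence* in the fieldmap, computed from the same graph-cut
machinery that performs the phase unwrapping. This vignette describes the
models, the numerical choices, and what the synthetic validation does and
does not demonstrate.

## The problem

EPI has very low bandwidth along the phase-encode (PE) axis, so a local
off-resonance of $f$ Hz displaces signal by

$$\delta_{PE} = f \, T_{acq} \quad \text{voxels},$$

where $T_{acq}$ is the effective readout time. phaseflow carries fieldmaps
in Hz (the gyromagnetic ratio folded in), which makes this relation exact
and unit-unambiguous. The field is estimated from the phase difference of
two gradient echoes at times $TE_1 < TE_2$:

$$f = \frac{\Delta\Theta}{2\pi\,\Delta TE},$$

but the measured phase is only known modulo $2\pi$, confined to
$(-\pi, \pi]$ (ties at the boundary map to $+\pi$ throughout the package).
Recovering the integer wrap counts $k$ with
$\phi_t = \phi_w + 2\pi k$ is the phase unwrapping problem.

## Unwrapping as MAP inference on an MRF

The true phase is modelled as a six-neighbourhood pairwise Markov random
field with convex squared-difference potentials; the likelihood is a hard
constraint (the unwrapped phase must equal the wrapped phase modulo
$2\pi$ exactly). The MAP wrap-count field minimises

$$E(k \mid \phi_w) = \sum_{(i,j)} w_{ij}\,
  \bigl(2\pi(k_i - k_j) + \phi_{w,i} - \phi_{w,j}\bigr)^2 .$$

Starting from $k = 0$, each iteration solves for the binary increment
field $\delta \in \{0,1\}^{|I|}$ minimising $E(k + \delta)$. With
pairwise move energies $E(0,0) = E(1,1) = V(t)$, $E(1,0) = V(2\pi + t)$,
$E(0,1) = V(-2\pi + t)$, convexity of $V$ gives
$V(2\pi + t) + V(-2\pi + t) - 2V(t) = 8\pi^2 > 0$: every move problem is
submodular and solved *exactly* by one s/t minimum cut. Iteration stops at
the first move with no energy decrease (or after `max_iterations`,
default 100; typical phantom runs converge in 3–6 moves). Only $+1$ moves
are used: the energy depends on count differences alone, so relative
negative wraps are reachable and the global offset is a gauge freedom.
All outputs are therefore defined up to a global integer offset, which the
misclassification metric removes before comparison (the mode of
$k_{est} - k_{true}$ inside the mask).

The flow networks use the standard elementary-graph reparameterisation:
$e_{00}$ into a constant, $e_{10} - e_{00}$ and $e_{11} - e_{10}$ onto
terminal arcs (negative parts swapped to the other terminal), and
$e_{01} + e_{10} - e_{00} - e_{11} \ge 0$ on the pairwise arc. Max-flow is
an exact augmenting-path (Dinic) solver written for this package in C++;
capacities are doubles with a $10^{-11}$ residual tolerance, appropriate
for move energies of order $1$–$10^2$. On exact cut-cost ties the
per-node labels are implementation-defined (source-reachable nodes take
label 0); energies are not.

### Quality weighting

Phase is unreliable where magnitude is low, so per-edge weights are the
geometric mean of the two voxels' magnitudes, each normalised by the 95th
percentile and clipped to $[0, 1]$ — monotone, bounded and symmetric.
Voxels below 5% of the normalised magnitude (`mask_threshold`) are
excluded entirely (weight 0) and are not counted in any error metric.
Anisotropic voxel sizes do not rescale the potential; the six directions
are weighted equally.

## Confidence from min-marginals

The min-marginal $\psi_{v;j}$ is the minimum move energy with voxel $v$
forced to move-label $j$; forcing amounts to one infinite-capacity
terminal arc, and the extra max-flow equals the residual flow between $v$
and the opposite terminal. The solver computes it by a search rooted at
$v$ on the residual graph of the single unconstrained solve, recording and
rolling back every push, so all constrained solves reuse the same residual
flow and are value-identical to cold re-solves (both paths are exposed and
tested against each other and against enumeration).

The confidence of the MAP label is the softmax of negative min-marginals,

$$\omega_{v} = \frac{e^{-\psi_{v;MAP}}}{e^{-\psi_{v;0}} + e^{-\psi_{v;1}}}
 = \frac{1}{1 + e^{-(\psi_{v;other} - \psi_{v;MAP})}} \in [0.5, 1],$$

in which the partition function of the Gibbs distribution cancels; the
energy-difference form is used for numerical stability. Two deliberate
choices:

* **Gauge fixing.** Because the move energy has no unary term, the
  all-ones move costs exactly as much as the all-zeros move, so without
  further structure $\psi_{v;0} = \psi_{v;1}$ at *every* voxel and
  $\omega \equiv 0.5$. Confidence is meaningful only modulo this gauge:
  the computation anchors the single highest-quality voxel to the zero
  move. $\psi_{v;1}$ then measures the cheapest $2\pi$ flip of a region
  containing $v$ but not the anchor — the min cut between $v$ and the
  anchor — which is small exactly where a region is weakly tied to the
  rest of the volume (low magnitude, steep residual phase).
* **Aggregation.** Confidence is taken from the final, converged move
  problem, where the MAP move is all-zero, so $\omega$ measures the
  stability of the converged wrap counts. (A per-step aggregate is a
  conceivable conservative alternative; it is not retained by default.)

Min-marginal gaps larger than `psi_cutoff` (default 50) are not resolved
further: $e^{-50} \approx 2\times10^{-22}$, so $\omega$ is 1 to double
precision regardless, and capping the constrained searches there bounds
the per-voxel work. Oracle-equivalence tests run with the cap disabled.
For large volumes a `stride` option evaluates $\omega$ on a subgrid and
interpolates linearly; it is off by default. These min-marginals are
MAP-stability scores, not exact marginal probabilities.

## Fieldmap correction

The *wrapped difference* of the two echoes is unwrapped (differencing
first eliminates echo-common phase), converted to Hz, then to a PE
displacement field. Correction resamples each PE line at $y + \delta(y)$
with 1D natural cubic splines (out-of-field samples are zero) and
multiplies by the 1D Jacobian $1 + \partial\delta/\partial y$ (central
differences), which undoes the signal pile-up and conserves total
intensity of compactly supported images to within 1%. Non-positive
Jacobians (folded fields) are clamped at 0.05 with a warning. The phantom's
forward distortion uses the same model inverted per line by monotone
linear interpolation, so distort-then-correct round trips are accurate to
about 1% RMS for smooth fields up to ~5 voxels.

## Confidence-modulated discrete registration

The refinement registers the distorted EPI (floating) to an undistorted
structural image (reference), with a cubic-B-spline displacement field
constrained to the PE axis over a discrete label set, optimised by
$\alpha$-expansion, coarse to fine (spacing doubled at the coarser level,
label step halved at the finer; defaults: finest spacing 5 voxels, two
levels, labels $\pm 10$ voxels in steps of 1 then 0.5). The data term is
spatially encoded NMI (SEMI): for control point $s$, a joint histogram

$$H_s(r, f) = \sum_{x \in \Omega_s} w_r I_r(x)\, w_f I_f(x)\, \Gamma_s(x)$$

with cubic B-spline Parzen intensity windows (64 bins over the 1st–99th
intensity percentiles of each image) and an isotropic Gaussian spatial
weight $\Gamma_s$ of sd equal to the control spacing, truncated at 3 sd;
the score is Studholme's $NMI = (H(R) + H(F)) / H(R, F)$ with natural
logarithms (the base cancels). A degenerate single-bin histogram scores
the identity bound 2. Candidate labels are scored as a *constant*
displacement of the control point's weighted region on top of the current
field, with the floating intensities Jacobian-recomputed at every
resampling; scoring the basis-attenuated single-point move instead would
under-shift the region by the tensor basis peak ($\approx 0.30$) and bias
the recovered amplitudes upward by its inverse. The per-level data table
is computed once from the level's baseline field (all other current-level
coefficients at zero) — the standard local approximation that makes the
unaries fixed during the expansion sweeps.

The pairwise term penalises the absolute difference of the *total*
accumulated refinement (across cycles and levels) plus candidate label of
neighbouring control points. The fieldmap-derived initialisation is the
resampling baseline but is deliberately not included in these totals: with
the regulariser fully weighted the zero refinement is then exactly optimal
and the method returns its initialisation unchanged, which is the
behaviour the confidence modulation is meant to produce (a
total-deformation penalty would instead flatten a smooth, *trusted* init).
The objective is

$$E = \sum_i -\bigl(1 - \sigma_i\lambda\bigr)\,\mathrm{SEMI}_i
      + \sum_{(i,j)} \bar\sigma_{ij}\lambda\, \bigl|(R_i + d_i) - (R_j + d_j)\bigr|,$$

with $\sigma_i$ the unwrapping confidence projected onto the control grid
(a convex combination under the nonnegative basis weights),
$\bar\sigma_{ij}$ the mean of the two endpoints, and $\sigma\lambda$
clamped to $[0,1]$ so the data weight stays nonnegative. Absolute-value
pairwise terms on totals are not guaranteed submodular under expansion
moves; violating edges have their weights set to zero for that move, and a
move is only accepted if the *true* objective decreases, so the trace is
non-increasing by construction. Missing confidence input falls back to
$\sigma \equiv 0$ (purely image-driven) with a warning.

## The synthetic phantom

The validation phantom emulates the statistical structure the unwrapper
depends on — smoothness, dynamic range, SNR structure — rather than MR
physics. The true phase is a low-order 3D polynomial (spanning more than
one full cycle across the head, about $3.2 \times 2\pi$ with defaults)
plus Gaussian bumps, plus a resection-like ellipsoid carrying a steep
radial Gaussian phase ridge on its rim (sub-$\pi$ per voxel step provided
`rim_amplitude` $\le 4\,$`rim_width`, since the ridge's maximum slope is
$\approx 0.61\,A/w$ per voxel). The magnitude is a plateau of 100 inside
an ellipsoidal head mask with a deep cavity (3% of plateau) whose signal
recovers smoothly over a collar of $2\,$`rim_width` voxels outside the
cavity boundary — the partial-volume signal loss of a real resection
margin, and the reason the rim is a genuinely low-quality, low-confidence
area. The default grid is $64 \times 64 \times 32$ voxels of
$2.5 \times 2.5 \times 2.7$ mm, a typical interventional EPI resolution;
module tests use a $32 \times 32 \times 16$ version of the same structure
to keep runtimes low.

Noise is added either directly to the unwrapped phase (i.i.d. Gaussian of
stated variance — the model of the simulation study; the spatial scale of
the noise is not specified there, so i.i.d. per voxel is assumed) or to
the real and imaginary channels of $A e^{i\phi}$, whose angle reproduces
the exact phase-noise law: uniform where $A = 0$ and
$\mathcal{N}(0, (\sigma/A)^2)$ where $A \gg \sigma$. All stochastic
outputs are bit-reproducible for a fixed seed.

What passing phantom tests do **not** show: the phantom has no true phase
discontinuities (tissue-boundary susceptibility steps), no spatially
correlated noise, no intensity artefacts in the magnitude, and its
misclassification ratios are accordingly lower than benchmark figures
reported for Bloch-equation-simulated data at the same noise variances;
such figures function as upper bounds here. Clinical-grade performance
claims require real dual-echo data.

## Reproducing the simulation study

`scripts/acceptance.R` regenerates the phantom, adds Gaussian phase noise
of variance 0.08, 0.26 and 0.71 rad$^2$ (five seeds each, derived from
`--seed`), wraps, unwraps with defaults, and reports the masked,
offset-aligned misclassification ratio averaged over seeds. On one CPU the
three levels together take a few minutes; the registration recovery
experiment in the test suite (a $32^3 \times 16$ textured pair with a
smooth $\le 3$-voxel field) takes about half a minute. Problem sizes were
chosen so the full test suite runs in well under half an hour.

## Known limitations

* Min-marginal confidence is a stability score, not a calibrated
  probability; exact marginals would require sampling or variational
  inference.
* The unwrapper assumes the true field is smooth at the voxel scale;
  adjacent true-phase steps $\ge \pi$ (severe susceptibility gradients at
  air interfaces) violate the model for any unwrapper of this family.
* The registration moves control points along the PE axis only and
  assumes affine pre-alignment; no eddy-current, motion or
  gradient-nonlinearity correction is attempted.
* $T_{acq}$ is taken as the user-supplied *effective* readout time;
  parallel-imaging acceleration must already be folded in.
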