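---
title: "From facial surface EMG to simulated lip motion: models and methods"
author: "lipmaps"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lipmaps` implements, end to end, a pipeline that drives a biomechanical
model of the perioral soft tissue with muscle activation patterns (MAPs)
derived from multi-channel facial surface electromyography (sEMG), and then
scores how well the simulated lip-marker motion matches reference motion.
Because no public dataset of paired facial sEMG and 3-D lip-marker
recordings exists, the package ships a seeded synthetic-data generator with
known ground truth, so every stage — and the pipeline as a whole — is
testable without any download.  This vignette documents the models, the
tunable parameters, the numerical choices, and what the synthetic
experiments can and cannot show.

## Pipeline overview

1. **Synthetic data** — ground-truth activation envelopes per muscle, an
   amplitude-modulated band-limited sEMG synthesis with configurable
   cross-talk, and reference marker trajectories produced either by the
   finite-element model itself (self-consistent mode) or by a cheap
   kinematic surrogate.
2. **Feature extraction** — 15–500 Hz fourth-order Butterworth band-pass,
   Willison amplitude (WAMP) over a 200 ms sliding window with maximum
   overlap, per-channel min–max normalisation.
3. **Activation mapping** — the 7 measured bilateral muscles (OOS, OOI,
   RIS, ZYG, LLSAN, DAO, MEN) are mapped onto the 20 model muscle channels,
   and one of three activation strategies gates the channels.
4. **Forward simulation** — a reduced hexahedral finite-element model of
   the upper and lower lip, Mooney–Rivlin ground matrix with embedded
   transversely isotropic muscle fibres, implicit dynamics.
5. **Synchronisation** — both trajectory sets are resampled to a common
   160-frame grid, reduced to 1-D via the first principal component (SVD),
   and aligned by cross-correlation maximisation.
6. **Evaluation** — the per-marker 3-D correlation coefficient, with
   grouped summaries (per strategy, instruction, marker).

## Feature extraction

The Willison amplitude of channel $m$ in a window of $N$ samples is

$$g_m(t) = \sum_{n=1}^{N-1} \mathbf{1}\!\left[\,|s_m(t+n-1) - s_m(t+n)|
\ge s_{\mathrm{lim}}\,\right],$$

with threshold $s_{\mathrm{lim}} = 10$ mV and a 200 ms window
($N = \mathrm{round}(0.2 f_s)$, i.e. 410 samples at 2048 Hz).  "Maximum
overlap" is implemented as a hop of one sample, and every frame is stamped
with its window-centre time.  The filter is applied forward–backward
(zero phase, squared fourth-order magnitude) so that feature frames stay
aligned with marker frames.  Min–max normalisation maps each channel's
feature trace onto $[0,1]$ over the time index of one repetition; a
constant (silent) channel maps to zeros rather than dividing by zero.

A note on units: 10 mV is a large threshold for physiological sEMG, which
suggests amplifier-referred units.  The synthetic carrier amplitude is
chosen (30 mV RMS at full activation) so that the default threshold sits on
the sensitive part of the counting curve; both the threshold and the
carrier scale are configurable.

## Activation mapping

Per side, with normalised features $g$:

$$\mathrm{OOP} = 0.50\,(\mathrm{OOS} + \mathrm{OOI}),\quad
\mathrm{OOM} = 0.10\,(\mathrm{OOP} + \mathrm{OOI}),\quad
\mathrm{BUC} = 0.50\,(\mathrm{RIS} + \mathrm{ZYG}),$$
$$\mathrm{LAO} = 0.75\,\mathrm{LLSAN},\qquad
\mathrm{DLI} = 0.75\,\mathrm{DAO},$$

with MEN, ZYG, RIS, DAO and LLSAN passed through unchanged and OOS/OOI
dropped.  (OOM is sometimes described verbally as a fifth of the OOP; the
equation above, with the OOI cross-term, is what this package implements.)
Outputs are clipped to $[0,1]$: the sums of normalised channels stay within
range for the stated coefficients, but clipping guards arbitrary inputs.

The three strategies:

* `act_all` — all 20 channels pass unchanged;
* `act_3` — only the three muscles with the largest time-variance of the
  *bilaterally averaged* trace $\bar g_m = \tfrac12 (g_m + g_{m+10})$ are
  kept; the average is used for selection only, each side keeps its own
  trace.  Ties break on the canonical muscle order (OOP, OOM, BUC, LAO,
  DLI, MEN, ZYG, RIS, DAO, LLSAN) via a stable sort;
* `act_rel` — only the muscles listed as relevant for the instruction
  (editable table in `inst/extdata/relevant_muscles.json`) are kept,
  bilaterally, with their traces unchanged (no re-normalisation within the
  subset).

## The reduced lip model

The mesh is a deliberately reduced stand-in for a full generic face model:
two curved all-hexahedral slabs (upper and lower lip) on a cylindrical arc
(inner radius 25 mm, 120° span, 10 mm lip height, 2 mm initial lip
separation), three element layers through the 6 mm depth — inner (2.5 mm),
centre (2 mm) and outer (1.5 mm, the epidermis/dermis scale — with the
default 16×4×3 discretisation per lip (384 elements, 680 nodes).  All
inner-surface nodes are fixed (attachment to mandible and maxilla); ten
marker nodes sit on the vermilion border (philtrum base, cupid-bow pair and
corners on the upper lip; centre, mid and lateral pairs on the lower lip).
Coordinates: $x$ lateral (left $+x$), $y$ vertical (gravity $-y$),
$z$ anterior.

The passive tissue is Mooney–Rivlin with a logarithmic volumetric term,

$$W = C_{10}(\tilde I_1 - 3) + C_{20}(\tilde I_1 - 3)^2 +
\tfrac{\kappa}{2}(\ln J)^2,$$

with $C_{10} = 2.5$ kPa, $C_{20} = 1.175$ kPa, $\kappa = 25$ kPa,
$\tilde I_1 = \mathrm{tr}(\tilde{\mathbf B})$,
$\tilde{\mathbf B} = \tilde{\mathbf F}\tilde{\mathbf F}^T$ and
$\tilde{\mathbf F} = J^{-1/3}\mathbf F$ (the standard distortional split).
Soft incompressibility adds a quadratic bulk penalty
$\tfrac{\kappa_b}{2}(J-1)^2$ with bulk modulus $\kappa_b = 25$ kPa at
quadrature level; this element-level penalty approximates a nodal-averaged
variant.  Tissue density is 1040 kg m⁻³ and gravity 9.8 m s⁻² acts
downward.  Internally the core works in the consistent mm/tonne/s/MPa
system; the user API is in kPa and mm.

Muscles are fibre polylines (schematic, editable configuration): elements
whose centroid lies within 5 mm of a polyline become muscle elements, with
the fibre direction given by the nearest segment's tangent; explicit
element lists can override the rule (the manual-assignment hook used for
ring-shaped muscles in full face models).  The along-fibre Cauchy stress is

$$\sigma_f = \sigma_{\max}\left(f_p(\bar\lambda) +
a\, f_a(\bar\lambda)\right),\qquad \bar\lambda = \lambda/\lambda_{\mathrm{ofl}},$$

with the passive branch $f_p = 0$ for $\bar\lambda \le 1$,
$P_1(e^{P_2(\bar\lambda - 1)} - 1)$ up to the maximum stretch
$\lambda^* = 1.4$, and linear beyond with matched value and slope (C1);
$P_1 = 0.05$, $P_2 = 6.6$.  The active force–length curve is the parabola
$f_a = \max(0,\, 1 - 4(\bar\lambda - 1)^2)$, peaking at 1 at the optimal
stretch and vanishing at $\bar\lambda = 0.5$ and $1.5$.  The parabola is
our stated choice for the classic active-curve *shape* (only the passive
parameters are pinned down by the published values); it is isolated behind
the muscle definition so it can be swapped.  $\lambda_{\mathrm{ofl}} = 1$:
the reference configuration is taken as optimal fibre length.

The maximum stress $\sigma_{\max}$ starts at 300 kPa and is adapted: every
time an element inverts ($\det\mathbf F \le 0$) the stress is multiplied by
0.9 and the simulation restarts, a strictly geometric decrement with a hard
floor of 1 kPa.  In the synthetic experiments the strategy-comparison runs
share one adapted stress per (dataset, mesh) so strategy effects are not
confounded with stress re-adaptation.

### Numerics

* Implicit backward-Euler dynamics; the activation trace is resampled so
  that simulation frames align with the 160-step normalised timeline
  ($\Delta t = $ record duration / 160, i.e. 25 ms for a 2 s gesture with
  1 s rest padding each side).
* Lumped (row-sum) mass from the tissue density; for this heavily damped,
  slowly driven problem the difference from a consistent mass matrix is
  negligible and the diagonal form keeps the stepper simple.
* Stiffness-proportional damping $\beta K_{\mathrm{ref}}$ with
  $\beta = 0.05$ s, anchored at the reference-state stiffness so the
  damping force is symmetric and state-independent.
* Internal forces are exact (energy-consistent; verified against finite
  differences of the assembled energy).  The Newton tangent is assembled
  from a central finite difference of the first Piola stress per Gauss
  point ($h = 10^{-6}$); this affects only the iteration path, never the
  converged state.  8-point Gauss quadrature per hexahedron.
* Newton convergence at relative residual $10^{-9}$ with backtracking on
  element inversion and recursive step halving (depth ≤ 4) on
  non-convergence.
* The sparse free-DOF system is solved with `Matrix`; the sparsity pattern
  and submatrix extraction maps are precomputed once per mesh.

The quadratic bulk penalty bounds element volume change only relative to
the driving stresses: at a few kPa of active stress, $J$ stays within
±10 %, which is what the incompressibility property test asserts; at the
hundreds-of-kPa scale of the adapted maximum stress the 25 kPa penalty
permits larger excursions.  That is a property of the stated constants, not
a numerical artifact.

## Synchronisation

Both trajectory sets are linearly resampled to 160 frames, stacked into a
$30 \times T$ matrix (x, y, z of 10 markers per column), row-centred, and
reduced via SVD; the coefficient vector is
$\mathbf b = \mathbf u_1^T \mathbf X$.  Row centring is a deliberate
deviation from applying the SVD to the raw matrix: without it the first
component is dominated by the constant marker offsets and the coefficient
cross-correlation saturates.  It is switchable (`center = FALSE`).

The shift is the integer lag maximising the normalised cross-correlation of
the mean-removed coefficient vectors.  Two implementation details matter:

* the correlation at each lag is normalised by the *overlapping* segments
  (a global norm biases the argmax toward small lags, so a constructed
  delay of 10 frames would be recovered as 9 on smooth signals); lags
  leaving less than half the signal overlapping are not scanned;
* the first principal component carries an arbitrary sign, and for
  bimodal coefficient vectors (rest plateau vs. gesture plateau) the
  per-vector sign convention (largest-magnitude entry positive) can
  disagree between the two sets; the synchroniser therefore resolves the
  sign pairwise, flipping one vector when the opposite sign correlates
  better.

Shifts are integer frames only; the measured set is shifted, both sets are
cropped to the overlap, and an overlap below 16 frames is an error.

## Evaluation metric

For 3-D trajectories $\vec v_i$, $\vec w_i$:

$$\rho_{vw} = \frac{\tfrac1n \sum_i \vec v_i^{\,T}\vec w_i -
\vec\mu_v^{\,T}\vec\mu_w}{\sigma_v\,\sigma_w},\qquad
\sigma_v = \sqrt{\tfrac{1}{n-1}\sum_i \lVert \vec v_i - \vec\mu_v
\rVert^2}.$$

As printed above, the numerator uses $1/n$ while $\sigma$ uses $1/(n-1)$,
so $\rho(v,v) = (n-1)/n$; this mixed normalisation is the package default
(`mode = "printed"`).  A `mode = "consistent"` switch uses $1/n$ in both,
restoring $\rho(v,v) = 1$ exactly; the closed-loop experiment uses it so
that "perfect" means 1.  Both modes are tested; neither is silently
preferred.  Summaries report mean, sample standard deviation and median per
strategy/instruction/marker; single-observation groups report a standard
deviation of 0 with a degeneracy flag rather than erroring.

## The synthetic-data generator

Ground truth is generated per (instruction, repetition):

* six instructions — A purse lips, B raise upper lip, C depress mouth
  corners, D voluntary smile, E left-right-left with closed mouth,
  F purse–smile–purse;
* the measured-muscle envelopes engaged by an instruction follow a
  raised-cosine ramp (0.3 s) – hold – release profile over a 2 s gesture,
  with per-muscle peak amplitudes drawn from $U(0.6, 0.9)$; instructions
  A–D are left-right symmetric, E alternates side dominance across three
  sub-gestures, F stages purse–smile–purse;
* the 20-channel model truth is the measured envelopes pushed through the
  same measured-to-model transfer used by the analysis path, masked to the
  instruction's relevant muscles — so the truth is, by construction,
  expressible by the measurement model;
* repetitions default to four per instruction, separated by 2 s of rest
  (1 s padding each side of a record); the count is a configuration knob.

The sEMG carrier is Gaussian white noise band-passed to 15–500 Hz and
scaled to 30 mV RMS at full activation; each measured channel is the
cross-talk mixture (default: 0.1 leakage between anatomically adjacent
electrode sites, rows normalised, identity available) plus a white noise
floor (0.5 mV RMS).  Everything is bit-reproducible under a seed.

What this emulates: amplitude modulation, band-limited spectra, cross-talk,
additive noise, instruction/repetition structure, and kinematics consistent
with the biomechanical model.  What it does not: motor-unit statistics,
electrode geometry and skin impedance, volunteer-specific anatomy,
nonstationary artifacts, or tracking noise with outliers.  Passing the
closed-loop and benchmark tests therefore demonstrates the internal
consistency and robustness of the pipeline, not clinical performance on
real recordings.

## Experiments and problem sizes

* **Closed loop** (`closed_loop_experiment()`): instruction A, one
  repetition, no cross-talk/noise/offset, full 16×4×3-per-lip mesh, 160
  steps, consistent-mode metric.  Feature extraction distorts the
  activation envelopes only monotonically, so per-marker correlations
  approach 1; the package asserts a median ≥ 0.99.
* **Standard benchmark** (`standard_benchmark_config()`): all six
  instructions, cross-talk 0.1, noise on, three strategies sharing one
  adapted stress.  The mesh is scaled to 8×2×3 per lip and one repetition
  per instruction so a full three-strategy comparison stays tractable on a
  single CPU; the asserted property is ordinal — the selective strategies
  (`act_3`, `act_rel`) are not outperformed by blanket activation
  (`act_all`) by more than 0.05 in median correlation — not any particular
  correlation value.

## Known limitations

* No lip–lip contact: the reduced geometry keeps the lips initially
  separated and interpenetration is unchecked.
* Fibre geometry is schematic; the polylines are configuration, not
  anatomy.
* No jaw/maxilla rigid-body dynamics, no layered skin anisotropy, no
  remeshing.
* The benchmark's cross-talk and noise levels are mild; real facial sEMG
  cross-talk is stronger and structured, and the degradation of `act_all`
  relative to the selective strategies is correspondingly mild here.
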