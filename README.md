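# lipmaps

Driving a biomechanical lip model with muscle activation patterns derived
from facial surface EMG — as a fully synthetic, fully tested R pipeline.

## The problem

Surgery for lip cancer trades oncological margins against residual oral
function. One way to reason about that trade-off before operating is to
drive a biomechanical model of the perioral soft tissue with the patient's
own muscle activity, recorded noninvasively by multi-channel surface
electromyography (sEMG), and compare the model's lip motion against the
motion the person actually makes. `lipmaps` implements that pipeline for
researchers in neuromuscular signal processing and soft-tissue simulation:

* seeded **synthetic data** with known ground truth (no facial sEMG +
  3-D marker dataset is publicly available): amplitude-modulated
  band-limited sEMG with configurable cross-talk, and reference marker
  trajectories simulated by the model itself or by a kinematic surrogate;
* **feature extraction**: 15–500 Hz Butterworth band-pass, Willison
  amplitude (WAMP) over a 200 ms window with maximum overlap,

  g_m(t) = Σ_{n=1}^{N−1} 1[ |s_m(t+n−1) − s_m(t+n)| ≥ s_lim ],   s_lim = 10 mV,

  then per-channel min–max normalisation to [0, 1];
* **activation mapping** of the 7 measured bilateral muscles onto 20 model
  muscles (OOP = 0.50(OOS+OOI), OOM = 0.10(OOP+OOI), BUC = 0.50(RIS+ZYG),
  LAO = 0.75·LLSAN, DLI = 0.75·DAO, the rest passed through), under three
  strategies: `act_all` (every channel), `act_3` (the three muscles with
  the largest bilateral-average variance), `act_rel` (an editable
  per-instruction relevance table);
* a reduced **hexahedral finite-element lip model**: Mooney–Rivlin ground
  matrix W = C10(Ĩ₁−3) + C20(Ĩ₁−3)² + κ/2 (ln J)² with C10 = 2.5 kPa,
  C20 = 1.175 kPa, κ = 25 kPa, soft-incompressibility bulk penalty
  (25 kPa), density 1040 kg/m³, gravity, fixed inner surface, and
  transversely isotropic muscle fibres (exponential passive branch turning
  linear at λ* = 1.4, P1 = 0.05, P2 = 6.6; parabolic active force–length;
  maximum stress adapted from 300 kPa by 10 % decrements whenever an
  element inverts);
* **synchronisation** of simulated and measured trajectories on a
  160-frame grid via the first principal component (SVD) and
  cross-correlation lag maximisation;
* **evaluation** with the 3-D correlation coefficient
  ρ = [ (1/n) Σ vᵢᵀwᵢ − μᵥᵀμ_w ] / (σᵥ σ_w) per marker, plus grouped
  summaries (strategy / instruction / marker).

The methods vignette (`vignettes/lipmaps-methods.Rmd`) documents every
model, parameter and numerical choice in detail.

## Worked example

A complete closed-loop run on a reduced mesh — synthetic ground truth →
sEMG → WAMP features → `act_rel` activations → FEM → synchronisation →
per-marker correlation (consistent normalisation, so 1 is perfect):

```r
library(lipmaps)
report <- closed_loop_experiment(mesh = mesh_config(nx = 8, ny = 2),
                                 frames = 160, seed = 1)
median(report$rows$rho)
#> [1] 0.9930051
round(report$rows$rho, 3)
#>  [1] 0.996 0.992 0.943 0.993 0.996 0.994 0.992 0.950 0.993 0.994
```

Ten numbers, one per lip marker: the motion simulated from the activations
*recovered from the synthetic sEMG* correlates ≥ 0.94 with the motion
simulated from the ground-truth activations, with the lip-centre markers
(smallest excursions) lowest — the pipeline loses almost nothing end to
end when the data are clean.

The noisy strategy benchmark (cross-talk 0.1, noise floor on, six
instructions, shared adapted maximum stress):

```r
report <- run_experiment(standard_benchmark_config(seed = 1))
print(report$summary_by_strategy, row.names = FALSE)
#>    group   n      mean         sd sd_degenerate    median
#>    act_3  60 0.7773840 0.43579385         FALSE 0.9708845
#>  act_all  60 0.8677090 0.39479000         FALSE 0.9824161
#>  act_rel  60 0.9769253 0.03019168         FALSE 0.9896937
#>    (all) 180 0.8740061 0.34779915         FALSE 0.9826538
```

The instruction-relevant strategy is the most *reliable* (smallest spread);
blanket activation pays for cross-talk with occasional strongly negative
markers (large sd, heavy lower tail).

The `analysis/` directory holds the numbered drivers
(`01_synthesise_dataset.R` … `04_strategy_benchmark.R`) that run these
experiments and write their tables under `results/`.

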