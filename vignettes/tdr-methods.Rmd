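---
title: "Temporal Diffusion Ratio: model, optimisation and noise behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal Diffusion Ratio: model, optimisation and noise behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdrmri)
```

## The contrast

The Temporal Diffusion Ratio (TDR) contrasts two single-diffusion-encoding
(SDE) shells that share one large b-value but differ in gradient timing.
With rectangular pulses of duration $\delta$, separation $\Delta$ and
amplitude $G$,

$$ b = \gamma^2 G^2 \delta^2 (\Delta - \delta/3), $$

and for a shell of $N$ uniformly distributed gradient directions with
per-direction signals $S_i$ the spherical mean is $\bar S = \sum_i S_i/N$.
TDR is

$$ \mathrm{TDR} = \frac{\bar S_2 - \bar S_1}{\bar S_2}. $$

Because both shells share $b$, Gaussian (unrestricted) diffusion attenuates
them identically and contributes nothing; any non-zero TDR reflects
time-dependent — in white matter, restricted — diffusion. The statistic
requires no model fit: it is a contrast, not a size estimate, and it grows
with pore diameter over the sensitive range. At $b = 8\ \mathrm{ms/\mu m^2}$
(the package default) extra-cellular water is essentially suppressed, which
is why the signal engine models the intra-pore compartment only.

Negative values are possible in real tissue (grey matter shows them,
plausibly from inter-compartment exchange); the package returns them
unclipped.

## Units

Everything internal uses ms, µm, mT/m, ms/µm² and µm²/ms, with
$\gamma = 2.6752218744\times 10^{-4}\ \mathrm{rad\,ms^{-1}\,\mu m^{-1}\,(mT/m)^{-1}}$.
File IO converts at the boundary: FSL `.bval` files carry s/mm²
(1 ms/µm² = 1000 s/mm²) and Camino scheme files carry SI units.

## Signal engine

Restricted-diffusion attenuation in impermeable cylinders and spheres is
computed with the Gaussian phase distribution (GPD) series. For a pore of
radius $R$ transverse to a gradient $G$,

$$ -\ln S = 2\gamma^2G^2 \sum_m
   \frac{2D\alpha_m^2\delta - 2 + 2e^{-D\alpha_m^2\delta}
         + 2e^{-D\alpha_m^2\Delta} - e^{-D\alpha_m^2(\Delta-\delta)}
         - e^{-D\alpha_m^2(\Delta+\delta)}}
        {D^2\alpha_m^6\,(\beta_m^2 - c)}, $$

with $\alpha_m = \beta_m/R$, where $\beta_m$ is the $m$-th positive root of
$J_1'(x)=0$ for cylinders ($c=1$) or of $j_1'(x)=0$ for spheres ($c=2$).
Roots are found by bracketed bisection once and cached; the series is
extended in blocks of 20 terms until the last block contributes less than
$10^{-8}$ of the running sum (at least 20 roots, at most 240, else a
truncation error is raised). A cylinder at angle $\theta$ to the gradient
composes free axial diffusion with the transverse series:
$S = e^{-bD\cos^2\theta}\,S_\perp(G\sin\theta)$.

`mc_oracle()` is the package's independent check: a seeded Gaussian random
walk with radial elastic reflection inside a single disc (cylinder
cross-section) or sphere, accumulating phase under the rectangular pulse
pair. Its step length obeys $\sqrt{2D\,dt} \le d/10$ (violations raise an
error), and a step-halving study shows its estimates are converged at that
resolution.

**Where the GPD is trustworthy.** Across all twelve protocol presets the
series agrees with the walker to well under 1% wherever attenuation is
moderate — in particular everywhere the $b=8$, $G\le600$ mT/m optimisation
operates. In the deep-attenuation/localisation regime (large pores, $b=20$,
very strong gradients) the Gaussian-phase assumption itself breaks down and
the series can overestimate strongly attenuated signals by several
percentage points of signal (e.g. a 10 µm cylinder under the short-pulse
$b=20$, 2500 mT/m shell: series 0.080 vs walker ≈0.026). The test suite
documents this known limitation rather than hiding it; quantitative use of
the engine should stay out of that regime.

## Substrates and discretisation

Diameter distributions are gamma for cylinders (axon calibres; truncated at
20 µm) and normal for spheres (cell somas), discretised into 50 bin centres
on `[max(1e-3, mean − 4·sd), upper]` with weights proportional to
pdf × pore volume (d² for cylinders, d³ for spheres), normalised to one.
Volume weighting reflects that the signal of each pore scales with the spins
it holds; it is also why size grids are tail-sensitive. Doubling the bin
count moves the weighted moments by <0.5%. Gamma cells where the 20 µm
truncation shifts the number-weighted mean by more than 10% are flagged
inadmissible and excluded from size-grid maps.

The reference substrates are: large cylinders (gamma, mean 5.33, sd
3.00 µm; spinal-cord-like), small cylinders (gamma, 1.93/0.81 µm;
callosal), small spheres (normal, 7/0.5 µm) and large spheres (normal,
15/0.5 µm), all with intrinsic diffusivity 2 µm²/ms. Crossing-fibre
configurations use 1–3 mutually orthogonal bundles with equal volume
fractions (configurable).

Orientation dispersion uses the antipodally symmetric Watson density
$\propto \exp(\kappa(\mu\cdot u)^2)$. The default scheme is deterministic:
polar nodes at equal quantiles of the Watson marginal about the mean axis
crossed with uniform azimuths, all equal-weighted. A global density-weighted
grid was rejected because at high concentration the weight collapses onto
whichever few grid points sit nearest the pole, leaving a spurious fixed
tilt; the quantile quadrature resolves any $\kappa$ and converges to the
parallel-bundle limit (<1% at $\kappa = 3000$ on directions carrying
signal). Note that convergence in $\kappa$ is physically slow at high b:
a tilt spread $E[(g\cdot u)^2] \approx 1/2\kappa$ multiplies
perpendicular-direction signals by roughly $e^{-bD/2\kappa}$, which is still
≈0.92 at $\kappa = 100$, $bD = 16$ — dispersed fibres are *not* within 1% of
parallel ones at realistic concentrations. Seeded rejection sampling is
available as an alternative.

## Direction sets

HARDI direction sets are generated by minimising the antipodally
symmetrised Coulomb energy $\sum_{i<j} \|u_i-u_j\|^{-1} + \|u_i+u_j\|^{-1}$
with BFGS and an analytic gradient in spherical coordinates, from a seeded
random start. The result is deterministic given the seed and its minimum
pairwise angle comfortably beats random placement. Readers/writers cover
FSL bval/bvec and Camino STEJSKALTANNER schemes with exact unit conversion.

## Waveform optimisation

`optimise_tdr()` maximises noise-free TDR over
$(\delta_1,\Delta_1,\delta_2,\Delta_2)$ at fixed b under a constraint set
$(G_{max}, T_{max} \ge \Delta+\delta)$, with G solved per shell from b.
Since $\mathrm{TDR} = 1 - \bar S_1/\bar S_2$ and each spherical mean
depends only on its own shell's timings, the 4-D problem decouples exactly:
shell 1 minimises and shell 2 maximises the same mean-signal surface. The
implementation evaluates that surface once on an exhaustive feasible grid
(default 40×40) and polishes each shell with Nelder–Mead; an interior-point
scheme is unnecessary for a cheap smooth 2-D objective, and the exhaustive
grid removes any dependence on starting points.

Two design choices deserve note:

* **Refocusing gap.** Feasibility requires $\Delta \ge \delta + 2$ ms by
  default (`min_gap`). A spin-echo SDE sequence needs room for the 180°
  pulse between the gradient lobes, and every published shell-1 setting of
  the reference protocols shows exactly this ~2 ms margin. With a zero gap
  the short-shell optimum degenerates to $\delta = \Delta$, which no
  spin-echo implementation can play.
* **Optimum structure.** The short shell always lands on the feasibility
  corner (maximum G, minimum timings); the long shell trades duration
  against amplitude, e.g. under (600 mT/m, 45 ms) on the large-cylinder
  substrate it reaches $(\delta, \Delta) \approx (14.1, 31)$ ms. This
  matches the intuition from the long-pulse limit
  $-\ln S \propto r^4 g^2 \delta$ at fixed b: attenuation is maximised by
  short-$\delta$/high-G and minimised by long-$\delta$/low-G.

`hardware_sweep()` repeats the optimisation for four reference constraint
sets — (600, 45), (2700, 45), (300, 80) and (80, 80) in (mT/m, ms). The
achievable contrast collapses as $G_{max}$ drops: with 80 mT/m the peak
mean-signal difference on the large-cylinder substrate is only ≈0.02, of
the order of typical noise. Our GPD-based optima put the clinical and
Connectome TDR at ≈0.12 and ≈0.49; reference matrix-formalism figures for
the same settings are ≈0.106 and ≈0.44 (≈10–15% lower). The timing optima
agree to a fraction of a millisecond and the walker confirms the GPD
signals in these regimes to <3%, so we attribute the residual to
engine-formalism and optimiser-convergence differences and report our
values as computed.

## Noise model and the sorted-subset statistic

Magnitude MR noise is Rician: each signal $s$ becomes
$|s + n_1 + i n_2|$, $n_{1,2}\sim N(0, \sigma)$ with $\sigma = 1/\mathrm{SNR}$
on b0-normalised data, independently per direction and shell. Low-signal
measurements are pulled up toward the floor $\sigma\sqrt{\pi/2}$, which
inflates $\bar S_1$ relatively more than $\bar S_2$ and biases TDR low.

`tdr_subset()` mitigates this by keeping only the $M$ directions with the
highest mean signal $(S_1+S_2)/2$ (the average stabilises the ordering
under noise; ties break by direction index):

$$ \mathrm{TDR}_M = \frac{\sum_{top\,M} S_2 - \sum_{top\,M} S_1}
                        {\sum_{top\,M} S_2}. $$

Noise-free, $\mathrm{TDR}_M$ is constant in $M$; under Rician noise the
ensemble mean decreases as low-signal directions are admitted, while the
ensemble standard deviation shrinks with $M$ — an accuracy/precision
trade-off. For a single bundle at SNR 20 with the optimised preclinical
pair, the package reproduces a ≈2% depression of $\mathrm{TDR}_{12}$
against ≈25% for $\mathrm{TDR}_{60}$ (10,000 instances; the reference
ensembles at 100,000 instances report 1.6% and 24.5%).

`cov_across_configs()` asks which $M$ makes the statistic most consistent
across fibre geometries sharing one size distribution (1/2/3 orthogonal
bundles). Its default metric is the coefficient of variation of the noisy
$\mathrm{TDR}_M$ values pooled over configurations *and* noise instances:
per-estimate noise penalises small $M$, while the noise-floor depression of
the mean (and the between-configuration spread) penalises large $M$, giving
an interior minimum — stably at $M \approx 27$–28 of 60 at SNR 20 across
direction-set seeds with 10,000 instances per configuration. A
means-only CoV (between-configuration spread of ensemble means alone) is
retained as an option, but it is monotone decreasing in $M$ here because
the three ensemble means converge at large $M$; it identifies no useful
subset size.

## Simulation runners and phantom

* `run_sim1()`: one constrained optimisation plus the full
  $(\delta,\Delta)$ mean-signal map its grid explored.
* `run_sim2()`: noise-free TDR over a (mean, sd) grid of size
  distributions; defaults 0.5–10 µm × 0.1–4 µm (20×20) for gamma
  cylinders and 2–20 µm × 0.1–3 µm for normal spheres, inadmissible gamma
  cells masked. On these maps, tight small-diameter distributions (mean
  ≤ 2 µm, sd ≤ 0.5 µm) sit below the resolution limit of a 600 mT/m
  system (|TDR| < 0.02), but the volume-weighted gamma tail matters: cells
  with sd approaching 1 µm reach TDR ≈ 0.05–0.11 even at means below
  3 µm, consistent with a few-percent contrast for sub-3 µm calibre
  distributions. The "TDR ≈ 0 below mean 3 µm / sd 1 µm" shorthand holds
  only for the tight-distribution corner of that region.
* `run_sim3()`: accuracy/precision curves of $\mathrm{TDR}_M$ for the
  bundle configurations and a sphere substrate, plus the pooled CoV curve.
  Sphere substrates are direction-independent, so their curves stay flat
  in $M$ — using every direction is optimal for isotropic pores.
* `generate_phantom()` / `tdr_map()`: a labelled voxel slab with seeded
  Rician noise and the voxelwise sorted-subset map; noise-free and with
  $M = N$ it reproduces the direct per-substrate computation identically,
  which pins the pipeline to the core statistics.

## Problem sizes and reproducibility

Defaults used throughout the tests and the reproduction script: 60
repulsion directions, 50 diameter bins, 40×40 optimisation grids, 10,000
noise instances (including per configuration in the CoV sweep; the
reference ensembles used 100,000), 8,000 walkers in oracle comparisons.
Every stochastic step takes an explicit seed; results carry the inputs
needed to recompute them. The walker, not any shared code path, validates
the series engine, so the two can disagree — and where they do, the
vignette above says which to trust.

## What the synthetic results do and do not show

The generator emulates ideal geometries: impermeable, non-abutting
cylinders and spheres, no extra-cellular compartment, no exchange, no
membrane permeability, no undulation or calibre variation along fibres,
rectangular pulses (infinite slew), single-coil Rician noise. Passing
tests therefore demonstrate the statistic's behaviour under restriction
alone. Real tissue adds exchange (which can drive TDR negative, as seen in
grey matter), extra-axonal water (a few-percent depression at $b = 8$),
dispersion-related depression under noise, and multi-coil noise statistics
— none of which these tests certify. TE/TR and relaxation weighting are
assumed identical across shells and cancel in the normalisation.
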