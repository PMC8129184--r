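---
title: "Calibrating a heterogeneous Ogden-QLV brain material"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating a heterogeneous Ogden-QLV brain material}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braincalib)
```

`braincalib` implements an inverse-calibration pipeline for a heterogeneous
brain material model: magnetic resonance elastography (MRE) defines *relative*
stiffness across the brain, a quasi-linear viscoelastic (QLV) Ogden law
defines the tissue response, a CORA-style rating scores model-vs-experiment
displacement agreement, and a staged golden-section search identifies the two
free deviatoric parameters. This vignette explains the model, the tunable
parameters, the synthetic-data phantom, and the numerical and design
decisions; it states no result that the test suite and acceptance script do
not themselves compute.

## The material model

The deviatoric elastic response of each brain part is a one-term
incompressible Ogden solid,
$$W(\lambda_1,\lambda_2,\lambda_3) = \frac{\mu}{\alpha}
  \left(\lambda_1^\alpha + \lambda_2^\alpha + \lambda_3^\alpha - 3\right),$$
with shear-modulus coefficient $\mu$ (kPa) and dimensionless non-linearity
$\alpha$; $\alpha = 2$ is a Neo-Hookean solid. The infinitesimal shear
modulus — the initial slope of the shear stress–strain curve — is
$\mu_0 = \mu\alpha/2$. Closed forms used throughout
(`instantaneous_stress()`): uniaxial nominal stress
$T(\lambda) = \mu(\lambda^{\alpha-1} - \lambda^{-\alpha/2-1})$ with
$\lambda_2 = \lambda_3 = \lambda^{-1/2}$; simple-shear stress
$\tau(\gamma) = \mu(\lambda_1^{\alpha} - \lambda_1^{-\alpha})/\sqrt{\gamma^2+4}$
with $\lambda_1 = (\gamma + \sqrt{\gamma^2+4})/2$. Compression is handled on
the same uniaxial path with $\lambda = 1 - |\varepsilon|$, keeping a single
code path.

Time dependence follows Fung's QLV separation $R(\varepsilon, t) = g(t)\,
T^e(\varepsilon)$ with a four-term Prony reduced relaxation function
$$g(t) = g_\infty + \sum_{i=1}^{4} g_i e^{-t/\tau_i}, \qquad
  g_\infty + \sum_i g_i = 1 .$$
The default spectrum (`brain_prony()`) uses decade time constants
$\tau$ = 10, 1, 0.1, 0.01 ms with $g$ = 0.8619, 0.0383, 0.0412, 0.0249 and
hence $g_\infty = 0.0337$. Because tan δ = loss/storage is independent of the
absolute stiffness, the spectrum is identified from loss-tangent data alone
(`fit_prony()`): the coefficients are estimated by least squares on the true
tan δ residual under the simplex constraints ($g_i \ge 0$, normalization
exact), implemented through a softmax reparameterization and quasi-Newton
descent with a simplex polish; the time constants stay fixed on the decade
grid, which removes the non-convex $\tau$ search. Round-trip tests recover a
known spectrum to near machine precision.

**Modulus reference convention.** Textbook QLV makes $T^e$ the
*instantaneous* elastic response, but reported brain stiffnesses are usually
*quasi-static*. Material cards therefore carry a `reference` flag. Under the
default `"quasi_static"`, the relaxation function is rescaled by
$1/g_\infty$ so the long-term shear modulus equals $\mu_0$ (the
instantaneous modulus is then $\mu_0/g_\infty \approx 30\,\mu_0$); under
`"instantaneous"` the literal equation applies. Which convention an external
solver uses affects only the absolute high-rate stiffness; both are exposed
and neither is asserted as the original implementation's choice.

The hereditary integral $\sigma(t) = \int_0^t \hat g(t-s)\,\dot T^e(s)\,ds$
is evaluated with the standard recursive exponential (internal-variable)
update, which is exact for piecewise-linear $T^e$ within a step,
unconditionally stable and $O(n)$ (`qlv_stress_history()`). Single-element
virtual experiments (`single_element_curves()`) load at constant engineering
strain rate to 50% strain in tension, compression and simple shear at 0.5, 5
and 30 1/s; the integration grid resolves the ramp (≥1600 steps) rather than
the shortest Prony term, since the update is exact in the relaxation part.

## Heterogeneity from MRE

`truncate_and_normalize()` removes voxels below the 15th percentile
(approximate CSF stiffness range in template MRE maps) and above the 98th
(edge and inversion artifacts), takes the median of the retained
distribution, and divides all voxels by it. Percentiles interpolate linearly
between order statistics (the most common convention; the choice is not
dictated by the method) and the retained set is the half-open interval
(q_low, q_high]. `bin_relative_stiffness()` splits the retained normalized
range into `n_bins = 10` equal-width bins whose midpoints are the relative
stiffnesses $\gamma_i$; equal-width binning reproduces the near-uniform
≈0.111 spacing of published center lists, which equal-count binning would
not. Values on an interior edge go to the upper bin; truncated-low and
truncated-high voxels are assigned to bins 1 and 10. Centers are kept at full
precision and rounded only on export.

`build_material_cards()` turns a labelling into one card per bin via
$$\mu_i = \frac{2\,\gamma_i\,\mu_{0,\mathrm{med}}}{\alpha},$$
so part $i$'s infinitesimal modulus is exactly $\gamma_i\,
\mu_{0,\mathrm{med}}$ *for any* $\alpha$ — the α-invariance that makes the
staged calibration well-posed. With $\alpha = 2$ this reduces to the linear
ladder $\mu_i = \gamma_i \mu_\mathrm{med}$ used in stage 1.

## Objective rating

`cora_score()` rates one signal pair on [0, 1] as
$w_\mathrm{corr}\,(w_\mathrm{shape} R_\mathrm{shape} + w_\mathrm{size}
R_\mathrm{size} + w_\mathrm{phase} R_\mathrm{phase}) + w_\mathrm{corridor}
R_\mathrm{corridor}$ with, over an evaluation window from the first to the
last sample where $|y_\mathrm{ref}| \ge 0.03\,\max|y_\mathrm{ref}|$:

- $R_\mathrm{shape}$: maximum normalized cross-correlation over time shifts
  up to 12% of the window, clipped at 0 (computed by FFT with
  overlap-restricted normalization; verified against a direct-loop oracle);
- $R_\mathrm{size}$: energy ratio $\min(A)/\max(A)$, $A = \int y^2\,dt$;
- $R_\mathrm{phase}$: $1 - |\delta^*|/\delta_{max}$ for the optimal shift,
  ties resolved toward zero shift;
- $R_\mathrm{corridor}$: per-sample score, 1 inside an inner corridor of
  ±5% of the reference peak, 0 outside ±50%, quadratic in between.

The weights ($w_\mathrm{corr} = w_\mathrm{corridor} = 0.5$;
$w_\mathrm{shape} = 0.5$, $w_\mathrm{size} = w_\mathrm{phase} = 0.25$) and
corridor constants follow common rating-tool defaults; the original tool's
exact release is not pinned, so no absolute score parity with it is claimed —
tests pin *this* documented configuration (`cora_params()`), and all
constants are user-configurable. Axis scores combine into a per-receiver
composite weighted by each axis's peak reference displacement (an RMS
alternative is a flag); a zero-energy axis gets weight 0 rather than a 0/0.
Receiver composites combine into the case score
$\mathrm{wcCORA} = \sum_i \alpha_i\,\mathrm{cCORA}_i$,
$\alpha_i = \beta_i/\sum\beta_i$ with $\beta_i$ the receiver's maximum
resultant reference displacement (always recomputed, never trusted from
input). The calibration objective is the mean wcCORA across subjects.

## Two-stage search

Both stages share the machinery: evaluate the objective on a scan grid,
bracket the maximum by the two neighbours of the grid argmax (an argmax on
the boundary is an explicit error advising grid extension), then
golden-section refine with $\varphi = (\sqrt 5 - 1)/2$, shrinking the
interval by $\varphi$ per iteration with exactly one new objective
evaluation after the first iteration thanks to interior-point reuse.
Defaults (`calibration_config()`): stage-1 grid 0.25–2.6 kPa (6 points),
termination width 0.1 kPa; stage-2 grid (2, 6, 10), width 0.2. All forward
evaluations are memoised in an evaluation ledger keyed on the parameter
rounded to 1e-9, so the evaluation accounting (grid size + iterations + 1)
is exact and auditable in the returned trace. Termination is checked after
each interval update and the returned argmax is the *best evaluated point* —
every candidate already has a known objective value, so no extra simulation
is spent on the interval midpoint. Objective ties follow the $f(x_1) >
f(x_2)$ branch, deterministically. On the stage-2 interval [2, 10] with
width 0.2 this yields 8 iterations and 12 total evaluations (3 bracketing +
9 golden); on a stage-1 bracket of width 0.9 kPa with 0.1 kPa termination,
5 iterations and 12 total (6 + 6). Generic golden-section accounting
predicts $\lceil \ln(tol/W)/\ln\varphi \rceil$ iterations for any unimodal
objective, which the tests check directly.

Stage 1 (`calibrate_stage1()`) fixes $\alpha = 2$ and searches
$\mu_{0,\mathrm{med}}$ on the low-severity axial case (20 rad/s, 60 ms);
stage 2 (`calibrate_stage2()`) searches $\alpha$ on the higher-severity
coronal case (40 rad/s, 30 ms), rebuilding every card set through the
μ₀-preserving rule so the stage-1 result is never disturbed — an invariant
the tests check at every visited $\alpha$. `run_calibration()` adds the
held-out low-severity verification between the stages and a full case-matrix
verification (12 cases: 3 axes × {20, 40} rad/s × {30, 60} ms) with summary
statistics afterwards.

## The phantom: what it emulates, and what it does not

The original calibration ran subject-specific continuum finite-element
models for ~15 h per simulation. `braincalib` replaces the forward model
with a desk-scale surrogate (`phantom_config()`, `simulate_phantom()`): ~150
lumped-mass nodes on a jittered lattice inside a rigid spherical shell of
radius 70 mm, connected to neighbours and (outer layer) to shell anchors by
springs whose axial force follows the Ogden simple-shear law through the
QLV hereditary integral, with per-spring stiffness scaled by the node-pair
mean $\gamma$ drawn from a synthetic MRE volume. The shell follows the
prescribed rigid rotation exactly (half-sine angular-velocity pulses,
`make_pulse()`); interior nodes are integrated semi-implicitly (symplectic
Euler, default dt = 0.05 ms, checked against the stability bound of the
stiffest spring and smallest mass, with an explicit error naming the limit
if violated). Receiver displacements are reported in the shell-fixed frame,
like skull-fixed experimental receivers. Mass damping is small and fixed
(20 1/s); essentially all damping flows through the Prony terms so the
calibration stays sensitive to the intended parameters.

The phantom reproduces the *statistical structure* the analysis needs —
heterogeneous stiffness, rate-dependent relaxation, direction- and
severity-dependent rotational loading, receiver-level 3-axis signals — and
nothing else. It has no CSF, membranes, ventricles, contact or
subject anatomy, and no continuum accuracy. Passing recovery tests on the
phantom demonstrates that the calibration machinery is correct and
well-posed under the model class it assumes; it says nothing about how well
the calibrated values describe real tissue.

Two generator constants deserve explanation:

- **Compliance (`area_scale = 1.5`).** The effective spring cross-section
  sets how far the phantom deforms under the standard pulses. The staged
  design presumes a scale separation: the low-severity case must be
  insensitive to $\alpha$ (else stage 1 is biased by its Neo-Hookean
  constraint), while the high-severity case must deform far enough into the
  non-linear range that $\alpha$ stays identifiable above measurement noise.
  The two calibration pulses have *identical total rotation angle*
  (2·20·60/π = 2·40·30/π rad), so in the very soft, inertia-dominated
  regime both cases reach similar ~50% strains and the separation collapses;
  in a very stiff regime strains fall below ~10% everywhere and $\alpha$
  becomes invisible. The default places the phantom between these regimes
  (95th-percentile peak spring strains ≈ 10% in the 20 rad/s, 60 ms case and
  ≈ 20% in the 40 rad/s, 30 ms case), chosen once by requiring the package's
  own landscape properties — stage-1 optimum at the true modulus, stage-2
  optimum at the true $\alpha$ under 5% noise — and then frozen.
- **Sampling (0.1 ms).** Receiver histories are sampled at 0.1 ms.
  Measurement noise is modelled as independent Gaussian noise per sample and
  axis with sd a fraction of that receiver's peak resultant displacement
  (amplitude-proportional instrument noise); denser sampling therefore
  averages noise down in the correlation-based ratings, as it would for a
  real high-rate acquisition.

`make_dataset()` wraps phantom generation and simulation into an experiment
bundle (per subject × case receiver references with full provenance:
true parameters, noise level, seeds). Everything is deterministic given the
seed: a single base seed fans out arithmetically into per-subject layout
seeds, the MRE field seed and per-case noise streams, and regenerating a
bundle from its recorded provenance is bit-identical.

## Strain metrics

`strain_from_displacement()` computes the displacement gradient on the voxel
grid by central differences (one-sided at mask edges; voxels with no
neighbour along some axis are excluded from the metrics), forms
$F = I + \nabla u$ and the Green–Lagrange tensor $E = (F^\top F - I)/2$, and
takes the largest eigenvalue per voxel as the maximum principal strain (MPS)
via a vectorized closed-form symmetric 3×3 eigensolver, verified against
`eigen()` per voxel. Green–Lagrange is the standard choice in the
tagged-MRI brain-strain literature, but the definition is not universal, so
principal stretch − 1 is available behind a flag (the two differ only at
large strain). Rigid motions are exactly strain-free under this definition,
which the tests exploit. `mps95()` uses the same linear-interpolation
percentile convention as the binning; `exceedance_fraction()` defaults to
the 2% strain threshold; `regional_summary()` reports both per region plus
globally.

## Problem sizes and runtimes

The testing and acceptance workloads were sized to run interactively: unit
tests use ~40-node phantoms with 120 ms records (a forward simulation takes
~0.1 s), while the parameter-recovery acceptance check uses the default
3-subject, 150-node phantom with 200 ms records (~0.3 s per simulation,
~50 s per full two-stage calibration, ~12 objective evaluations per stage,
and six independent calibrations: one noise-free plus five noisy seeds).
The synthetic MRE default is a 64³ voxel volume (<1 s to generate).

## Known limitations

- The phantom is a surrogate; no claim of continuum accuracy or anatomical
  realism is made, and calibrated-parameter agreement with cadaveric or
  in vivo datasets cannot be assessed at desk scale.
- The CORA configuration is a documented, self-consistent default, not a
  certified reproduction of any particular rating-tool release.
- The Prony fit fixes the time constants on a decade grid; spectra whose
  true time constants fall far from the grid are represented only in a
  least-squares sense.
- Registration of stiffness maps into model space is out of scope: the
  binning assumes stiffness and label grids already share a common space.
- The two-stage design deliberately avoids joint (μ₀, α) optimization; if
  the low-severity response were strongly non-linear, the stage-1 estimate
  would be biased (the generator's defaults were chosen so this premise
  holds on the phantom, mirroring the assumption the staged design makes
  about the real system).
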