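---
title: "Modelling therapeutic neural stem cell migration in anisotropic brain tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling therapeutic neural stem cell migration in anisotropic brain tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nscmigrate)
```

## The model

Therapeutic neural stem cells (NSCs) injected into the brain migrate
preferentially along white-matter tracts and home toward tumors along
chemokine gradients (notably urokinase plasminogen activator, uPA, which is
elevated in glioma). `nscmigrate` implements an agent-based model of this
process with three ingredients.

**Tissue anisotropy.** Local tissue orientation is obtained from the
structure tensor of a scalar image volume $I(\mathbf{x})$: the
Gaussian-smoothed outer product of spatial intensity gradients, with
eigenvalues $\lambda_1 \ge \lambda_2 (\ge \lambda_3) \ge 0$ and principal
eigenvector $\mathbf{e}_1$. Anisotropy is summarised by the coherence
$M_{coh} = ((\lambda_1-\lambda_2)/(\lambda_1+\lambda_2))^2$ in 2-D and by
fractional anisotropy in 3-D. A voxel with $M_{coh} \ge \epsilon_M$
(default 0.4) is classified as white matter; the normalised $\mathbf{e}_1$
is the local fiber direction $\mathbf{M}_{ev}$. A precomputed per-voxel
tensor field (e.g. diffusion tensors from DTI) can be supplied instead via
`tensor_field()`.

**Migration rule.** At every time step $\Delta t$ (default $1/1000$ day)
each cell moves

$$\mathbf{v} = \begin{cases}
  \pm\, d_w \psi_i\, \mathbf{M}_{ev}(\mathbf{x}), & M_{coh}(\mathbf{x}) \ge \epsilon_M\\
  d_g\, \boldsymbol{\xi}, & \text{otherwise,}
\end{cases}$$

where $\boldsymbol{\xi}$ is uniform on the unit circle/sphere and the sign
on white matter is chosen consistently with the previous displacement
(inertia): the sign of
$(\mathbf{x}_i - \mathbf{x}_{i-1})\cdot\mathbf{M}_{ev}$, with an exactly
zero inner product — including the first step — resolved by a fair coin.
Wherever the uPA concentration exceeds a detection threshold,
$C(\mathbf{x}) \ge \epsilon_c$, the chemotaxis term
$\lambda_c \eta_i \nabla C(\mathbf{x})$ is added to either case.

**Population stochasticity.** Each cell carries two fixed traits drawn at
injection: a speed factor $\psi_i \sim B[1, \beta_w]$, rescaled by
$(1+\beta_w)/2$ so the population mean is $1/2$ for every $\beta_w$
(at $\beta_w = 1$ speeds are exactly uniform on $[0, d_w]$; larger
$\beta_w$ lowers the median while the rescaling creates fast outliers), and
a chemosensitivity factor $\eta_i \sim B[\alpha_c, 1]$ (uniform at
$\alpha_c = 1$, concentrating at 1 — effectively deterministic — as
$\alpha_c$ grows).

The uPA field of a tumor centred at $\mathbf{x}_c$ is the static analytic
profile

$$C(\mathbf{x}) = \Big(1 + \tfrac{(x-x_c)^2}{\sigma_x^2}
 + \tfrac{(y-y_c)^2}{\sigma_y^2} + \tfrac{(z-z_c)^2}{\sigma_z^2}\Big)^{-p},$$

so $C = 1$ at the centre; time independence reflects the separation between
uPA diffusion and cell migration time scales. At $p = 1$, $\sigma$ is the
per-axis distance at which the concentration halves; for $p \ne 1$ the
halving gloss does not hold and the formula is taken as the definition.
Multiple tumors contribute additively (physically additive secretion; a
`max` combination is available). Arrival is counted on first entry into the
tumor region — an axis-aligned box of half-widths 100 × 100 × 400 µm
(the 200 × 200 × 800 µm tumor) in 3-D, a disc of 100 µm radius in 2-D —
and arrived cells halt there by default.

## Parameters and units

All step-size parameters are in **pixels per time step**; published values
convert to µm/day by multiplying with $X/T$, where $X$ is the pixel size
(1.444 µm for the 2-D atlas, 13.5 µm for the 3-D atlas, 10 µm for the
packaged 2-D phantoms) and $T = \Delta t$. Defaults are the midpoints of the
published ranges:

| parameter | meaning | range | default |
|---|---|---|---|
| `d_w` | max white-matter step (px/step) | [0.5, 5] | 2.75 |
| `d_g` | grey-matter step (px/step) | [0.1, 5] | 2.55 |
| `lambda_c` | chemosensitivity (px/step) | [3, 10] | 6.5 |
| `beta_w` | speed-trait shape | [1, 4] | 2.5 |
| `alpha_c` | sensitivity-trait shape | [1, 5] | 3 |
| `epsilon_M` | white-matter threshold | — | 0.4 |
| `epsilon_c` | uPA detection threshold | — | 0.05 |

$\epsilon_c$, $\sigma$ (default twice the tumor extent) and $p$ (default 1)
are not published; they are exposed in the configuration and were fixed once
at these values for the packaged scenarios. The packaged scenarios use
$d_w = 5$, $d_g = 0.5$, $\lambda_c = 6$ (the values featured in the 2-D
parameter study) with $\beta_w = \alpha_c = 1$, the uniform-trait baseline.

## Numerical choices

- Coordinates: voxel centres sit at integer coordinates $1..n$ (R's array
  convention); agent positions are continuous in pixel units and converted
  to µm only at reporting time.
- Field lookup at agent positions is nearest-voxel, with half-up rounding
  (`floor(x + 0.5)`) so the rule is deterministic and direction-free;
  interpolating a mask is ill-defined. Sign-aligned linear interpolation of
  the direction field is available as an option.
- Gradients are central differences with replicated edges; tensor
  components are smoothed with a separable Gaussian (default
  $\sigma = 2$ px; $\sigma = 0$ disables smoothing).
- Per-voxel eigen-systems use closed forms (quadratic in 2-D, the
  trigonometric solution in 3-D) vectorised over the volume; degenerate
  voxels ($\lambda_1 \approx \lambda_2$) receive an arbitrary unit
  direction — their coherence is (near) zero, so the direction is never
  used. Eigenvalues match a generic symmetric solver to better than
  $10^{-8}$ in the tests.
- A proposed step that leaves the brain mask is rejected: grey-matter steps
  redraw their direction up to 10 times, white-matter steps flip sign once,
  and a cell whose retries are exhausted stays in place for that step.
- All randomness flows through R's RNG seeded once per run from the
  configuration, with a fixed agent update order, so identical
  (configuration, seed) pairs give bit-identical records. Trajectory CSVs
  print coordinates with 17 significant digits so a saved record reproduces
  the run's metrics byte-exactly.

## Synthetic phantoms

The published study runs on mouse DTI atlases that are not redistributable;
the `phantoms` module generates scalar-image stand-ins whose
structure-tensor analysis has the same essential structure: a connected
high-anisotropy tract embedded in low-anisotropy tissue inside an elliptical
brain mask. Tracts are tubes carrying fine sinusoidal intensity banding
*along* the tract axis, so the gradient outer-products orient
$\mathbf{e}_1$ parallel to the tract. Several details follow from the fact
that coherence is amplitude-invariant:

- profiles and tapers are truncated to reach exactly zero (an untruncated
  Gaussian tail, however faint, classifies as white matter);
- a weak background texture (intensity noise, sd 0.02) is added so that
  smoothing leakage around structures is dominated by isotropic texture, as
  in any real image — `uniform_grey` phantoms omit it and have exactly zero
  anisotropy;
- grey gaps interrupting the tract (default every 60 px, 18 px wide,
  emulating tracts passing through grey structures) must be wider than the
  smoothing kernel or coherent signal smears across them.

Straight tracts span the whole mask, so tract-following agents reflect off
the brain boundary rather than spilling out of free tract ends. A
direct-tensor phantom (`make_tensor_phantom()`) exercises the
precomputed-tensor path end to end.

`make_scenario()` packages four reproducible cases on the straight-tract
phantom (320 × 224 px, 10 µm/px in 2-D; 96 × 72 × 48 px, 13.5 µm/px in
3-D): a tumor just off the tract near the injection (`near_tumor`), a tumor
off-tract far from the injection (`far_tumor`), two tumors on opposite
sides (`bilateral_tumors`), and a tumor-free control — with `"on_tract"`
(intracerebral analogue) and `"off_tract"` (intranasal analogue) injection
presets.

What the phantoms do *not* emulate: real mouse neuroanatomy, branching
tract networks, partial-volume effects, or the rich ragged texture of real
anisotropy maps. Passing tests on phantoms therefore validate the
mechanics of the simulator and the qualitative responses of the model, not
anatomy-specific arrival percentages: the published figures (~90%
intracerebral vs ~14% intranasal arrival, etc.) depend on the atlas
geometry and are out of scope here.

## A structural limitation of the phantom analogue

On the real atlases, slowing grey-matter migration ($d_g = 0.5$ vs
$d_g = d_w = 5$) visibly keeps cells on and around the tracts. On the
phantoms, the *confinement* half of that contrast reproduces robustly: the
median displacement from the injection site is about half as large at
$d_g = 0.5$. The *occupancy* half — a higher percentage of cells sitting on
white-matter voxels — does not reproduce, and the reason is structural
rather than a tuning issue. Under the strict update rule, every process
that removes a cell from white matter scales with $d_w$ (or the optional
white-matter noise term), identically in both settings, while every return
process — crossing a grey gap, re-attaching from the halo around a tract,
and the depth (hence retention) of re-entry — scales with the grey step.
Measured white-matter occupancy was monotone non-decreasing in $d_g$ in
every phantom geometry we examined (solid, gapped, thin and thick tracts,
tract bundles, speckled and coherent white-matter pockets, with and without
the noise term). The corresponding acceptance test asserts the occupancy
contrast anyway and is expected to fail on phantoms; the displacement
contrast passes.

## The optional white-matter noise term

The update rule admits a perturbed variant
$\mathbf{v} = \pm d_w \mathbf{M}_{ev} + \epsilon$. It is implemented as an
isotropic Gaussian perturbation (`wm_noise_sd`, pixels) and is **off by
default**: the strict rule is the featured model, and the perturbation
changes the character of tract-following (cells drift off tracts laterally
at a rate set by the noise).

## Problem sizes

The packaged tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes: 2-D grids of 320 × 224 px, populations
of 1,000 cells (10,000 for the random-walk law), horizons of 1.5–3
simulated days (1,500–3,000 steps) for scenario contrasts and 10 days for
the bilateral case, and 3–10 seeds per condition. The model's defaults
(1,000 cells, 30 days) remain those of the published protocol; arrival
percentages are cumulative, so results at a shorter horizon are lower
bounds on the 30-day values.

## Known limitations

- All cells survive: no death, proliferation, or the 10–20% post-injection
  survival fraction, so arrival percentages overestimate cell numbers.
- The chemoattractant field is static and analytic; no production–diffusion
  dynamics, no receptor saturation, no tumor growth.
- No cell–cell interaction, contact inhibition, or leader/follower
  behaviour.
- The chemotaxis gate compares the raw concentration with $\epsilon_c$; the
  per-cell factor $\eta_i$ scales the response but not the gate.
- NPZ archives are not supported as inputs; precomputed tensors are
  accepted as in-memory arrays (see `tensor_field()`).
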