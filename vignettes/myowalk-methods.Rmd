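---
title: "myowalk: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{myowalk: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of what it simulates, which knobs
matter, and where numerical or modelling choices were genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. What is being modelled

A DT-CMR voxel (default 2800 x 2800 x 8000 µm³) contains on the order of
10⁵ cardiomyocytes. The package represents that tissue as a periodic tiling
of one block of extruded cell cross-sections, walks water molecules through
it during a diffusion-encoding sequence, adds the signal of blood spins
advected through an anisotropic capillary network, and fits the
mono-exponential tensor a scanner would fit. Everything is normalized:
relaxation, noise, imaging gradients and readout are out of scope, so
`S/S0 = 1` at `b = 0` by construction.

### Units

Lengths in µm, times in ms, gradients in mT/m, diffusivities in µm²/ms
(1 µm²/ms = 10⁻³ mm²/s), speeds in mm/s (numerically equal to µm/ms).
The gyromagnetic ratio 2.675x10⁸ rad s⁻¹ T⁻¹ becomes
`GAMMA_EFF = 2.675e-4 rad ms⁻¹ µm⁻¹ (mT/m)⁻¹`, so b-values come out in
ms µm⁻² directly (0.6 ms µm⁻² = 600 s/mm²).

## 2. The synthetic substrate

`generate_cross_sections()` builds convex polygonal cell cross-sections as
the Voronoi diagram of a jittered hexagonal lattice, clipped to the
bounding box and inset so the gaps form a connected extracellular space.
This emulates the salient features of a segmented histology region —
densely packed, convex-ish, size-jittered cross-sections at a controllable
ECV — and supports exact, overlap-free morphing: because each cell is the
intersection of half-planes, a uniform offset of those half-planes
(`morph_ecv()`, binary search to |ECV − target| < 10⁻³) can shrink or grow
every cell without ever creating overlaps, covering the protocol range
18.8–41.8%.

What it does **not** emulate: concave or branching cell outlines, spatially
correlated cell-size gradients, sheetlet laminae (shear layers of cells),
curved or tapering cells, and any realistic inter-block spacing. A green
trend test therefore establishes that the *mechanisms* (restriction,
exchange, end-cap blocking, perfusion mixing) move the tensor in the
reported directions — not that absolute tensor values match a particular
histology sample, which would require the original segmented contours.

The block (default 127 µm extrusion, matching the order of cardiomyocyte
lengths) is tiled periodically; each block row along the radial direction Y
is rigidly rotated about Y by `ha_rate x Ly` (10°/mm default) so the local
cell long axis precesses like the transmural helix angle, and alternate
block columns are shifted half a block in Z to break up straight
extracellular channels. The rotation is piecewise constant per block row —
the tiling stays exact within a row and the geometric mismatch at row
boundaries is accepted, as it is in histology-based phantoms of this
construction. Cell end caps (and the side-wall band within `icd_depth =
2 µm` of a cap) form the intercalated-disk region with its own
permeability.

Boundary conventions: a point exactly on a membrane belongs to the
extracellular space; segment-membrane intersections use a half-open
parametric interval `(0, 1]` so a step that starts on a membrane does not
immediately re-hit it.

## 3. Sequences

`make_waveform()` returns the *effective* gradient: refocusing pulses are
folded into the sign of G(t), so the phase is the single integral
`γ ∫ X·G dt` and `∫G dt = 0` at echo.

* STEAM and PGSE: two matched trapezoidal lobes (flat-top `delta`, ramps
  `epsilon`) separated by `Delta`, the second negated.
* MCSE: four trapezoidal lobes with effective signs `+,−,+,−`. Nulling
  m0, m1 and m2 requires at least three sign changes (a function orthogonal
  to all quadratics must change sign three times), which is why the
  `+,−,−,+` pattern cannot work. The four flat-tops are solved by Newton
  iteration on exact piecewise moments; at the default `T_enc = 70 ms`,
  `epsilon = 1 ms`, `t_rf = 6 ms` the solution is an odd-symmetric train
  with unequal pair durations (about 8.5 and 19.5 ms).

Default timings are representative clinical values — PGSE
`delta = 20, epsilon = 1, Delta = 30 ms`; STEAM `delta = 6, epsilon = 1,
Delta = 1000 ms` (mixing of order one cardiac cycle); MCSE `T_enc = 70 ms` —
and every timing is overridable through `sequence_spec()`, because
published protocols differ and the perfusion signal is sensitive to them:
for a near-constant capillary speed the phase dispersion scales like
`sqrt(b·Delta)·σ_v`, so a protocol with shorter `Delta` retains more
perfusion signal at the same b-value. Quantitative comparisons against a
specific protocol should drop in that protocol's timing table.

b-values are computed exactly for piecewise-linear G (Gauss–Legendre per
piece on the quartic `q²`), and `solve_gmax()` uses `b ∝ Gmax²`, so the two
amplitudes per sequence (reference `b = 0.15`, main `b = 0.6 ms µm⁻²`)
round-trip to machine precision.

## 4. The random walk

Each step moves `±sqrt(2 D δt)` per Cartesian component. Membrane
interactions are resolved by substeps (budget `max_substeps = 100`; an
exhausted budget is counted and reported, not silently ignored): the
earliest membrane crossing is found analytically in the block-local frame,
a uniform draw decides transit versus specular reflection, and on transit
the remaining path is rescaled by `sqrt(D_to/D_from)`.

The transit model treats the permeability barrier and the diffusivity step
as successive barriers: `p_b = 2κδx/(D_ICS + 2κδx)` with `δx` the walker's
start distance projected on the membrane normal (clamped at 10⁻⁶ µm so a
walker sitting on the membrane keeps a finite probability), and a factor
`p_d = (D_ICS/D_ECS)^p` on extracellular-to-intracellular transits. The
exponent was genuinely open: with `p_b` written with `D_ICS` on both sides
(as above), flux balance at equal concentration — hit rate ∝ sqrt(D) and
mean `δx` ∝ sqrt(D) give a per-step crossing flux ∝ `κ·D_side/D_ICS·p_d` —
requires the **plain ratio** `p = 1`, and the package's equilibrium test
(compartment occupancy stationary over 600 steps at κ = 0.02) confirms
that `p = 0.5` drifts walkers into the cells while `p = 1` conserves
occupancy. The default is therefore `p = 1`, with
`walk_config(pd_exponent = 0.5)` available for comparison with square-root
interface conventions.

Phase is accumulated per step as `φ += a_k (X_mid·e_g) δt` where `a_k` is
γ times the *exact mean* of G over the step, so a stationary walker
dephases exactly zero. Because the gradient direction and amplitude factor
out of the phase integral, each walker carries a 3-vector `Ψ = Σ a_k X_mid
δt` from which every (direction, b) measurement of a scheme is evaluated
after the walk — one walk serves all 12 measurements. The measurements of
one walk share Monte Carlo noise across directions; the replicate protocol
(6 independent walks in the full-scale configuration) is what provides
independent error bars, exactly as in the published protocol.

Randomness: every walker owns a counter-seeded xoshiro256++ stream derived
from `(seed, walker id)`, so results are independent of execution order and
bit-reproducible.

Walkers seed uniformly over the voxel plus a buffer of width
`4·sqrt(2 D_ECS T)` (≈ 4 free-diffusion standard deviations of the longest
sequence; the protocol source does not state a width) and the signal sums
walkers inside the voxel at echo time.

## 5. Perfusion

Spins seed on the voxel plane z = 0, draw one truncated-Gaussian speed, and
traverse Watson-oriented, Weibull-length segments. The local frame of a
spin is fixed by its seed depth (`θ = ha_rate·y`); paths of a few hundred
µm would rotate it by well under a degree, so following the instantaneous
depth was not worth the cost. Negative speeds (allowed by the −0.1 mm/s
truncation) traverse the same segment sequence backwards. The per-segment
phase uses the exact running integral `M(s) = ∫m0` of the normalized
profile (piecewise cubic), so the only Monte Carlo error in the perfusion
signal is sampling of orientations, lengths and speeds — there is no
quadrature error. Zenith sampling is by rejection: a uniform proposal on
`cos θ` for K ≤ 1, a truncated-exponential proposal near the axis for
K > 1 (acceptance stays O(1) up to K ≫ 50).

The reported "along E1" direction is the cardiomyocyte long axis at the
voxel centre; the diffusion-tensor E1 aligns with it by construction of the
substrate. MCSE nulls the phase of any constant-velocity straight path to
machine precision (its first moment vanishes); residual MCSE perfusion
attenuation comes only from direction changes between segments and
therefore grows with the distance `v·T` travelled during encoding.

## 6. Tensor fitting

Log-linear least squares on `ln S = −b e'De`. With `b_ref > 0` the default
"ratio" fit regresses the per-direction difference
`ln S(b) − ln S(b_ref)` on `(b − b_ref)`, which cancels any signal
component common to both b-values — this is the mechanism by which a
reference b-value suppresses perfusion; a joint 12-point fit with a common
intercept is available (`method = "joint"`) and agrees on noiseless data.
Eigenvalues are ordered descending; E1's sign is fixed against the mean
long axis, E2/E3 by their largest component. The eigenvector cone of
uncertainty across replicates is the 95th percentile of angular deviations
from the principal axis of the mean dyadic tensor (sign-invariant).

## 7. Parameter summary

| Parameter | Default | Units | Note |
|---|---|---|---|
| `D_ICS`, `D_ECS` | 1, 2.5 | µm²/ms | protocol constants |
| `kappa_sarco` | 0–0.05 | µm/ms | physiological exchange range |
| `kappa_icd` | 0.005 | µm/ms | reduced end-cap permeability |
| `icd_depth` | 2 | µm | end-cap band |
| `ha_rate` | 10 | °/mm | transmural helix rotation |
| ECV targets | 0.188 / 0.2469 / 0.418 | – | morphing range |
| `Np`, `Nt` | 10⁵, 10⁴ | – | full scale; tests scale down |
| `K` | 3.25 | – | capillary Watson concentration |
| `mu_L`, `sigma_L` | 60, 40 | µm | Weibull segment lengths |
| `v_bar`, truncation | 0.5, [−0.1, 1] | mm/s | capillary speeds |
| `sigma_v` | 0.001–0.15 | mm/s | velocity dispersion sweep |
| `f` | 0.10 | – | perfusion fraction |
| `b`, `b_ref` | 0.6, 0.15 or 0 | ms/µm² | encoding scheme |

## 8. Known limitations

* Absolute tensor values depend on the cross-section geometry; the
  synthetic packing reproduces mechanisms and trends, not a specific
  histology sample.
* Sequence timings are representative, not protocol-exact; perfusion
  signal magnitudes at fixed b are timing-sensitive (section 3).
* Perfusion spins do not interact with the cell geometry and carry no
  intracapillary velocity profile; MCSE's insensitivity to perfusion is
  exact only for constant-velocity straight paths.
* No relaxation weighting, no noise floor, no Rician bias — fits are on
  noiseless normalized magnitudes.
* The walk uses a fixed per-component step; near-membrane accuracy is
  first-order in `sqrt(δt)`, which is why `Nt` defaults high.
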