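# myowalk

Monte Carlo simulation of diffusion tensor cardiovascular magnetic resonance
(DT-CMR) in a virtual myocardium, with permeable cell membranes and
microvascular perfusion.

## The problem

DT-CMR measures the self-diffusion of water in the beating heart and reports
it as a 3x3 tensor per voxel: the mean diffusivity (MD), fractional
anisotropy (FA), eigenvalues λ1 ≥ λ2 ≥ λ3 and eigenvectors E1–E3. The link
between those numbers and the underlying microstructure — cardiomyocyte
packing, extracellular volume fraction (ECV), sarcolemma and
intercalated-disk (ICD) permeability, capillary flow — is not directly
observable. This package closes that gap by simulation: it builds a periodic,
helix-angle-rotated virtual tissue, walks water molecules through it under
clinical diffusion-encoding sequences, adds the phase carried by blood
perfusing an anisotropic capillary network, and fits the same tensor model a
scanner would fit. It is written for researchers who want to ask "if the
microstructure changed like *this*, what would the measured tensor do?"

## The model

**Diffusion.** Walkers take fixed steps `X(t+δt) = X(t) + sqrt(2 D δt) R`,
with `R ∈ {−1, +1}³` and `D` the local diffusivity (`D_ICS = 1`,
`D_ECS = 2.5` µm²/ms). At a membrane a walker crosses with the hybrid
transit probability

    p(ICS→ECS) = p_b,   p(ECS→ICS) = p_b · p_d,
    p_b = 2 κ δx / (D_ICS + 2 κ δx),   p_d = D_ICS / D_ECS,

where `κ` is the permeability of the membrane hit (sarcolemma or ICD) and
`δx` the walker's starting distance from the wall projected on its normal;
otherwise it reflects specularly. Each walker accrues the phase
`φ = γ ∫ X(t)·G(t) dt` under the effective gradient `G(t)` of a STEAM, PGSE
or second-order motion-compensated spin-echo (MCSE) sequence, and the voxel
signal is `S/S0 = |Σ exp(−jφ)| / N`.

**Perfusion.** Spins travel at constant per-spin speed (Gaussian
`v̄ = 0.5 mm/s`, SD `σ_v`, truncated to [−0.1, 1] mm/s) along piecewise
straight capillary paths whose zenith angles follow a hemispherical
Dimroth–Watson axial distribution `p(θ) ∝ sin θ exp(2K cos²θ)` about the
local cell long axis (default `K = 3.25`) and whose lengths are Weibull with
mean 60 µm and SD 40 µm. The per-spin phase reduces to an exact sum over
segments of the integrated normalized gradient moment — no time stepping.

**Mixing and fitting.** `S = f·S_perf + (1−f)·S_diff` with perfusion
fraction `f` (default 10%), then a log-linear tensor fit
`S/S0 = exp(−b e'De)` on six dual-gradient directions at `b = 0.6 ms/µm²`,
using either `b_ref = 0` or a per-direction reference at
`b_ref = 0.15 ms/µm²` that cancels signal components shared by both
b-values (this is how a higher reference b-value suppresses perfusion).

## Worked example

Healthy-ECV substrate, permeable membranes, STEAM encoding, 10% perfusion
with wide velocity dispersion, tensor fitted with a 0.15 ms/µm² reference:

```r
library(myowalk)

cs  <- morph_ecv(generate_cross_sections(100, mean_diameter = 18, seed = 2), 0.2469)
sub <- build_substrate(tissue_block(cs, Lz = 127, icd_depth = 2))
cfg <- walk_config(Np = 1e4, Nt = 1e3, kappa_sarco = 0.03, seed = 1)

sig  <- run_diffusion(sub, sequence_spec("STEAM"), cfg)
perf <- run_perfusion(perfusion_config(sigma_v = 0.15, Np_perf = 2e4, seed = 1),
                      sequence_spec("STEAM"), b = c(0.15, 0.6),
                      directions = encoding_scheme()$directions)
fit  <- fit_tensor(combine_signals(sig, dplyr::mutate(perf, sequence = "STEAM"),
                                   f = 0.10), bref = 0.15)
fit
#> <tensor_fit> b 0.60 / bref 0.15 (ratio fit)
#>   MD 0.8563 um^2/ms, FA 0.4545, lambda (1.3382, 0.6537, 0.5769)
```

λ1 points along the mean cardiomyocyte long axis; the restricted transverse
eigenvalues and FA ≈ 0.45 reflect the 24.7% ECV packing with
`κ_sarco = 0.03` µm/ms, and the perfusion contribution at this velocity
dispersion inflates MD relative to the diffusion-only fit — the behaviour
that makes STEAM MD sensitive to microcirculation. `glance(fit)` returns the
same numbers as a one-row tibble, `tidy(fit)` the six tensor components,
`autoplot(fit)` the eigenvalue spectrum.

A scripted front end with the same stages is installed at
`inst/cli/myowalk` (subcommands `substrate`, `diffuse`, `perfuse`, `fit`,
`run`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

rebuilds the substrate from scratch, runs replicate diffusion walks for all
three sequences, runs the perfusion model, mixes and fits the tensors, logs
the replicate-mean tensor metrics to stderr, and writes the JSON report to
`--out`. All randomness derives from `--seed`.

## Vignette

`vignettes/myowalk-methods.Rmd` documents the model assumptions, the unit
system, every tunable parameter with its default and provenance, what the
synthetic substrate does and does not emulate, and the numerical choices
(exact piecewise gradient integrals, membrane substepping, moment-nulled
MCSE construction, detailed-balance considerations for the transit model).
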