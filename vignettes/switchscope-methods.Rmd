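---
title: "Models and methods in switchscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in switchscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchscope)
```

switchscope implements the quantitative analyses used to characterize
disease-associated Gα variants by their nucleotide-state phenotypes: thermal
melt fitting and classification, exchange-kinetics fitting, STD-NMR
amplification-factor fingerprinting, and trajectory-based structural
read-outs. This vignette documents the models, the parameters that matter,
the numerical choices, and the limits of what the synthetic fixtures can
establish.

## Thermal melts

A single-wavelength CD melt (ellipticity at 220 nm, 25–89 °C at 1 °C/min) is
fit to the Boltzmann sigmoid

$$Y = \mathrm{Bottom} + \frac{\mathrm{Top} - \mathrm{Bottom}}
        {1 + e^{(V_{50} - X)/\mathrm{Slope}}}$$

where $V_{50}$ (°C) is the melting temperature $T_m$ — the temperature of
half-unfolding — and Slope (°C) sets the transition steepness. The model
assumes a two-state, reversible unfolding with flat pre- and post-transition
baselines; sloped-baseline models are deliberately out of scope.

Numerical choices:

* **Initialization is deterministic** — $V_{50}$ at the half-amplitude
  crossing of the data, Slope at one tenth of the temperature range — so a
  fit never depends on RNG state.
* The primary solver is `nls` (port algorithm, $V_{50}$ box-bounded to the
  data range); on solver failure (including its spurious "singular
  convergence" on zero-residual data) a Nelder–Mead fallback takes over.
  Either path is finished by a quasi-Newton polish (`optim` BFGS,
  relative tolerance $10^{-15}$), which is what makes noise-free parameter
  recovery hold to at least six significant figures.
* **Honest convergence**: a fitted $V_{50}$ outside the observed temperature
  range, or a non-positive slope/amplitude (a melt must run
  folded → unfolded, i.e. the oriented signal increases), flags the fit
  `converged = FALSE` instead of silently extrapolating.
* **Degenerate inputs**: fewer than 10 points is an input error; an amplitude
  below 5× the noise MAD (robustly estimated from first differences) is a
  "no transition" error rather than a garbage fit.
* By default Top and Bottom are free parameters and $T_m$ is invariant under
  affine rescaling of the signal; `fix_normalization = TRUE` fixes them at
  1/0 for data already normalized to folded fraction. Both conventions occur
  in practice and the choice is surfaced rather than guessed.

Triplicates are summarized as mean and sample (n−1) standard deviation of
$V_{50}$ over converged fits. Classification of a variant × nucleotide pair
follows the reference logic: $\Delta T_m = T_m^{GTP} - T_m^{GDP}$ above a
threshold is `nucleotide_responsive`; otherwise the variant is `gdp_like` or
`gtp_like` by the nearer wild-type reference, and `indeterminate` within the
threshold of both or exactly equidistant. The default threshold,
$\max(3\,°C,\ 2\times\text{pooled sd})$, is a package choice: the underlying
comparison is conventionally made visually against wild-type reference lines
and no numeric rule is standard, so the default encodes "clearly larger than
replicate scatter, and at least a third of the wild-type gap". Apo (no
nucleotide) samples carry no $\Delta T_m$ and are compared against the
references only.

## Exchange kinetics

Tryptophan-fluorescence traces after GTP-analog addition follow the one-phase
association

$$Y = Y_0 + (\mathrm{Plateau} - Y_0)\,(1 - e^{-kx})$$

with $k$ in reciprocal time-axis units and $t_{1/2} = \ln 2 / k$. Decreasing
traces (Plateau < $Y_0$; some loss-of-function variants quench rather than
gain fluorescence) are supported — the amplitude goes negative while $k$
stays positive. Initialization mirrors the melt fitter (first point,
tail-5% mean, $\ln 2 /$ half-amplitude time). No dead-time correction is
applied: mixing precedes acquisition and the first recorded point defines
$x = 0$, matching the definition of $Y_0$. Flat traces error out as
"no signal"; a non-positive fitted $k$ is reported non-converged.

## STD-NMR fingerprints

Peak integrals from the reference ($I_0$) and saturated ($I_{sat}$) spectra
give per-proton amplification factors

$$A_{STD} = \frac{I_0 - I_{sat}}{I_0}\cdot\frac{[L]}{[P]}, \qquad
  \sigma = \frac{A_{STD}}{SNR_{diff}}$$

at the conventional 50-fold ligand excess (2 mM ligand, 40 µM protein).
Inputs are assumed background-corrected integrals; spectral processing is out
of scope. $I_{sat} > I_0$ (a subtraction artifact) yields a negative
$A_{STD}$ preserved with a warning, never clipped.

The fingerprint normalizes each proton to the reference proton (default
`'a'`, whose local environment is the least perturbed across variants), with
ratio errors propagated in quadrature of relative errors,
$\sigma_r = r\sqrt{(\sigma_p/A_p)^2 + (\sigma_{ref}/A_{ref})^2}$ — whether
published error bars on such normalized values are propagated this way or
taken from the ratio's own SNR is generally unstated, and quadrature is this
package's documented choice. Bins follow the conventional color map
(<50% weak, 50–99% weak-moderate, 101–150% moderate, >150% strong); since
that scheme leaves exactly-100% and the boundary percents unassigned, the
implementation uses half-open intervals plus a configurable ±2%
"reference-equivalent" band around 1.0. Background-overlapped protons enter
with `usable = FALSE` and are reported `excluded` with no bin. The
saturation-time helper picks the smallest time within 5% (configurable) of
the maximum build-up signal.

## Trajectory read-outs

**Hydrogen bonds.** Geometric criterion on explicit-hydrogen coordinates:
H···A < 2.4 Å and D–H···A > 120°. The cutoffs describe only geometry, so atom
typing is a package decision: donors are N/O/S with a covalently attached
hydrogen (bond list if present, else nearest within 1.2 Å), acceptors are any
N/O (which covers backbone carbonyls, side-chain carboxylates and the
nucleotide's phosphate oxygens) excluding the donor itself and atoms bonded
to the hydrogen. The 2.4 Å magnitude identifies the distance as H···A rather
than heavy-atom donor–acceptor. Occupancy matrices count, per inter-region
residue pair, the fraction of frames with ≥1 qualifying bond in either
direction; intra-region pairs are excluded. Persistence masks apply ordered
occupancy thresholds — the default set {0.1, 0.25, 0.5, 0.75} is a
documented configuration guess, since published intensity levels rarely state
their cutoffs — and are monotone in the threshold by construction.

**RMSF.** Per atom,
$\mathrm{RMSF}_i = \sqrt{\langle\|x_i(t) - \langle x_i\rangle\|^2\rangle_t}$,
averaged over selected backbone atoms per residue. Superposition is **off by
default**: restrained spherical-boundary simulations share a lab frame, and
superposing would only blur the restrained-shell reference. For generic
trajectories `superpose = TRUE` Kabsch-aligns every frame to the trajectory
average (two alignment passes), making the profile invariant to per-frame
rigid motions. A single frame yields an all-zero profile with a warning.

**Proximity profiles.** Per frame and labeled nucleotide proton, the nearest
protein hydrogen strictly within the radius (default 6 Å — "~6 Å" is
implemented as a strict inequality, configurable) attributes the frame to its
residue; distance ties break deterministically by lowest atom id. Frames with
nothing in radius accrue to a `none_in_radius` bucket, so frequencies always
sum to 1. Because "closest within a radius" could also be read as residence
time, an alternative `mode = "within"` counts any-residue-in-radius
fractions; closest-only is the default as it matches the "frequency of being
the closest" reading. Labels mapping to two equivalent protons (the `'d'`
pair) are computed per atom and averaged arithmetically. Replica ensembles
are aggregated as mean ± s.e.m. (sample sd / √n), rendered in the
conventional `"97.4±1.4%"` style.

Trajectories are read and written as multi-model PDB. No pre-installed R
package in the target environment parses multi-model PDB, so a minimal
fixed-column reader/writer is included; it rejects models with missing atoms
rather than imputing, and round-trips coordinates at the format's 10⁻³ Å
column precision. Residue numbering follows the source structure's author
numbering throughout; the default switch-region map (Switch I 197–207,
II 225–235, III 252–268 for Gα_S) is editable configuration, not hard-coded
truth.

## The synthetic-data generator

The generator forward-models exactly the statistical structure each analysis
assumes, with seeded determinism (identical spec + seed ⇒ byte-identical
output):

* **Melts**: the Boltzmann sigmoid on the 25–89 °C, 1 °C grid with iid
  Gaussian noise; the stated-world wild-type pair sits ~9 °C apart
  (56.2/65.2 °C) with slope 2 °C.
* **Kinetics**: the one-phase association sampled every 12 s for 200 min.
* **STD tables**: $I_{sat} = I_0(1 - w_p) +$ noise for per-proton transfer
  weights $w_p \in [0,1]$. The noise sd is $I_0 w_p / snr$, i.e. `snr` is
  the signal-to-noise of the *difference* signal — the same $SNR_{diff}$
  whose reciprocal scales σ downstream; a noise sd of $I_0/snr$ would put
  100% relative error on the difference signal at realistic weights and make
  normalized ratios undefined in the mean.
* **Toy trajectories**: scheduled hydrogen bonds are realized by placing the
  acceptor oxygen on the donor N–H axis at 2.0 Å (bonded frames) or 4.0 Å
  (broken frames) — safely inside/outside the 2.4 Å/120° cutoffs even under
  coordinate jitter ≤ 0.3 Å; scheduled closest-residue contacts move a
  dedicated marker proton to 3 Å from the labeled proton. Every scheduled
  interaction lives in its own spatial zone hundreds of Å from the others, so
  schedules cannot interfere. Gaussian jitter of sd σ per coordinate drives
  RMSF toward σ√3.

Noise magnitudes (2% of amplitude for CD, 1% for fluorescence, difference
SNR 20–100 for NMR) are stated-world defaults chosen to put fitted
uncertainties at the order of magnitude of typical triplicate error bars;
they were fixed before the acceptance thresholds were evaluated and are not
tuned against them.

**Deterministic vs Bernoulli assignment.** By default, target fractions are
realized by exact frame counting (`round(f · n_frames)` frames per class,
assigned as deterministic blocks), which removes sampling error and lets
oracle tests assert scheduled occupancies *exactly*. This cannot, by
construction, produce replica-to-replica variability, so the generator also
offers `assignment = "bernoulli"` (each frame draws its class independently),
which is what the 100-replica s.e.m.-recovery check uses. Unsatisfiable
schedules — per-proton fractions summing past 1, or one acceptor oxygen
claimed by two bond pairs — raise construction errors naming the conflict.

What a green test does **not** establish: the fixtures contain no force
field, solvent, thermostat or real spectral lineshape. They validate the
*analysis* — that fits recover known parameters under the assumed noise, and
that detectors measure scheduled geometry exactly — not that the assumed
models describe any particular experiment. Real CD melts can be multi-state,
real STD intensities depend on relaxation pathways the amplification factor
ignores, and real trajectories have correlated, anisotropic fluctuations.

## Reporting and determinism

`run_pipeline()` (CLI `run-all`) generates the synthetic demonstration for
every selected analysis and writes CSV/JSON reports plus a merged per-variant
dossier. Every artifact carries a config hash (FNV-1a over the canonical
config JSON, excluding the output directory so relocation does not change the
fingerprint), and the whole run is byte-identical under a fixed seed and
config. Defaults are echoed at startup so no threshold applies silently;
stage failures preserve completed artifacts and exit non-zero.

## Known limitations

* Two-state melts and single-exponential kinetics only; no sloped baselines,
  two-phase or lag models, and no global multi-trace fitting.
* No spectral processing and no binding-affinity estimation from STD data.
* The PDB reader handles coordinate trajectories (MODEL/ATOM/ENDMDL), not
  the full format; no periodic-boundary unwrapping (the intended systems are
  spherical and non-periodic).
* Classification thresholds, persistence thresholds and the region map are
  scientific configuration with documented defaults — results should quote
  them, which is why every report embeds the config hash.
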