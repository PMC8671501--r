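---
title: "Models and methods: surface-hopping dynamics and transient-absorption analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hopta)
```

## What this package computes

`hopta` is a desk-scale reimplementation of the simulation-to-observable
chain used to study the ultrafast excited-state decay of pyrimidine
nucleosides in water: mixed quantum-classical (fewest-switches surface
hopping) dynamics on electronic surfaces, synthesis of pump-probe
transient-absorption (TA) maps from the per-step energies and transition
dipoles, and the full analysis protocol applied to such maps — global
multi-exponential fitting with decay-associated spectra, population
lifetime fits, band-pass extraction of coherent vibrational oscillations,
two-dimensional Fourier maps with node/phase analysis, excited-state
normal-mode analysis, decay-channel statistics and ensemble barrier
mapping.

At desk scale the expensive multireference electronic structure is replaced
by analytic multi-state vibronic models. These are not fits to any molecule;
they are minimal constructions that reproduce the *mechanistic ingredients*
of the problem — a bright state funnelled to the ground state through a
barrier-controlled crossing along an out-of-plane (ring-puckering)
coordinate, gap-modulating skeletal modes near 600 and 750 cm$^{-1}$, a
nearby dark state, and a slow solvent coordinate that gates the barrier.
Everything downstream of the model (propagation, spectra, analysis) is the
same machinery one would run on ab initio data.

## The nucleoside-mimetic model

`make_pucker_model()` builds a 2- or 3-state, 4-mode diabatic Hamiltonian
(internally hartree/bohr/electron-mass; all interfaces in eV, fs,
cm^-1, amu):

* **Ground diabat**: harmonic in every mode (puckering wavenumber 400
  cm^-1 by default; tuning modes 600 and 750 cm^-1 with 6 amu effective
  masses) plus a quartic confining wall along the puckering coordinate.
  The wall sits on the ground diabat only, so the bright surface and its
  scanned barrier are untouched by it.
* **Bright diabat** ($\pi\pi^*$-like, vertical energy 4.52 eV): the same
  tuning harmonics plus linear (gap-modulating) couplings
  $\kappa_1 q_1 + \kappa_2 q_2$; along the puckering coordinate a
  unit-height barrier bump of height
  $B_{eff} = \Delta E^\ddagger + \lambda_s (1 - q_s)$
  at 0.8 bohr, a smooth 8 eV drop beyond 1.4 bohr that carries the surface
  below the rising ground diabat (the internal-conversion funnel), a gentle
  downhill tilt (the barrierless ballistic limit), a late-onset sextic wall
  that keeps the hot trajectory bound with its vertical gap inside the probe
  window, and a solvent-relaxation stabilisation $-\lambda_{shift} q_s$
  that produces the stimulated-emission red-shift.
* **Diabatic coupling**: a Gaussian in $u = q_p^2$ centred at the
  bright/ground crossing (located numerically at build time), amplitude
  0.5 eV. The amplitude sets the hop probability per crossing passage
  (Landau-Zener-like); the width is chosen so the passage is resolved by the
  nuclear step.
* **Dark diabat** ($n\pi^*$-like): harmonic, no funnel, vertical offset
  +0.15 eV above the bright state (aqueous solution destabilises the
  $n\pi^*$ state), weakly coupled to the bright diabat. Production
  dynamics use the two-state variant (`include_dark = FALSE`), matching a
  protocol whose state-averaging covers only the ground and bright states;
  the three-state variant is the *extended* basis for the diabatic re-hop
  upper bound (`diabatic_rehop()`).
* **Solvent coordinate** $q_s$: overdamped and driven — it carries no
  momentum and relaxes exponentially from 0 (unrelaxed) to 1 with time
  constant $\tau_s$. Barrier gating is linear in $(1 - q_s)$, so the
  effective barrier is non-increasing as the solvent relaxes. Because the
  coordinate is driven, it is excluded from Wigner sampling, from the
  conserved-energy ledger (its work on the active surface is accounted for
  explicitly), and from minimisation/normal-mode analysis.

The two study conditions are packaged as pipeline presets
(`default_config()`):

* `urd_like` — puckering mass 1 amu (hydrogen out-of-plane), no static
  barrier, no solvent gating: ballistic decay, ensemble lifetimes below
  200 fs.
* `fivemurd_like` — puckering mass 15 amu (methyl-carrying), solvent gating
  $\lambda_s = 0.10$ eV with $\tau_s = 150$ fs and a 0.15 eV
  solvent red-shift: the initially blocked, dynamically trapped variant
  whose decay is delayed to several hundred femtoseconds with of order 20%
  of trajectories still excited at 1 ps.

These generator settings *are* the study conditions; they were calibrated
once, when the model was built, to place the two variants in the ballistic
and trapped regimes, and are not tuned per run.

## Dynamics

Nuclei follow velocity Verlet on the active adiabatic surface with
analytic Hellmann-Feynman gradients. The recorded grid is uniform
(`dt_fs`, presets 0.25/0.5 fs; the coarse 1.0 fs default of
`run_trajectory()` is appropriate for smoother surfaces such as the
scattering benchmarks); inside each recorded step the integrator sub-steps
adaptively, capping per-substep displacement and, through a model-supplied
local stiffness bound, the local phase advance — the analytic funnel is far
steeper than ab initio surfaces, and a fixed 1 fs step there would lose
millihartrees at every crossing passage. With sub-stepping the total energy
between hops is conserved to better than 1e-4 hartree over a picosecond on
every shipped model, and trajectories violating that are flagged invalid.

Electronic amplitudes obey the TDSE in the adiabatic basis with energies
interpolated linearly across the nuclear step and time-derivative couplings
$\sigma_{ij} = d_{ij}\cdot v$ interpolated with a parabolic correction
that reproduces the overlap-derived step integral
$(U_0^T U_1 - U_1^T U_0)/2\Delta t$
— the Tully-Hammes-Schiffer-style treatment. Without this, a crossing
transit faster than the nuclear step transfers almost no amplitude and the
heavy variant never decays. Integration is fixed-substep RK4 (default 40
substeps, raised automatically so the phase advance per substep stays below
0.025 rad); the raw norm drift per step is below 1e-8 and is a hard error
otherwise.

Hop probabilities are accumulated substep-by-substep inside the integrator
(the positive part of the net integrated flux out of the active state),
again so that sub-step transits carry their full fewest-switches
probability. Accepted hops rescale the momentum along the nonadiabatic
coupling vector and conserve total energy to 1e-10 hartree; frustrated hops
leave the momentum unchanged by default (velocity reversal along the
coupling vector is available via `reverse_frustrated`). The energy-based
decoherence correction damps non-active amplitudes with
$\tau_i = \frac{\hbar}{|E_i - E_a|}(1 + C/E_{kin})$, C = 0.1 hartree by
default. Two deliberate policy notes:

* **Benchmarks run without decoherence.** On single-passage scattering the
  energy-based correction biases branching ratios measurably (+0.07 at
  k = 20 on the single-avoided-crossing benchmark, 500 trajectories) while
  the plain fewest-switches algorithm reproduces exact wavepacket branching
  to ~0.015. The correction is kept (default on) for the condensed-phase-like
  funnel models it was designed for.
* **Internal conversion is irreversible** (`irreversible_gs = TRUE` in the
  presets): after the first hop into the lowest state, hopping is switched
  off. On a low-dimensional model the hot ground-state trajectory re-crosses
  the coupling region every vibrational period and would otherwise
  artificially re-populate the bright state; high-dimensional ab initio
  dynamics has no such recurrences. The trajectory keeps propagating on the
  ground state (by default to `t_max_fs`; a finite `gs_window_fs` truncates
  the record) to feed the hot-ground-state spectra.

Initial conditions are T = 0 Wigner samples of the ground-state normal
modes (`wigner_sample()`:
$\mathrm{Var}(q) = \hbar/2m\omega$, $\mathrm{Var}(p) =
\hbar m\omega/2$), filtered by a hard vertical-excitation window
(4.43-4.60 eV in the presets, emulating the pump bandwidth) and uniformly
thinned to the ensemble size (57 in the presets). Thermal Wigner weighting
and pump-envelope weighting beyond the hard window are out of scope.

## Spectra

While a trajectory is in the bright state it emits a stimulated-emission
stick at the bright-ground gap with weight $-|\mu|^2 \times$ gap, and
excited-state-absorption sticks for every higher state; after internal
conversion it absorbs at the hot ground-state gap, damped by an exponential
vibrational-cooling factor (default 2 ps). The signal convention
$|\mu|^2 \times$ transition energy omits the cubic-frequency emission
prefactor; the choice is recorded in the map metadata and is invertible.
Sticks are Gaussian-broadened in probe energy ($\sigma_E$ = 0.15 eV),
averaged over trajectories and convolved along delay with a Gaussian IRF
(FWHM 30 fs, the midpoint of a 25-35 fs instrument response). The
SE/ESA/hotGS decomposition is retained and sums to the total exactly.
Ground-state bleach appears only as the absence of ground-state absorption
from excited trajectories; no steady-state subtraction is modelled.

In the default three-state geometry the only ESA transition (bright to
dark) lies at ~0.15 eV, far below the probe window, so the computed preset
maps contain SE and hot-GS bands; the ESA channel is exercised by tests on
models with a higher-lying state.

## Analysis protocol

* `global_fit()` — separable (variable-projection) least squares of the
  IRF-convolved multi-exponential model: linear in the decay-associated
  spectra across all probe energies simultaneously, Nelder-Mead in
  $\log\tau$ with a deterministic multi-start over the decades of the
  fit window. Standard errors come from the Jacobian of the profiled
  residual. The fit is exactly reproducible: the multi-start jitter is a
  fixed quasi-random sequence, not drawn from the session RNG.
* `fit_population_lifetime()` — mono-exponential population fit (optional
  amplitude/plateau), standard error from the fit Jacobian.
* `extract_oscillations()` — the detrending/band-pass step is implemented
  as one exact orthogonal projection: the trace is projected onto the span
  of the in-band DFT cosine/sine pairs orthogonalised against a
  polynomial trend basis (order 8). The polynomial complement absorbs the
  broadband leakage of multi-exponential kinetics (a pure Fourier mask
  would leak ~50% of a 100 fs decay into the 600 cm^-1 band); the
  projection is zero-phase and idempotent to machine precision. A
  raised-cosine band edge is available (`edge_width_cm`), implemented as a
  tapered mask after trend removal — tapering and exact idempotence are
  mutually exclusive, and the projection was chosen as the default. The
  first 50 fs are excluded by default (coherent-artifact region).
* `ftmap_2d()` — Hann window, zero-padding factor 4, cosine-phase
  convention at the window start.
* `node_phase_analysis()` — amplitude minimum flanked by maxima along probe
  energy at fixed wavenumber, circular phase difference between the flanks.
  A wavepacket modulating a band about its centre gives zero oscillation
  amplitude at the centre and a $\pi$ flip across it, which is exactly
  what the analysis recovers on constructed input (node within one grid
  step of the mean gap, phase jump $\pi \pm 0.2$).
* `normal_modes()` — central-difference Hessian from analytic gradients,
  mass-weighted, imaginary frequencies reported negative. Driven
  (overdamped) coordinates are excluded from the Hessian and reported as
  zero-frequency unit modes, keeping the mode count equal to the mode
  number.
* `channel_yields()` / `classify_hop()` — hop-geometry classification by
  normalized displacement against per-channel thresholds (default: half the
  crossing displacement for puckering), precedence puckering >
  ring_opening > O_oop on ties; Wilson 95% intervals; fractions are over
  decayed trajectories with the undecayed fraction reported separately.
* `ensemble_barrier_map()` — per time window, minimum bright-state energy
  in bins along the reaction coordinate, with each visited frame evaluated
  by default with the spectator (tuning) coordinates at rest: the raw frame
  energies carry several tenths of an eV of spectator-mode energy that
  would swamp a ~0.1 eV barrier. The effective barrier is the highest point
  of the visited profile relative to the Franck-Condon bin — a lower bound
  while the ensemble is still confined behind the barrier — with frames
  beyond the crossing excluded. With solvent gating the late-window barrier
  is not larger than the early-window one.

## Problem sizes and reproducibility

The shipped test-and-acceptance runs use: 500-trajectory swarms for the
scattering benchmark (dt = 0.1 fs, two momenta), 57-trajectory preset
ensembles (the selection size of the study conditions), 100 + 100
trajectories for the light/heavy mechanistic comparison, 50 replicates for
the biexponential recovery study and 1e4 Wigner samples for the moment
checks. Every stochastic step takes an explicit integer seed; ensembles
derive per-trajectory seeds as `base_seed + index`, and a pipeline run is
reproducible byte-for-byte from its archived config and seed (the manifest
records MD5 hashes of every artifact).

## What passing tests do and do not show

The synthetic generator reproduces mechanisms, not molecules: barrier
gating, inertia, gap modulation, funnel internal conversion, hot
ground-state absorption. It does not contain the real compounds' state
energetics, transition dipoles, anharmonic couplings, intramolecular
vibrational redistribution, conformer ensembles, intersystem crossing, or
explicit solvent structure. Agreement of the analysis layer with its
oracles (exact wavepacket branching, closed-form kinetics, injected
oscillations) validates the *pipeline*; numbers produced on the model
systems (lifetimes, yields, survival fractions) characterise the model
systems, not uridine or 5-methyluridine.

## Known limitations

* One-dimensional reaction coordinate per channel; the rare channels
  (ring opening, carbonyl out-of-plane) are threshold conventions on the
  tuning coordinates, not separate surfaces.
* The diabatic re-hop bound ignores decoherence and momentum rescaling
  along the frozen paths, which is why it is an upper bound.
* The hot ground-state band is broader than a real cooling band: a single
  bound coordinate sweeps the whole gap range every period.
* Fewest-switches hopping itself carries its known biases (no interference
  between passages, classical nuclei); the benchmark suite quantifies them
  against exact propagation on the scattering models.
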