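# hopta

Surface-hopping dynamics and transient-absorption simulation on model
vibronic Hamiltonians.

## The problem

Pyrimidine nucleosides dissipate absorbed UV energy on sub-picosecond
timescales by internal conversion through conical intersections: the bright
¹ππ* state rides a ring-puckering (hydrogen or methyl out-of-plane)
coordinate over a small barrier into a crossing with the ground state. In
water the methylated base is an order of magnitude slower than the
unmethylated one — partly inertia, partly a *dynamic barrier* created by
the solvent shell that must reorganize around the bulky deformation.
Resolving this requires connecting nonadiabatic molecular dynamics to the
actual observable, the pump–probe transient-absorption (TA) map
ΔA(delay, probe energy), and then analysing both simulated and measured
maps with the same protocol.

`hopta` implements that chain at desk scale for R users: analytic
multi-state vibronic models with conical intersections stand in for the
expensive electronic structure, and everything downstream is the real
machinery:

* **Models** — the three canonical 1D scattering benchmarks
  (`make_tully_model()`) and a nucleoside-mimetic 3-state × 4-mode funnel
  model (`make_pucker_model()`): barrier-gated crossing along a puckering
  coordinate, 600/750 cm⁻¹ gap-modulating modes, a nearby dark state and an
  overdamped solvent coordinate that lowers the barrier as it relaxes.
* **Dynamics** — Tully's fewest-switches surface hopping: velocity-Verlet
  nuclei with adaptive sub-stepping, TDSE amplitudes with
  overlap-corrected (Tully–Hammes–Schiffer-style) couplings, momentum
  rescaling along the nonadiabatic coupling vector, frustrated-hop
  handling, and the Persico-type energy-based decoherence correction
  (`run_trajectory()`, `run_ensemble()`, `diabatic_rehop()`).
* **Initial conditions** — T = 0 Wigner sampling with a pump-window filter
  (`wigner_sample()`, `excitation_window()`).
* **Spectra** — per-step stimulated emission, excited-state absorption and
  hot-ground-state absorption sticks, energy broadening and IRF
  convolution (`ensemble_ta_map()`).
* **Analysis** — IRF-convolved global multi-exponential fits with
  decay-associated spectra by variable projection (`global_fit()`),
  population lifetimes (`fit_population_lifetime()`), band-pass Fourier
  extraction of coherent oscillations (`extract_oscillations()`), 2D FT
  maps with node/phase detection (`ftmap_2d()`, `node_phase_analysis()`),
  excited-state normal-mode analysis (`normal_modes()`), decay-channel
  yields, survival fractions and ensemble barrier maps
  (`channel_yields()`, `survival_fraction()`, `ensemble_barrier_map()`).

The central kinetic quantity is the mono-exponential excited-state lifetime
τ from P(t) = e^(−t/τ), and the central spectroscopic model is

    ΔA(t, E) = Σ_k DAS_k(E) · [exp(−t/τ_k) ⊛ IRF](t)

fit by separable least squares. See the methods vignette
(`vignettes/hopta-methods.Rmd`) for the model construction, the numerical
choices and their rationale.

## Worked example

The two packaged study conditions differ only in the puckering mass and
the solvent gating:

```r
library(hopta)

run <- run_pipeline(default_config("urd_like", seed = 1, n_select = 57),
                    out_dir = "runs/urd_like")

run$lifetime$tau_fs          # excited-state lifetime from P(t)
run$fit                      # global fit of the simulated TA map
run$survival$fraction        # still excited at the end of the window
```

which prints (seed 1, 57 trajectories):

```
> run$lifetime$tau_fs
[1] 47.34273
> run$fit
<global_fit>
  time constants (fs): 30.4 +- 0.1, 2259.5 +- 24.1
  t0 = 0.0 fs, IRF FWHM = 30.0 fs, residual RMS = 0.261
> run$survival$fraction
[1] 0
```

The light (hydrogen-like) variant decays ballistically in ~50 fs: the fast
global-fit component tracks the stimulated-emission decay and the
picosecond component is the slowly cooling hot-ground-state absorption
left behind. The `fivemurd_like` preset (15 amu puckering mass, solvent
gating λ_s = 0.10 eV relaxing with τ_s = 150 fs) is dynamically trapped:
its fitted lifetime is more than an order of magnitude longer and roughly
20% of trajectories are still excited after 1 ps. The run directory
contains the sampled initial conditions, the population traces, the TA map
(text matrix + JSON sidecar), fit results and a manifest with MD5 hashes
of every artifact; re-running with the same config and seed reproduces the
outputs byte for byte.

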