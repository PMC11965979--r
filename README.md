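# pathmetad

Enhanced-sampling and analysis toolkit for mapping large-scale
conformational transitions — the kind of slow, cooperative rearrangement
seen in G protein-coupled receptor (GPCR) activation, where helix TM6
translates by a few Angstrom and rotates by tens of degrees between the
inactive and active states.  The package is aimed at computational
structural biologists who want the full method stack (path collective
variables, well-tempered metadynamics, reweighting, trajectory
statistics, protein structure networks) in a form that is testable at
desk scale: every component can be exercised end-to-end on built-in toy
energy models whose free-energy surfaces are known analytically, with no
external MD engine or downloads.

## The methods

**Path collective variables (PCVs).**  Given a reference path of N
conformations X(1)…X(N) spanning a transition, a configuration R is
located by its progress along and distance from the path:

    s(R) = (1/(N-1)) * Σᵢ (i-1) exp(-λ‖X(R)-X(i)‖²) / Σᵢ exp(-λ‖X(R)-X(i)‖²)
    z(R) = -(1/λ) ln Σᵢ exp(-λ‖X(R)-X(i)‖²)

where ‖·‖² is either the mean-squared deviation after optimal rigid
superposition (Kearsley's quaternion algorithm) or the summed squared
difference of switched contact maps, C(r) = (1-(r/r₀)ⁿ)/(1-(r/r₀)ᵐ).
Paths are built from a transition trajectory by equal-arc-length frame
extraction plus two extrapolated terminal frames, spacing is validated,
and λ is calibrated from the mean inter-frame distance (rule 2.3/⟨d⟩,
with explicit overrides honored).  Analytic gradients are provided so
the CVs can be biased.

**Well-tempered metadynamics (WT-MetaD).**  A history-dependent bias
V_G(S,t) of Gaussian kernels is grown on the CVs; each new kernel height
is damped by the bias already present, W = ω₀τ_G · exp(-V_G/(k_B ΔT))
with ΔT = (γ-1)T, so the bias converges to -(ΔT/(ΔT+T))·F(S) and the
free energy is recovered as F(S) = -(γ/(γ-1))·V_G(S).  The module also
provides reweighting onto arbitrary CVs (time-dependent-offset scheme),
basin free energies, convergence profiles, the acceleration factor
α = exp(ΔF/k_B T), and a bit-exact HILLS-style kernel log.

**Sampling.**  A BAOAB-discretized Langevin integrator over pluggable
energy models, with metadynamics bias forces (chain rule through the CV
gradients), moving harmonic (steered) restraints with work accounting,
and one-sided harmonic walls.  Units are Angstrom, kcal/mol, ps
throughout; kJ/mol inputs are converted at the configuration layer.

**Analysis.**  Dynamical cross-correlation matrices of Cα fluctuations
(C_ij = ⟨Δr_i·Δr_j⟩/√(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)), region RMSD summaries with
built-in receptor region tables (orthosteric site, connector,
intracellular site), ionic-lock style distance probes with interaction
occupancies, and protein structure networks: residues as nodes, edges
weighted by the normalized side-chain contact count
I_ij = n_ij/√(N_i N_j)·100, filtered at I_min, with hub detection and
frequency-weighted metapaths across frames.

## Worked example

Build the two-state bead-chain fixture, extract a reference path, and
recover the free-energy surface of the analytic double well with
WT-MetaD:

```r
library(pathmetad)

chain <- make_two_state_chain()                   # 24-bead "receptor"
traj  <- make_transition_trajectory(chain, n_frames = 50,
                                    noise = 0.05, seed = 1)
path  <- build_path(traj, 10)                     # 10 real + 2 terminal
path
#> ReferencePath: 12 frames (10 real), metric rmsd, lambda 45
validate_spacing(path)
#> PathDiagnostics (rmsd): mean inter-frame distance 0.2256, cv 0.070

evaluate_path_cv(chain$A$coords, path)$s          # 0.091  (near start)
evaluate_path_cv(chain$B$coords, path)$s          # 0.909  (near end)

model <- double_well_model(barrier = 6, tilt = 2)
ref   <- analytic_reference(model)
#> analytic: delta G = 1.96, barrier = 7.03 kcal/mol

run <- run_metad(model, langevin_params(n_steps = 1e6, seed = 1),
                 x0 = -1, cvs = list(coordinate_cv(1, 1)),
                 wt = wt_params(height = 0.95, stride = 1,
                                bias_factor = 15, widths = 0.1),
                 gs = grid_spec(-2.2, 2.2, 441),
                 walls = list(wall_restraint(1,  1.9, 100, "upper"),
                              wall_restraint(1, -1.9, 100, "lower")))
run
#> DynamicsRun: 100000 recorded frames, seed 1, 10000 kernels

fes <- fes_from_bias(run$state, grid_spec(-2.2, 2.2, 441))
basin_free_energy(fes, c(0.04, 1.8)) - basin_free_energy(fes, c(-1.8, 0.04))
#> 1.82                                     # vs analytic 1.96 kcal/mol

estimate_boost(13.4, 300)                         # 5.78e9
```

The recovered basin free-energy difference (1.82 kcal/mol here) sits
within the stochastic tolerance of the analytic 1.96 kcal/mol; the
acceleration factor says a 13.4 kcal/mol barrier is crossed about
5.8 x 10^9 times faster under the converged bias at 300 K.

## Command line

A subcommand CLI wraps the same functions:

```sh
Rscript inst/cli/pathmetad.R fixtures  --out fixtures
Rscript inst/cli/pathmetad.R make-path --traj fixtures/transition.xyz \
    --frames 10 --out pathdir
Rscript inst/cli/pathmetad.R metad --n_steps 200000 --seed 1 --out mrun
```

Subcommands: `make-path`, `validate-path`, `metad`, `steer`, `fes`,
`reweight`, `correl`, `regions`, `probes`, `psn`, `fixtures`.  Each run
writes a `provenance.json` (config hash, seed, version) beside its
outputs; configs are YAML validated against a schema, with unit
suffixes such as `"10000 kJ/mol"` converted to internal units.

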