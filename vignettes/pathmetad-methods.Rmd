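---
title: "Methods and design notes for pathmetad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for pathmetad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmetad)
```

# Scope and model

pathmetad implements the computational machinery used to map slow,
cooperative conformational transitions — prototypically class A GPCR
activation, where the intracellular end of helix TM6 translates by a
few Angstrom while rotating by tens of degrees — onto one or two path
collective variables, and to reconstruct the free-energy surface over
them with well-tempered metadynamics.  All components run end-to-end on
built-in toy systems with analytically known free energies, so the
statistical machinery can be validated independently of any all-atom
force field or MD engine, which are out of scope.

Internal units are Angstrom, kcal/mol and picoseconds everywhere;
masses are amu.  Configuration inputs in kJ/mol (the convention of
GROMACS-style workflows) are converted at parse time with
1 kcal = 4.184 kJ.  Boltzmann's constant is fixed at
0.0019872 kcal/(mol K).

# Path collective variables

A reference path is an ordered set of N reduced representations X(l).
Progress `s` and distance `z` are the standard soft-min expressions
over the squared metric distances d_i from the current configuration to
each path frame (see the README for the formulas).  Two metrics are
supported:

* **coordinate-RMSD**: d_i is the mean-squared deviation (A^2) of a
  chosen atom subset after optimal rigid superposition.  Superposition
  uses Kearsley's quaternion method, whose smallest-eigenvalue
  eigenvector is the optimal rotation; being a proper rotation by
  construction it has no reflection branch to repair.  The post-fit
  RMSD is recomputed from the applied transform rather than from the
  eigenvalue, which is far more accurate near zero residual.
* **contact-map**: X is the vector of switched contacts
  C = (1-(r/r0)^n)/(1-(r/r0)^m) and d_i the summed squared contact
  difference (dimensionless).  Default exponents are n = 6, m = 12 when
  a contact table omits them.  The switching function is evaluated
  through `expm1` so the removable singularity at r = r0 (value n/m) is
  crossed at full precision, for the value and the derivative alike.

**Exponent convention.**  The quantity multiplying lambda in the
exponential kernels is always the *squared* metric distance: the
mean-squared deviation for the coordinate metric, and the summed
squared contact difference used directly (not re-squared) for the
contact metric.  This makes the coordinate-metric lambda carry units of
1/A^2, consistent with production settings quoted in that unit.

**Gradients.**  For the coordinate metric the rotation is held fixed at
its optimum when differentiating d_i; the first-order contribution of
the rotation vanishes there (envelope argument), so the gradient
(2/n)(x - x_aligned) is exact, as the finite-difference tests verify to
better than 1e-5 relative error.  Contact-metric gradients chain
through dC/dr and the inter-atomic unit vectors.  Kernel sums are
evaluated in log space, so large lambda*d cannot overflow.

**Path construction.**  `build_path()` extracts n frames approximately
equidistant in the chosen metric by greedy selection along the
cumulative arc length of a transition trajectory, aligns each selected
frame onto its predecessor, and adds one linearly extrapolated terminal
frame at each end (clamped to [0,1] for contact values).  The terminal
frames are flagged non-physical (`is_extra`) and excluded from the real
frame count; they give the sampling room past the endpoints.  A path is
declared equally spaced when the coefficient of variation of the
inter-frame distances is at most 0.25 — a threshold we chose, since the
practice it encodes ("verify the frames are equally spaced") comes with
no published tolerance; violations warn rather than error.

**Lambda calibration.**  The default rule is lambda = 2.3/mean(d) with
d the quantity entering the exponent.  For the contact metric this
reproduces production-scale settings to a few tenths of a percent
(mean distance 0.63 gives lambda 3.65).  Coordinate-metric values in
the literature do not follow a single reproducible rule — published
lambdas are roughly of order 1/(mean RMSD)^2 but not exactly — so an
explicit lambda (e.g. 1.22 A^-2) always overrides calibration and is
the recommended route for production-style settings.

# Well-tempered metadynamics

Kernel heights follow W = w0 * exp(-V_G/(kB dT)), dT = (gamma-1)T.
Defaults mirror common production practice for receptor activation:
initial height 0.95 kcal/mol, bias factor gamma = 15, temperature
300 K, Gaussian widths per CV (0.1 on a path-progress CV is typical),
deposition stride 1 ps in the toy runs (production strides are a few
ps; the stride is configuration, not a constant).  The free energy is
recovered as F = -(gamma/(gamma-1)) V_G — prefactor 15/14 at the
default bias factor — and zeroed at its minimum.

During dynamics the bias and its CV-gradient are accumulated on the
deposition grid (1D or 2D), so the per-step force cost is independent
of the kernel count; kernels update the grid within 6 sigma, a cutoff
with relative error below 1e-8.  The kernel list itself is kept and
written to a HILLS-style log at full precision, so a bias state is
bit-exactly reconstructible from its log.

**Reweighting** implements the time-dependent-offset scheme: a sample
at time t carries weight exp((V(s_t, t) - c(t))/kBT), with the offset
c(t) computed from the evolving bias on the deposition grid at every
kernel time and interpolated to frame times.  The weighted histogram of
any target CV becomes its free energy.  On the biased CV this agrees
with the bias-inversion estimate to about 0.1 kcal/mol on converged toy
runs; on an orthogonal coordinate it recovers the analytic profile
within 0.3 kcal/mol over the thermally sampled range (tail bins beyond
~1.5 kcal/mol above the minimum carry mostly histogram noise at the
problem sizes used).

**Convergence and timescales.**  `convergence_profile()` recomputes the
basin-to-basin free-energy difference from the bias truncated at each
checkpoint; we declare convergence when the drift over the final 20% of
checkpoints is below 0.5 kcal/mol (the literature reports convergence
times but no criterion, so this is the package's own).  The
acceleration factor alpha = exp(dF/kBT) turns a barrier into the boost
factor of the slowest crossing: 13.4 kcal/mol at 300 K gives 5.8e9,
inside the 1e9-1e10 decade typical of converged receptor-activation
runs.

# The Langevin sampler

Integration uses the BAOAB splitting, chosen for its accuracy in
configurational averages at large steps.  Toy-run defaults: timestep
0.01 ps, friction 5 ps^-1, mass 40 amu — a deliberately heavy, strongly
coupled particle so that a 1e6-step (10 ns) run both equilibrates and
converges the tempered bias on one CPU in well under a minute.  A seed
is mandatory; a run is bit-reproducible from it, and all CLI runs
record it in their provenance file.  Steered schedules interpolate the
spring constant and target linearly between knots (matching the shape
of multi-stage pulling protocols) and accumulate the external work
analytically from dV/dt.  Walls are one-sided harmonic restraints
active only beyond their threshold.  Energy non-finiteness aborts with
the offending frame index.

For the double-well acceptance runs the CV domain is gridded on
[-2.2, 2.2] at 0.01 spacing with walls at ±1.9 (100 kcal/mol/unit^2) to
confine sampling to the physically meaningful region; bias lookup uses
the nearest grid node, a discretization visible only at the grid-step
scale.

# Synthetic fixtures and what they do (not) show

`make_two_state_chain()` builds a helix-like 24-bead chain whose second
half — the "TM6 segment" — translates 3 A and rotates 45 degrees
between endpoints A and B, the hallmark magnitudes of receptor
activation at bead scale.  The energy is a tilted quartic double well
along the A-to-B line in configuration space plus an isotropic harmonic
restraint orthogonal to it.  Because the orthogonal modes are Gaussian
and identical in both basins, the free energy along the transition
coordinate is exactly the 1D profile, and `analytic_reference()`
computes the basin free-energy difference and barrier by quadrature —
an independent closed-form target for the entire bias/recovery stack.
Default barrier parameter 6 kcal/mol and tilt 2 kcal/mol give a
thermally rare but samplable transition at 300 K (about 10 kBT).

`make_correlated_trajectory()` draws frames from a multivariate normal
with a prescribed atom-atom correlation matrix applied independently
per Cartesian axis, so the dynamical cross-correlation equals the input
rho exactly in expectation — ground truth for the correlation module.

These fixtures validate the statistics, not the physics: they have no
solvent, no membrane, no rugged energy landscape, no metric anisotropy
between path frames, and their transition tube is straight by
construction.  Passing tests therefore certify the estimators and
bookkeeping (unbiased sampling, bias growth, free-energy inversion,
reweighting, CV gradients), not force-field realism; fixture scale
(tens of beads, thousands of frames) is chosen so the full suite runs
in minutes on one CPU.

# Trajectory analyses

Cross-correlation uses the vector form
C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>), the conventional
reading that keeps C_ii = 1; fluctuations are measured about the
trajectory mean after two rounds of iterative superposition onto the
running average (fitting is configurable and can be disabled for
pre-aligned or synthetic input).  Pairs with |C| > 0.5 are classified
correlated/anti-correlated.  Zero-variance atoms yield NA rows rather
than dividing by zero.

Region RMSD ships the author-numbered residue tables of the receptor's
orthosteric site, connector and intracellular site; whether the
literature fits on the whole receptor or per region before measuring is
unstated, so the fit selection is exposed (default: all C-alpha).
Distance probes are plain Euclidean distances (internal coordinates,
no fitting); salt-bridge occupancy uses a configurable cutoff with
default 4.5 A between the specified side-chain atoms, the conventional
criterion, since reported occupancies do not print the cutoff used.

# Protein structure networks

Edges carry I_ij = n_ij/sqrt(N_i N_j) * 100 with n_ij the side-chain
atom pairs (backbone N, CA, C, O excluded) within 4.5 A.  The published
per-residue-type normalization constants are not reproduced in the
sources this package follows, so by default N_i is self-calibrated from
the input ensemble as the mean side-chain contact count per residue
type (floored at 1); a user table overrides.  Sequence neighbors
|i-j| <= 1 are excluded, standard PSN practice.  The default
I_min = 3% is configurable.  A "metapath" is defined here
operationally — the sources leave it qualitative — as the
source-to-sink path maximizing the product of per-frame edge
frequencies, computed as a shortest path under weight -ln(frequency)
after dropping edges below a frequency floor; ranking is verified
against exhaustive enumeration on small graphs.

# Numerical choices and degenerate inputs

* Log-sum-exp stabilization in all kernel sums; `expm1` through the
  contact switching singularity.
* Superposition requires >= 3 non-collinear points; collinear input is
  an error, identical sets give exactly zero RMSD and the identity
  rotation.
* Alternate PDB locations resolve to the highest-occupancy copy;
  unparseable records fail naming the line; elements missing from a
  structure are inferred from atom names with a warning.
* Empty atom selections warn (not error), letting range queries span
  gaps; PSN on side-chain-free input returns an empty graph with a
  warning.
* Histogram bins in reweighting are uniform; free energies are zeroed
  at their sampled minimum, and unsampled bins are +Inf rather than
  imputed.

# Problem sizes used by the shipped checks

The double-well recovery runs 3 seeds x 1e6 steps (10 ns each) with
1000 kernels/ns; path-CV oracle checks use 200 random small paths; the
correlation ground truth uses 5000 frames; PSN oracles use 6-residue
toys and 7-node graphs.  These sizes give stochastic errors of order
0.1-0.2 kcal/mol on recovered free energies and ±0.01 on correlations,
comfortably inside the stated tolerances, and keep the complete test
suite in the minutes range on a single CPU.

# Known limitations

Metadynamics grids support one or two CVs (the dimensionalities used in
practice for path CVs); adaptive or moving-path variants, multiple
walkers and infrequent-metadynamics rate recovery are not implemented.
The sampler is a CV-space validation engine, not an MD engine: no
solvent, constraints, or barostats.  mmCIF, topology perception and
protonation are out of scope for the structure model; helicity-based
restraints used in production are generalized here to walls on any
scalar CV.
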