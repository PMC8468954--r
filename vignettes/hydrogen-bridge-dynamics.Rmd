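---
title: "Modelling and analysing intramolecular O-H...O proton dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing intramolecular O-H...O proton dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbridge)
```

## The scientific problem

Short intramolecular O-H...O hydrogen bridges --- such as the two
resonance-assisted bridges of naphthazarin-type quinones --- host a
mobile proton in an asymmetric double-well potential.  At room
temperature the proton mostly resides on the donor oxygen, but it
repeatedly visits the acceptor side (proton transfer), the two bridges
of a molecule move in a correlated way, and the O-H stretch appears as
an extremely broad vibrational band.  First-principles molecular
dynamics is the natural tool for studying these systems, but the
trajectories themselves are expensive artefacts.  This package separates
the *analysis* layer --- everything one computes *from* a trajectory ---
from the engine that produced it, and couples it to a cheap surrogate
simulator so that every stage can be exercised and validated on a desk.

Four analysis families are covered:

* bridge geometry time series, Voronoi proton-possession statistics,
  transfer-event detection, joint donor-proton histograms and
  double-transfer synchronicity;
* velocity-autocorrelation functions and their cosine-transform power
  spectra, with band-region extraction;
* discrete proton-potential scans and barrier analysis with a
  discretization uncertainty;
* an a posteriori nuclear-quantum-effects (NQE) pipeline: snapshot
  extraction, arc-based proton paths, a degree-9 polynomial potential,
  a 1D grid Schrödinger solver and thermal expectations of the
  donor-proton distance.

## The surrogate model

Each bridge is reduced to two coordinates: the donor-proton distance
$r$ and the donor-acceptor distance $R$.  The per-bridge potential is

$$V(r,R) = D_d\left[1-e^{-a_d (r-\rho)}\right]^2
         + D_a\left[1-e^{-a_a (R-r-\rho)}\right]^2
         + \tfrac12 k_R (R-R_0)^2 ,$$

two opposed Morse wells --- one binding the proton to the donor at
distance $\rho$, one binding it to the acceptor at distance
$R - \rho$ --- plus a harmonic restraint on the bridge-breathing
coordinate.  Two bridges are coupled bilinearly through the signed
Voronoi coordinates $q_b = r_b - R_b/2$:
$V_c = \lambda_c\, q_1 q_2$, so a negative $\lambda_c$ favours
concerted configurations (both protons donor-side or both
acceptor-side), the correlation observed for real double-bridge
systems.  This functional form is *not* an ab initio surface; it is the
simplest Hamiltonian that reproduces the qualitative structure of one:
a deep donor-side minimum near 1 Å, a shallow acceptor-side minimum, a
barrier of a few kcal/mol that is strongly modulated by $R$, and a
breathing O...O distance.

### Default parameters and how they were chosen

| parameter | value | units | role |
|---|---|---|---|
| `D_d` | 48 | kcal/mol | donor-well depth |
| `D_a` | 46 | kcal/mol | acceptor-well depth (sets the asymmetry) |
| `a_d`, `a_a` | 3.2 | 1/Å | Morse range (sets barrier and O-H stretch) |
| `rho` | 0.95 | Å | covalent O-H rest length |
| `k_R` | 300 | kcal/mol/Å² | skeletal restraint on R |
| `R_0` | 2.68 | Å | rest length of that restraint |
| `lambda_c` | -2 | kcal/mol/Å² | inter-bridge coupling |
| `m_H` | 1.0078 | amu | proton mass |
| `m_R` | 7.9997 | amu | effective breathing mass (half an oxygen) |

The defaults were fixed once, against equilibrium targets evaluated by
2D Boltzmann quadrature (`boltzmann_bridge_stats()`), not against
dynamics: a double-well profile at a fixed 2.55 Å bridge with a barrier
of ≈5 kcal/mol and a deep minimum at ≈1.0 Å; a thermal mean O...O
distance of ≈2.55 Å at 295 K; a donor-site residence of ≈90 %, the
regime typical of gas-phase naphthazarin derivatives; and an O-H
stretch below ≈3400 cm⁻¹.  Two constraints deserve comment because
they push the parameters away from "textbook" O-H Morse values
($D_e \approx 110$ kcal/mol, $a \approx 2.2$ /Å):

* with textbook values the two opposed Morse tails overlap so strongly
  at $R \approx 2.55$ Å that the profile collapses into a *single*
  well.  A double well with a 3–8 kcal/mol barrier at this bridge
  length requires a steeper, shallower effective well; `D` ≈ 48 with
  `a` = 3.2 also keeps the harmonic O-H wavenumber
  $\tilde\nu = a\sqrt{2D/m_H}/(2\pi c)$ near 3400 cm⁻¹ (the actual
  normal mode, softened by the acceptor well, is ≈2510 cm⁻¹ —
  `model_normal_modes()`).  These are *effective* constants of a
  hydrogen-bonded proton, not gas-phase dissociation parameters.
* `R_0` is the rest length of the skeletal restraint, not the observed
  O...O distance.  The acceptor Morse well pulls the bridge inward by
  roughly 30 kcal/mol/Å near equilibrium, so the dynamical mean sits
  ≈0.13 Å below `R_0`; `R_0` = 2.68 with `k_R` = 300 places the
  thermal mean at 2.553 Å with a 0.06 Å standard deviation, and puts
  the breathing mode near 660 cm⁻¹, in the heavy-atom band region.

Two presets modify the defaults: `"solid"` equalises the Morse depths
(symmetric well, ≈50/50 possession — the strongly-shared regime of a
crystalline environment), and `"lowbarrier"` softens the range to
`a` = 3.0 and removes the coupling, dropping the barrier to
≈3.4 kcal/mol.  The low-barrier preset exists for ergodicity
validation: with ≈3000 transfer events per nanosecond, simulated
possession statistics converge to the quadrature reference well inside
a 1 ns run.

### What the generator emulates, and what it does not

The surrogate reproduces the *statistical structure* of ab initio
trajectories of a two-bridge system: double-well proton exchange with
realistic residence fractions, R-gated transfers, correlated
double-bridge motion, and a proton power spectrum with a broad stretch
band.  It does not attempt the paper-grade quantities that require an
electronic-structure engine: absolute barrier heights of a specific
molecule, substituent effects, crystal-field effects, or IR
intensities.  Tests passing on the surrogate therefore validate the
*analysis machinery* (estimators, transforms, solvers) — they say
nothing about any particular compound.

## Dynamics: integrator and reproducibility

Trajectories are generated by BAOAB-split Langevin dynamics (velocity
half-kick, half-drift, exact Ornstein-Uhlenbeck velocity update,
half-drift, half-kick) at `time_step` = 0.25 fs — more than 30 steps
per period of a 3400 cm⁻¹ oscillation.  The first
`n_equilibration_steps` (default 10 000) are discarded; production
frames (default 21 ps) are stored every `output_stride` steps with
absolute time stamps.  All noise comes from R's seeded RNG in a fixed
draw order (r1, R1, r2, R2 per step), so a run is bitwise reproducible
from its seed; `write_run_manifest()` records the full setup.  The
run starts from the Newton-polished minimum of the uncoupled bridge,
which makes a zero-temperature, zero-friction run an exact fixed point
— a useful integrator sanity check.  Divergence (non-finite energy or
coordinate) aborts with the failing step number.

## Statistics layer

Possession follows the Voronoi geometric criterion: a frame belongs to
the donor when $d_\mathrm{DH} < d_\mathrm{HA}$.  Exact ties are counted
as donor *and* reported separately — they are a measure-zero event, and
an explicit convention beats a silent one.  Transfer events are sign
changes of $s = d_\mathrm{DH} - d_\mathrm{HA}$ that persist at least
`min_dwell` (default 10 fs ≈ one O-H vibrational period); raw sign
changes would overcount barrier recrossings.  "Transfer event" has no
unique definition in the field, so reports should treat the dwell
filter as this package's operationalization.  The joint donor-proton
histogram uses 0.02 Å bins on [0.8, 1.8] Å (the visual granularity of
published density maps); out-of-range samples are clamped into edge
bins and counted, and the density always integrates to exactly one.
The synchronicity summary reports the four possession quadrants plus a
central region $|q_b| < \epsilon$ (default 0.05 Å, a free choice) whose
occupancy would flag synchronous double transfer.

## Spectra

The velocity autocorrelation
$C(k) = \langle v(t)\cdot v(t+k\,dt)\rangle / \langle v^2\rangle$ is
averaged over all time origins (via FFT) and over the Cartesian
components of the selected atoms; bridge-proton spectra select the
proton atoms only.  The power spectrum is the one-sided cosine
transform of the lag-windowed VACF — the VACF is real and time-even,
so this route gives a real spectrum by construction.  The wavenumber
axis is $\tilde\nu_j = j/(c L\,dt)$ with one-bin resolution
$1/(c L\,dt)$; with the default `max_lag` = min(2048, n/2) and 0.25 fs
frames this is ≈65 cm⁻¹.  The default Hann lag window trades a little
resolution for strongly suppressed side lobes; the window, lag count
and resolution are carried in the spectrum object since no canonical
convention exists.  Tiny negative leakage values are clipped to zero
and counted.  Band regions are maximal runs above a relative threshold
(default 5 % of the maximum) merged across gaps up to 50 cm⁻¹ — both
free parameters with no canonical values, exposed as arguments.

## Scan analysis

`scan_positions()` generates the customary fixed-increment (0.05 Å)
O-H scans; energies come from a pluggable backend — the builtin model,
a plain R function, or a CSV table of externally computed single points
(`distance_A,energy_kcal_mol`), which is the supported path for real
ab initio profiles.  `analyze_profile()` reports the barrier from the
discrete points only, with uncertainty equal to half the largest energy
step between the discrete maximum and its neighbours: scan protocols
determine the barrier only to the energy granularity near the
transition state, and interpolating would manufacture precision.  A
clearly-labelled three-point parabolic refinement is available but
never used for the primary value.  The analysis is invariant under
constant energy shifts, and on quartic test potentials the uncertainty
shrinks monotonically and the barrier converges as the increment is
refined.

## The NQE pipeline

Nuclear quantum effects are estimated a posteriori, snapshot by
snapshot: five snapshots at constant time intervals (endpoint
inclusive; the convention is this package's, as is `n = 1` taking the
final frame), proton positions on the circle through donor, proton and
acceptor (a straight segment when colinear within 1e-6 Å), energies
from a backend, a degree-9 polynomial fit, a grid solution of the 1D
vibrational Schrödinger equation, and a Boltzmann average of the
position operator.

Numerical choices worth recording:

* **Arc sampling.**  Positions are parameterized by donor-proton
  distance, uniformly from 0.80 Å to $d_\mathrm{OO} - 0.80$ Å, with
  $N = 16 + \mathrm{clamp}(\mathrm{round}((d_\mathrm{OO}-2.40)/0.05),
  0, 4)$ points — 16 to 20 depending on bridge length.  The margins and
  the count rule are this package's concrete instantiation of
  "a handful more points for longer bridges", and are overridable.
* **Polynomial conditioning and confinement.**  The degree-9 fit is
  performed in $u = (d - d_\mathrm{mid})/\mathrm{halfrange} \in [-1,1]$;
  outside the sampled range the potential continues as
  $V(\mathrm{endpoint}) + \kappa (d-\mathrm{endpoint})^2$ with
  $\kappa = 200$ kcal/mol/Å², because an unconstrained degree-9
  polynomial routinely dives to $-\infty$ inside the solver domain.
  The continuation is continuous in value (not in slope); the solver
  never sees the discontinuous derivative as an eigenvalue artefact at
  the 0.01 cm⁻¹ level checked by grid doubling.
* **Solver.**  A sine-DVR (particle-in-a-box discrete variable
  representation) on 400 interior points of [0.7, 2.0] Å with Dirichlet
  boundaries: the kinetic operator is exact in the sine basis, giving
  spectral accuracy for confined states.  Validation: box levels exact
  to 1e-10, a 3000 cm⁻¹ harmonic fundamental to <0.1 cm⁻¹, Morse
  ladders to <0.02 cm⁻¹ of the closed form, <0.01 cm⁻¹ movement on
  grid doubling, and <1 cm⁻¹ agreement with an independent dense
  finite-difference solver.  A warning fires if the ground state
  carries more than 1e-3 probability in the outermost grid cells.
* **Mass and thermal weighting.**  The default mass is the bare proton
  (1.0078 amu); an O-H reduced mass is a defensible alternative and is
  exposed in `solver_settings()` rather than hard-wired.  The thermal
  average uses Boltzmann weights over the three lowest levels at 295 K;
  both counts are settings, and the average is invariant under adding
  a constant to all energies.

```{r nqe-demo}
sol <- solve_bound_states(function(d) 35 * (1 - exp(-2.5 * (d - 1.1)))^2,
                          solver_settings())
sol
thermal_expectation(sol)
```

## Validation problem sizes

The shipped test-suite and acceptance script validate on deliberately
modest problems: quadrature grids of ~1200 x 500 points, a single 1 ns
low-barrier Langevin run (4 x 10^6 steps, stored every 10th frame) for
ergodicity, a 60 ps run at 100 K for the normal-mode/spectrum
comparison, 400-point (against 800- and 1500-point) eigensolves, and
2048-lag spectra.  At these sizes simulated possession fractions match
quadrature to well under 2 percentage points and the mean O...O
distance to under 0.001 Å, comfortably inside the ±5 pp / ±0.02 Å
bands asserted by the tests.

## Known limitations

* The surrogate has no crystal environment, no periodic boundary
  conditions, and no electronic structure; it reproduces regimes, not
  compound-specific numbers.
* Classical spectra carry no quantum correction factors, and no
  dipole-derived IR intensities are computed.
* The NQE treatment is strictly one-dimensional along the arc
  coordinate; multidimensional tunnelling and path-integral effects are
  out of scope.
* `derive_velocities()` uses one-sided differences at the two end
  frames, a documented bias accepted to keep series lengths aligned.
* Atom and frame indices are 1-based throughout, as everywhere in R;
  files produced by 0-based tools need their bridge definitions shifted
  by one.
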