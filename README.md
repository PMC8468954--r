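# hbridge

Analysis of intramolecular O–H···O hydrogen-bridge proton dynamics:
surrogate double-well Langevin trajectories, Voronoi proton-possession
statistics, transfer-event detection, velocity-autocorrelation power
spectra, discrete proton-potential scan analysis, and an a posteriori
nuclear-quantum-effects (NQE) workflow built on a 1D grid Schrödinger
solver.

## The problem and who this is for

Short, resonance-assisted O–H···O bridges (the naphthazarin family is
the archetype) hold a proton in an asymmetric double-well potential: it
resides mostly on the donor oxygen, hops repeatedly to the acceptor
side, and produces extremely broad O–H stretch bands.  The trajectories
that reveal this behaviour usually come from first-principles molecular
dynamics, but everything one *computes from* a trajectory — residence
fractions, event counts, correlation histograms, power spectra, barrier
analyses, quantum corrections — is engine-independent.  This package
implements that analysis layer for R, together with a cheap surrogate
simulator so the whole pipeline is testable without a quantum-chemistry
code.  It is aimed at computational chemists post-processing ab initio
MD of hydrogen-bonded systems, and at method developers who need a
controlled, fully reproducible test bed.

## The model at the core

Each bridge is reduced to the donor–proton distance *r* and the
donor–acceptor distance *R*, with potential

    V(r,R) = D_d [1 − exp(−a_d (r − ρ))]²
           + D_a [1 − exp(−a_a (R − r − ρ))]²
           + ½ k_R (R − R_0)²

— two opposed Morse wells plus a harmonic breathing restraint — and a
bilinear coupling λ q₁q₂ between the two bridges of a molecule, where
q_b = r_b − R_b/2 is the signed Voronoi coordinate.  Propagation is
BAOAB Langevin dynamics at 295 K (dt = 0.25 fs, seeded and bitwise
reproducible).  The proton is assigned to donor or acceptor by the
Voronoi criterion (d_DH vs d_HA); the vibrational spectrum is the
one-sided cosine transform of the windowed velocity autocorrelation
function; and quantum corrections are obtained per snapshot by fitting
a degree-9 polynomial to arc-sampled proton energies and solving the
1D vibrational Schrödinger equation in a sine-DVR basis (400 grid
points on 0.7–2.0 Å), then Boltzmann-averaging ⟨r⟩ over the three
lowest levels.

## Worked example

```r
library(hbridge)

params <- model_params()
characterize_model(params, R_fixed = 2.55)
#> Proton profile at fixed R = 2.55 A:
#>   deep minimum    r = 0.9963 A
#>   shallow minimum r = 1.5470 A (asymmetry 1.414 kcal/mol)
#>   barrier         4.769 kcal/mol at r = 1.2897 A

run <- simulate_bridges(params, simulation_settings(production_length = 100,
                                                    output_stride = 2, seed = 11))
traj <- embed_trajectory(run)
bridges <- embedded_bridge_definitions()
possession_statistics(compute_bridge_series(traj, bridges[[1]]))
#> Proton possession (Voronoi criterion, 200001 frames):
#>   donor     89.5%  (179006 frames)
#>   acceptor  10.5%  (20995 frames)

sol <- solve_bound_states(function(d) 35 * (1 - exp(-2.5 * (d - 1.1)))^2,
                          solver_settings())
sol
#> Vibrational solution (400 grid points on [0.70, 2.00] A, m = 1.0078 amu)
#>   level 0: E =      0.00 cm^-1,  <r> = 1.1287 A
#>   level 1: E =   2053.46 cm^-1,  <r> = 1.1909 A
#>   level 2: E =   3897.84 cm^-1,  <r> = 1.2614 A
#>   level 3: E =   5533.31 cm^-1,  <r> = 1.3422 A
#>   level 4: E =   6966.57 cm^-1,  <r> = 1.4305 A
```

The profile shows the donor-side minimum near 1 Å, a ~5 kcal/mol
barrier and a shallow acceptor-side well; a 100 ps room-temperature run
then spends ≈90 % of its time on the donor — the gas-phase regime of
these compounds.  The vibrational solution illustrates the solver on an
anharmonic Morse well: a compressed level ladder and per-state ⟨r⟩
values drifting outward with excitation.

A command-line wrapper is installed with the package
(`system.file("exec", "hbridge", package = "hbridge")`), exposing
`simulate`, `distances`, `possession`, `events`, `hist2d`, `sync`,
`spectrum`, `scan` and `nqe` subcommands over XYZ trajectory files.

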