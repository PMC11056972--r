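---
title: "Adaptive quantum-proton placement in multicomponent Hartree-Fock: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive quantum-proton placement in multicomponent Hartree-Fock: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`neoadapt` implements the nuclear-electronic orbital (NEO) ansatz at the
restricted Hartree-Fock level.  Selected hydrogen nuclei ("quantum
protons") are treated on the same footing as the electrons: the total
wavefunction is a product of an electronic and a protonic Slater
determinant, each expanded in atom-centered contracted Gaussian bases.  The
two determinants are coupled only through the Coulomb interaction between
the electronic and protonic one-particle densities; electron-proton
correlation is not included, so protonic densities are systematically
overlocalized and energies are qualitative.  This is a property of the
mean-field ansatz itself, not of the implementation.

The atomic centers split into two sets.  Classical nuclei enter the
Hamiltonian as point charges.  Quantum centers are *placeholders for basis
functions only*: the proton's charge acts through its density, never
through the point-charge list.  The energy therefore depends on where the
quantum centers are placed — this extended potential-energy surface
E(r_q, r_c) only turns into the physically meaningful standard NEO surface
E(r_c) once the quantum-center positions satisfy dE/dr_q = 0.

The package's central feature is the adaptive relocation scheme that
reaches that stationary surface *inside* the SCF cycle, without gradients:
after every converged nuclear subcycle, each occupied nuclear orbital is
assigned to a quantum center (maximum-Mulliken-population bipartite
matching, ties broken by center index) and the center is moved to the
orbital's charge centroid ⟨phi|r|phi⟩.  Both the protonic shells and that
atom's electronic shells ride along, since they share one center object.
The iteration is a heuristic fixed point, not a variational step: centroid
stationarity and energy stationarity coincide only for flexible enough
bases and gently anharmonic wells, which is why the package ships a
numerical-gradient optimizer as an independent oracle (`optimize_rq()`)
and asserts agreement on a fixture where the two must coincide.

## The stepwise SCF

`run_neo_scf()` alternates macrocycles of (i) nuclear Roothaan-Hall
subcycles converged at fixed electronic density and (ii) electronic cycles
converged at fixed protonic density.  Convergence of a stage requires the
energy change, RMS density change and Frobenius norm of the orbital
gradient FDS−SDF to fall below their thresholds; the calculation stops
when additionally the macrocycle energy change is below its own threshold
(and, in adaptive mode, the largest centroid displacement is below the
position threshold).  The interleaving granularity — converging each
electronic stage fully rather than taking single electronic iterations —
is a deliberate choice; the stage caps (`max_nuclear`, `max_electronic`,
`max_macro`) are settings.

Defaults (all configurable through `scf_settings()` /
`adaptive_settings()`):

| parameter | default | unit | meaning |
|---|---|---|---|
| `e_conv`, `d_conv`, `g_conv` | 1e-8 | au | subcycle energy / RMS density / gradient thresholds |
| `neo_e_conv` | 1e-6 | hartree | macrocycle energy change |
| `position_threshold` | 1e-5 | Bohr | largest centroid displacement |
| `diis_depth` | 10 | — | Fock matrices kept for Pulay extrapolation |
| `damping_factor` | 1 | — | centroid step scaling (1 = undamped) |
| proton mass | 1836.15267343 | m_e | CODATA value |

DIIS starts after the first iteration of each stage, with separate
histories per species.  Two numerical guards depart from the plain
textbook recipe: near-converged histories are linearly dependent, so the
oldest entries are dropped until the Pulay system is solvable (falling
back to the latest Fock matrix when nothing remains), and the error-overlap
block is rescaled before solving — the rescaling affects only the Lagrange
multiplier, not the extrapolation weights.  Orbitals come from canonical
orthogonalization; overlap eigenvalues below 1e-10 are projected out, which
makes duplicated basis functions harmless.

Electron counts must be even (closed-shell restricted treatment).  A
single electron is additionally supported as an exact special case — one
occupied orbital, no same-species two-electron terms — because the
one-proton/one-electron atom is the natural variational benchmark: its
exact ground-state energy with a clamped center of mass is −mu/2 =
−0.49972784 hartree (mu the electron-proton reduced mass), a strict lower
bound that any finite-basis mean-field energy must stay above.  Multiple
quantum protons occupy distinct spatial orbitals; the same-species Coulomb
term is kept and proton-proton exchange omitted, and with a single quantum
proton the same-species term is absent entirely (no self-interaction).

## Integrals

All integrals (overlap, kinetic, point-charge, position, and the ee/ep/pp
Coulomb tensors) are evaluated over contracted Cartesian Gaussians by a
compiled McMurchie-Davidson engine (Hermite expansion coefficients plus a
Boys-function downward recursion, series below x = 35 and the erf closed
form above).  Solid-harmonic (spherical) combinations are applied for
d functions and higher; the transformation rows are generated from the
solid-harmonic recurrences at load time, and every contracted function is
rescaled to unit self-overlap, which makes the whole pipeline independent
of primitive-normalization conventions.  Kinetic matrices carry the
1/mass factor of the species; point-charge matrices are attractive for
electrons and repulsive for protons; cross-species Coulomb tensors are
stored as positive kernels with signs applied in the Fock builds.

After any center move *all* position-dependent quantities are rebuilt,
including two-particle tensors — the moved center carries electronic
functions, so no tensor is safely stale.  This favors correctness over the
one-particle-only update that integral-direct engines can afford.

The test suite checks every integral class against quadrature oracles that
share no code with this engine: Gauss-Hermite rules (exact for
polynomial-times-Gaussian integrands) for overlap/kinetic/position, and a
kernel-transform representation of 1/r (a 1-D mapped Gauss-Legendre
integral over Gaussian-kernel inner integrals) for the Coulomb classes.

## The numerical-gradient oracle

`numerical_gradient()` uses central differences (default step 1e-3 Bohr)
of fully converged NEO-SCF energies at tightened thresholds (1e-10 au), so
finite-difference noise stays orders of magnitude below the step;
displaced points are warm-started from the reference densities.
`optimize_rq()` wraps BFGS over the quantum-center coordinates and
declares convergence at gradient norm < 1e-5 hartree/Bohr and step <
1e-4 Bohr.  Any convergent quasi-Newton would do; BFGS with these
thresholds reproduces the adaptive fixed point of the hydrogen-bond
fixture to ~4e-4 Å and ~5e-9 hartree.

## Fixtures: what they emulate and what they do not

The bundled fixtures are chosen so every property the package claims is
checkable on one CPU in seconds to a few minutes:

* `h_atom` — one quantum proton, one electron, no classical nuclei;
  exercises the variational bound and the one-electron special case.
* `h2_1q` — H2 with one quantum proton at the standard 1.4 Bohr
  separation; the cheap workhorse for equivariance and bookkeeping tests.
  Its covalent well is strongly anharmonic, so the centroid fixed point
  deliberately does *not* double as an energy-minimum oracle here.
* `hehhe_cation` — symmetric linear [He-H-He]+ (He at ±2.0 Bohr): the
  midpoint is an exact fixed point by symmetry, and off-center starts must
  contract back to it.
* `hbond_toy` — a stretched low-barrier hydrogen bond, [He-H-He]+ with
  He-He = 3.85 Bohr, weakly asymmetrized by a third helium 7.2 Bohr past
  the acceptor.  Three properties were designed in deliberately: the
  quantum proton sits in a single well (midpoint curvature positive); the
  *classical*-proton curve is double-welled with an off-center minimum, so
  quantizing the proton visibly shifts the scan minimum toward the
  hydrogen-bond midpoint; and the asymmetry is weak, because the
  centroid-vs-gradient agreement degrades linearly with odd (cubic)
  anharmonicity — at this geometry the two optima agree to ~5e-4 Å while
  the quantum/classical minimum shift stays ~0.1 Å.

The fixture electronic sets (`neo-svp`, an even-tempered 5s1p set for H
and He) and protonic sets (`pb-et` = 8s8p, `pb-et-d` = 6s6p6d, both
even-tempered with exponents spanning 2–64 Bohr⁻²) are package-defined and
documented as such; they keep the suite self-contained and fast.  The
upper end of the protonic exponent range follows the published
even-tempered convention; the lower end (2) is a package choice.  Published
protonic sets (PB4-D and relatives) are not redistributed here but load
from user-supplied files in the common block format, and production-grade
electronic sets (cc-pVTZ etc.) load the same way.  What passing tests show
is therefore that the machinery — integrals, coupled SCF, centroid
updates, gradients — is correct at fixture scale; they do not certify
chemical accuracy for real systems, which additionally needs the published
bases and, beyond mean field, electron-proton correlation.

## Numerical choices and degenerate inputs

* Initial guesses: electronic density from core-Hamiltonian
  diagonalization, protonic from diagonalizing T_p + V_p; warm-start
  densities can be injected (`init =`), and converged results are
  guess-independent to the SCF tolerance.
* Centroid updates are applied after each *converged* nuclear subcycle,
  undamped by default; `damping_factor` < 1 is available for oscillatory
  cases but the bundled systems never need it.
* A single adaptive displacement above 1 Bohr aborts with a runaway
  diagnostic rather than relocating a center into a different basin.
* At an exactly symmetric stationary point the centroid displacement is
  zero and the procedure converges in place; the method is Hessian-free
  and cannot distinguish a symmetric minimum from a symmetric saddle.
* Degenerate localized nuclear levels make the orbital-to-center
  assignment ambiguous; populations below 0.5 trigger a warning naming
  the centers.
* In double-well regimes the iteration converges to the basin of the
  starting point; no basin hopping is attempted, mirroring the intended
  use (refining a chosen structure, not global search).

## Problem sizes

The default test and acceptance runs use 2–32 electronic and 32–54
protonic spherical functions per system, scan grids of about a dozen
points, and three-start determinism checks; these sizes were chosen so
that each fixture property is established by fully converged calculations
in well under the stated per-fixture minute budgets on a single CPU.

## Known limitations

Restricted electrons only (even counts, plus the exact one-electron
case); quantum nuclei restricted to protons (the particle mass is a
single constant; deuterium would need only a configurable mass but is
untested and therefore unexposed); no electron-proton correlation, no
NEO-DFT, no analytic gradients, no density fitting; classical nuclei are
never optimized.
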