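---
title: "Two-fragment embedding with channel-resolved second-order perturbation theory: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-fragment embedding with channel-resolved second-order perturbation theory: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements, of
the tunable parameters, and of the numerical and design choices made where
the design was genuinely open. Every empirical statement here is one that
the test suite or `scripts/acceptance.R` computes.

## The model

The electronic Hamiltonian restricted to an active orbital space, in
chemists' notation and spin-adapted operators,

$$H = E_\mathrm{core} + \sum_{pq} h_{pq} E_{pq}
      + \tfrac12 \sum_{pqrs} (pq|rs)\, e_{pqrs},$$

is split over a user-chosen bipartition of the active orbitals into
fragments $A$ and $B$. The wave function is constrained to a product
$|\Psi^0\rangle = |\Psi_A\rangle \otimes |\Psi_B\rangle$ in which each
factor carries a fixed electron number and spin projection $S_z$. This is
an *ansatz*, not a symmetry: charge transfer and spin exchange between
fragments are exactly what it discards, and what the perturbative step
restores.

**Mean-field embedding.** Among the interfragment terms, those conserving
local charge and spin combine into
$\sum W_{abcd} E^A_{ab} E^B_{cd}$ with the generalized coulomb-exchange
coupling $W_{abcd} = (ab|cd) - \tfrac12 (ad|cb)$ (the $-\tfrac12$ exchange
part is the spin-singlet component of the interfragment exchange terms
after fermionic normal ordering). Substituting
$E \to \langle E\rangle + \delta E$ yields one-body embedding potentials
$f^A = W\,\gamma^B$, $f^B = W^\top \gamma^A$, a scalar double-counting
shift $\gamma^A\!\cdot\!W\!\cdot\!\gamma^B$, and a pure
fluctuation–fluctuation remainder (the dispersion channel). Alternating
exact diagonalization of $H_A + f^A[\gamma_B]$ and $H_B + f^B[\gamma_A]$
is exact block-coordinate descent on the product-state energy, so the
logged energy is non-increasing; convergence is declared on the energy
*and* the 1-RDMs, since the energy alone can mask oscillation between
near-degenerate solutions.

**Channels.** The residual interaction splits exactly into

* dispersion: $\sum W_{abcd}\, \delta E^A_{ab}\, \delta E^B_{cd}$;
* single charge transfer, resolved by direction ($A\!\to\!B$ and
  $B\!\to\!A$), with three-fermion fragment operators grouped as
  $a^\dagger_{p\sigma} E_{rs}$ and $E_{rs} a_{q\sigma}$ so that matrix
  elements factorize;
* double charge transfer: creation pairs on one fragment times
  annihilation pairs on the other;
* triplet–triplet spin exchange: the spin-triplet remainder of the
  exchange terms, i.e. products of one-body triplet tensor operators
  ($m = \pm 1$ spin-flip pairs and the $m=0$ spin-difference operators)
  on the two fragments.

The decomposition is an operator identity,
$H = H_A + H_B + V_\mathrm{mf} - \mathrm{shift} + \sum_c H'_c$, and the
test suite enforces it by building every term densely on small models
(max deviation below $10^{-10}$). This identity is what makes the
internal normalization conventions of the triplet split immaterial for
the total energy.

**Partially contracted second order.** For each channel
$H'_c = \sum g_{\mu\nu} O^A_\mu O^B_\nu$, the perturbing family
$\Phi_{\mu\nu} = O^A_\mu O^B_\nu |\Psi^0\rangle$ (kept only where
$g_{\mu\nu} \ne 0$) spans the space in which
$(M - E^0 S)\,C = -V$, $V = S g$, is solved; $e_2^{(c)} = C\cdot V$.
Because $H^0$ is a sum of fragment operators and $\Psi^0$ its
eigenstate, $S$ and $M - E^0S$ factorize into small per-fragment Gram and
Hamiltonian matrices over the distinct fragment operators; members are
stored implicitly as pairs of fragment sector vectors with their fermionic
crossing phases. Members living in the reference sector (dispersion, and
the $m=0$ spin-exchange family) are projected orthogonal to $\Psi^0$; the
projection is a rank-one metric correction and leaves $M - E^0S$
untouched because $\Psi^0$ is an $H^0$ eigenstate.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `tol_e` | 1e-9 Ha | embedding energy stationarity |
| `tol_rdm` | 1e-7 | max-abs 1-RDM change; guards against energy-flat oscillation |
| `max_iter` | 100 | embedding sweep cap; non-convergence raises a condition carrying the log |
| `damping` | 0 | RDM mixing `(1-d) new + d old`; a non-monotone undamped run retries once at 0.5 |
| `fci_cap` | 1e6 | largest sector (determinant count) the fragment solver accepts; below 2000 determinants the solver is dense, above it Davidson |
| `metric_threshold` | 1e-10 | relative overlap eigenvalue below which contracted members are discarded (standard practice for near-linearly-dependent contracted bases) |
| `ambiguous_threshold` | 0.7 | Mulliken population below which a localized orbital counts as a cross-cut bond/antibond; clean localized orbitals sit above 0.9, a shared sigma bond near 0.5 |
| `n_valence_virt` | requested actives + 2 | virtual orbitals entering localization; the margin lets each fragment find its antibonding shell even when the partner's levels interleave |

The convergence thresholds of the embedding loop are engineering choices
(nothing in the underlying formulation prescribes them); they are exposed
through `run_pipeline()` and the command line.

## Numerical choices

* **Spin sectors.** Fragment constraints are enforced as fixed $S_z$, the
  natural choice for determinant FCI solvers. Total-$S$ purity is not
  enforced; for every closed-shell test system the fragment ground states
  come out spin-pure, which is also what makes the first-order energies
  of the spin-exchange channel vanish. Both diagnostics (the five
  first-order energies) are computed and reported per run.
* **Phases.** Spin-orbital ordering is (all A: alpha then beta, then all
  B); all parity phases — inside fragments, for the B-operator crossing
  of fragment A, and between the fragment-blocked and global orderings —
  are fixed by this convention and validated against dense operator
  construction in the tests. CI phase fixing: the largest-magnitude
  coefficient (ties: smallest determinant index) is made positive.
* **Degeneracies.** The dense fragment solver computes a second root and
  warns when the gap falls below 1e-8. Degenerate frontier shells in the
  SCF are filled fractionally (spherically/spin-averaged), which both
  prevents symmetry-broken saddle points (the bare-core guess of N2
  otherwise converges 0.7 Ha too high) and provides the atomic references
  used for basis contraction.
* **High-order RDMs.** The single-charge-transfer zeroth-order matrix
  elements would require five-particle transition RDMs if assembled from
  stored density matrices; the implementation instead applies effective
  fragment Hamiltonians and operators directly to sector CI vectors,
  which is mathematically identical and avoids ten-index tensors.
  Explicit `compute_rdms()` is provided up to order 4 under a memory cap.
* **Basis sets.** STO-3G, 6-31G and cc-pVDZ are shipped as plain text in
  the Cartesian (6d) convention. The nitrogen cc-pVDZ general-contraction
  coefficients are regenerated with the package's spherically averaged
  atomic Hartree–Fock in the published primitive set (the transcribed
  literature coefficients proved lossy; the regenerated contraction
  reproduces the uncontracted-basis N2 RHF energy to 3.6 mHa, against
  2 mHa for the published contraction). The engine itself is validated
  against tabulated RHF energies (N2 STO-3G and 6-31G*, H2 STO-3G and
  cc-pVDZ) and against numeric quadrature oracles for d-function
  integrals.

## The synthetic model generator

`model_hamiltonian()` emulates two weakly coupled, weakly correlated
molecular fragments: per-fragment one-electron ladders anchored at the
fragment's own filling (HOMO near $-1$, LUMO near $0$ Ha, spacing 1.0, a
0.07 offset making the fragments inequivalent), a dominant on-site
repulsion of 0.5 on the diagonal two-electron elements, weak random
symmetric noise (s.d. 0.08 one-electron, 0.04 two-electron), and *all*
interfragment integrals scaled by a coupling $\lambda$. The anchoring
makes interfragment charge transfer uphill — as it is between neutral
molecules — so the zeroth-order Hamiltonian keeps its ground state in the
reference sector and perturbation denominators stay positive. What the
ensemble does **not** emulate: strong static correlation inside a
fragment (level spacing beats the repulsion, so fragments are
closed-shell-like), near-degenerate charge states, and realistic integral
sparsity. Passing tests on this ensemble therefore certify the operator
algebra, the factorized assembly and the perturbative machinery — not the
behavior of the method on strongly correlated real molecules, which the
N2-dimer benchmark probes instead.

Problem sizes used by the default suite and the acceptance script: the
seeded ensemble uses 2+2 and 3+3 orbital fragments (combined spaces up to
400 determinants, small enough for every dense oracle); the N2-dimer
benchmark uses the 1.2/1.6/2.0 Å desk points of the bond scan with the
full 853776-determinant CASCI reference at each point.

## Known limitations

* **Occupied-span-preserving localization.** The fragment orbitals are
  built by Pipek–Mezey rotations *within* the occupied and
  valence-virtual blocks, so the occupied projector of the mean field is
  preserved exactly (a module invariant, tested). The price appears when
  the supermolecular occupied space itself mixes the fragments: for the
  N2 dimer at 2.0 Å separation with the right bond stretched to 2.0 Å,
  the best reachable fragment populations drop to ~0.77, and the
  resulting tails inflate the interfragment exchange integrals. The
  embedding error then grows to tens of mHa and the spin-exchange channel
  becomes the largest second-order term, while at the 1.2 Å equilibrium
  the same channel is three orders of magnitude below dispersion and
  single charge transfer. A fragment-reference-based localization (as in
  intrinsic/reference fragment orbital schemes) would relax exactly this
  restriction; it is out of scope here.
* The partially contracted basis is kept in full; strongly contracted or
  stochastic variants, cumulant/RI compression of density matrices,
  more than two fragments, and excitations into the frozen core or
  external virtuals are not implemented.
* The perturbative step assumes the reference product sector is the
  ground sector of $H^0$; intruder-state-like situations are detected
  (non-positive-definite reduced zeroth-order matrix, near-singular
  dense resolvent) and reported loudly rather than regularized.
* RHF is the only mean field; open-shell molecules are handled only as
  spherically averaged atomic references, not as production references.
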