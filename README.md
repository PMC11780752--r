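# fragpt2

Two-fragment active-space embedding with perturbative interfragment
interactions, in R.

## The problem

Multiconfigurational (CAS-type) wave-function methods treat electron
correlation exactly inside an active space, but their cost grows
exponentially with its size. When a molecule splits naturally into two
weakly entangled fragments — two stacked monomers, two aromatic rings
joined by a single bond, the two halves of a polyene — one can instead
give *each fragment its own active space*, solve each fragment exactly in
the mean field of the other, and bring the neglected interfragment
correlation back perturbatively. This package implements that program for
two fragments, for computational chemists who want both the energies and a
physically labelled decomposition of the interfragment correlation.

The method, in the field's standard notation:

1. **Fragment orbitals.** Canonical RHF orbitals are localized
   (Pipek–Mezey over fragment Mulliken populations, occupied and valence
   virtual blocks separately), assigned to fragments A/B (with a bias rule
   sending an ambiguous bond/antibond pair across a covalent cut to the
   first fragment), recanonicalized by block-diagonalizing the Fock matrix
   within each fragment block, and selected into per-fragment active
   spaces by quasi-energy. The frozen occupied rest is contracted into the
   core energy and one-electron integrals.
2. **Mean-field embedding.** With the active Hamiltonian
   `H = E_core + Σ h_pq E_pq + ½ Σ (pq|rs) e_pqrs` and the ansatz
   `|Ψ⁰⟩ = |Ψ_A⟩ ⊗ |Ψ_B⟩` (fixed local charge and Sz), the
   charge/spin-conserving interfragment terms
   `Σ W_abcd E_ab E_cd`, `W_abcd = (ab|cd) − ½ (ad|cb)`, are decoupled by
   `E → ⟨E⟩ + δE`. Alternating exact (FCI) solves of
   `H_X + V_mf^X[γ_other]` minimize the product-state energy `E⁰`
   monotonically; the scalar double-counting shift `γ_A·W·γ_B` keeps the
   bookkeeping exact.
3. **Channel-resolved PT2.** The residual interaction splits exactly into
   dispersion (`δE⊗δE`), directional single charge transfer, double
   charge transfer, and triplet–triplet spin exchange (the spin-triplet
   remainder of the exchange terms). For each channel
   `H'_c = Σ g_μν O_μ^A O_ν^B`, the partially contracted basis
   `Φ_μν = O_μ^A O_ν^B |Ψ⁰⟩` defines the first-order equations
   `(M − E⁰S) C = −V`, solved after canonical orthogonalization of the
   overlap metric; `e2_c = C·V ≤ 0` and
   `E = E⁰ + Σ_c e2_c`. All matrices factorize over fragments, so only
   fragment-local operator applications and small Gram matrices are ever
   formed.

Everything is validated against brute-force oracles built from dense
linear algebra: full CASCI in the combined active space, dense
uncontracted second-order resolvents, and exact operator reconstruction
`H = H_A + H_B + V_mf − shift + Σ_c H'_c`.

The package also ships the infrastructure this needs when no quantum
chemistry backend is present: a Gaussian AO-integral engine
(McMurchie–Davidson, Cartesian up to d), a restricted Hartree–Fock solver
with DIIS, determinant FCI solvers (dense and Davidson), an FCIDUMP
interface, and seeded synthetic two-fragment model Hamiltonians.

## A worked example

Two parallel N2 molecules 2.0 Å apart (cc-pVDZ, one 6-electron/6-orbital
active space per molecule — the σ/π bonding and antibonding shells):

```r
library(fragpt2)
geom <- n2_dimer_geometry(separation = 2.0, bond_left = 1.2,
                          bond_right = 1.2)
rec <- run_pipeline(list(geometry = geom, basis = "cc-pvdz",
                         active = list(A = c(3, 3), B = c(3, 3)),
                         bias_first_fragment = FALSE, oracle = TRUE))
rec[c("e_hf_reference", "e0", "e2", "e_total", "e_exact")]
```

prints (Hartree):

```
$e_hf_reference  -217.6853562
$e0              -217.8730246
$e2
  dispersion -0.0020895;  ct1_AtoB -0.0027875;  ct1_BtoA -0.0027875
  ct2        -0.0000157;  tt       -0.0000249
$e_total         -217.8807097
$e_exact         -217.8819320
```

Reading: Hartree–Fock misses 0.197 Ha of active-space correlation; the
embedded product state recovers all but 8.9 mHa of it; second order brings
the remaining error to 1.2 mHa. The correction is dominated by single
charge transfer and dispersion, while double charge transfer and
triplet–triplet spin exchange are three orders of magnitude smaller —
the channel decomposition identifies which physical processes couple the
fragments. All five first-order energies vanish (< 1e-30 here), as they
must on a converged product state.

The same record is produced from the shell:

```sh
Rscript inst/cli/fragpt2.R make-fixture --seed 1 --lambda 0.2 --out model
Rscript inst/cli/fragpt2.R run --fcidump model.fcidump \
    --partition model.partition --oracle --out result.json
```

## Scope and caveats

- Exactly two fragments; real integrals; no point-group exploitation.
- Localization preserves the occupied span, so for strongly interacting
  or stretched systems the active orbitals can stay partially
  delocalized; see the methods vignette for what this does to the channel
  decomposition.
- cc-pVDZ is shipped in the Cartesian (6d) convention, with nitrogen
  contraction coefficients regenerated by the package's spherically
  averaged atomic HF (see `inst/extdata/basis/cc-pvdz.bas` and the
  vignette).
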