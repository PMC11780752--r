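# Pipek-Mezey localization, fragment assignment, recanonicalization and
# active-space selection.

h2_dimer_scf <- function(sep = 40) {
  cached(sprintf("h2dimer_%g", sep), {
    mol <- molecule(rep("H", 4), rbind(c(0, 0, 0), c(0, 0, 0.74),
                                       c(sep, 0, 0), c(sep, 0, 0.74)))
    rhf(mol, "sto-3g", tol = 1e-11)
  })
}

test_that("disjoint subsystems localize to pure fragment orbitals", {
  scf <- h2_dimer_scf()
  ao_frag <- rep(c("A", "B"), each = 2)
  loc <- pipek_mezey_localize(scf$C[, 1:2], scf$ints$S, ao_frag)
  pops <- fragpt2:::mulliken_populations(loc$C, scf$ints$S, ao_frag)
  expect_true(all(apply(pops, 1, max) > 0.99))
  # ascent property: the metric never decreases across sweeps
  expect_true(all(diff(loc$trace) > -1e-12))
})

test_that("localization rejects non-orthonormal input", {
  scf <- h2_dimer_scf()
  C_bad <- scf$C[, 1:2]; C_bad[, 1] <- C_bad[, 1] * 1.5
  expect_error(pipek_mezey_localize(C_bad, scf$ints$S,
                                    rep(c("A", "B"), each = 2)),
               "orthonormal")
})

test_that("the metric ascends on a genuinely delocalized input", {
  # single H2 with the two atoms in different fragments: canonical orbitals
  # are fully delocalized, the localizer must still move uphill monotonically
  mol <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  scf <- rhf(mol, "sto-3g")
  loc <- pipek_mezey_localize(scf$C, scf$ints$S, c("A", "B"))
  expect_true(all(diff(loc$trace) > -1e-12))
})

test_that("fragment assignment follows the population and the bias rule", {
  scf <- h2_dimer_scf()
  ao_frag <- rep(c("A", "B"), each = 2)
  loc <- pipek_mezey_localize(scf$C[, 1:2], scf$ints$S, ao_frag)
  asg <- assign_fragments(loc$C, scf$ints$S, ao_frag)
  expect_setequal(asg$fragment_of, c("A", "B"))
  # a sigma bond across the cut (single H2 split into two fragments) is
  # ambiguous (population ~0.5); the bias sends bond and antibond to A
  mol <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  scf2 <- rhf(mol, "sto-3g")
  asg2 <- assign_fragments(scf2$C, scf2$ints$S, c("A", "B"),
                           bias_first_fragment = TRUE)
  expect_lt(max(asg2$population), 0.7)
  expect_equal(asg2$fragment_of, c("A", "A"))
  # a clearly one-sided orbital is never biased away from its fragment
  scfd <- h2_dimer_scf()
  locd <- pipek_mezey_localize(scfd$C[, 1:2], scfd$ints$S,
                               rep(c("A", "B"), each = 2))
  asg3 <- assign_fragments(locd$C, scfd$ints$S, rep(c("A", "B"), each = 2),
                           bias_first_fragment = TRUE)
  expect_setequal(asg3$fragment_of, c("A", "B"))
  expect_true(all(asg3$population > 0.9))
})

test_that("recanonicalization diagonalizes the Fock blocks", {
  scf <- h2_dimer_scf(sep = 8)
  ao_frag <- rep(c("A", "B"), each = 2)
  loc <- pipek_mezey_localize(scf$C[, 1:2], scf$ints$S, ao_frag)
  asg <- assign_fragments(loc$C, scf$ints$S, ao_frag)
  rec <- recanonicalize(scf$F_AO, loc$C, asg$fragment_of)
  for (f in unique(asg$fragment_of)) {
    sel <- which(asg$fragment_of == f)
    Fs <- t(rec$C[, sel, drop = FALSE]) %*% scf$F_AO %*%
      rec$C[, sel, drop = FALSE]
    expect_lt(max(abs(Fs - diag(diag(Fs), nrow(Fs)))), 1e-9)
    expect_equal(diag(Fs), rec$quasi_energy[sel], tolerance = 1e-10)
  }
  # single-orbital block: unchanged, quasi-energy is the Fock expectation
  one <- recanonicalize(scf$F_AO, loc$C[, 1, drop = FALSE], "A")
  expect_equal(abs(one$C), abs(loc$C[, 1, drop = FALSE]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(one$quasi_energy,
               as.numeric(t(loc$C[, 1]) %*% scf$F_AO %*% loc$C[, 1]))
})

test_that("non-interacting dimer reproduces monomer orbital energies", {
  # 500 A separation: even the quadrupole field of the neighbor (which at
  # 40 A still shifts orbital energies by ~1e-7) is negligible
  scf <- h2_dimer_scf(500)
  mono <- cached("h2_mono", rhf(molecule(c("H", "H"),
                                         rbind(c(0, 0, 0), c(0, 0, 0.74))),
                                "sto-3g", tol = 1e-11))
  orbs <- localize_orbitals(scf, list(A = 1:2, B = 3:4),
                            n_valence_virt = 2)
  for (f in c("A", "B")) {
    qe_occ <- orbs$quasi_energy[orbs$fragment_of == f &
                                  orbs$block == "occupied"]
    qe_vv <- orbs$quasi_energy[orbs$fragment_of == f &
                                 orbs$block == "valence_virtual"]
    expect_equal(qe_occ, mono$eps[1], tolerance = 1e-8)
    expect_equal(qe_vv, mono$eps[2], tolerance = 1e-8)
  }
  # occupied span is preserved through the pipeline
  Pold <- tcrossprod(scf$C[, 1:2])
  sel <- orbs$block == "occupied"
  Pnew <- tcrossprod(orbs$C[, sel])
  expect_lt(max(abs(scf$ints$S %*% (Pold - Pnew) %*% scf$ints$S)), 1e-8)
})

test_that("active-space selection enforces availability and edge cases", {
  scf <- h2_dimer_scf()
  orbs <- localize_orbitals(scf, list(A = 1:2, B = 3:4), n_valence_virt = 2)
  expect_error(select_active_space(orbs, list(A = c(2, 1), B = c(1, 1))),
               "lacks")
  sel0 <- select_active_space(orbs, list(A = c(0, 1), B = c(1, 1)))
  expect_equal(sel0$partition$n_elec[["A"]], 0L)
  expect_equal(sel0$partition$n_elec[["B"]], 2L)
})

test_that("the full pipeline on separated fragments is exactly separable", {
  scf <- h2_dimer_scf()
  fas <- fragment_active_space(scf, list(A = 1:2, B = 3:4),
                               active = list(A = c(1, 1), B = c(1, 1)),
                               n_valence_virt = 2)
  mono <- cached("h2_mono", rhf(molecule(c("H", "H"),
                                         rbind(c(0, 0, 0), c(0, 0, 0.74))),
                                "sto-3g"))
  h1 <- t(mono$C) %*% mono$ints$hcore %*% mono$C
  g1 <- ao2mo(mono$ints$eri, mono$C)
  Hm <- active_hamiltonian((h1 + t(h1)) / 2, fragpt2:::symmetrize8(g1),
                           mono$ints$e_nuc)
  e_mono <- full_casci(Hm, 2, 0)$e_exact
  ps <- self_consistent_product_state(fas$hamiltonian, fas$partition)
  expect_equal(ps$e0, 2 * e_mono, tolerance = 1e-8)
})

test_that("active integrals: full space equals backend FCI; frozen core is
          exact against a core-restricted dense diagonalization", {
  # H2O / STO-3G
  mol <- molecule(c("O", "H", "H"),
                  rbind(c(0, 0, 0.1173), c(0, 0.7572, -0.4692),
                        c(0, -0.7572, -0.4692)))
  scf <- cached("h2o_scf", rhf(mol, "sto-3g"))
  # no frozen core, full MO space
  Hfull <- build_active_integrals(scf, scf$C)
  e_full <- full_casci(Hfull, 10, 0)$e_exact
  expect_lt(e_full, scf$energy)
  # rotating active orbitals leaves the CASCI energy invariant
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(49), 7, 7)))
  Hrot <- build_active_integrals(scf, scf$C %*% Q)
  expect_equal(full_casci(Hrot, 10, 0)$e_exact, e_full, tolerance = 1e-9)
  # freeze the O 1s: compare against the dense full-space Hamiltonian
  # restricted to determinants with a doubly occupied core orbital
  Hfz <- build_active_integrals(scf, scf$C[, 2:7, drop = FALSE],
                                scf$C[, 1, drop = FALSE])
  e_fz <- full_casci(Hfz, 8, 0)$e_exact
  space <- fragpt2:::sector_space(7, 5, 5)
  Hd <- fragpt2:::build_sector_hamiltonian(Hfull$h, Hfull$g, space)
  core_occ <- bitwAnd(space$astr, 1L) == 1L
  keep <- as.vector(outer(core_occ, core_occ, `&`))
  Hsub <- Hd[keep, keep]
  e_ref <- min(eigen(Hsub, symmetric = TRUE, only.values = TRUE)$values) +
    Hfull$e_core
  expect_equal(e_fz, e_ref, tolerance = 1e-9)
})
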