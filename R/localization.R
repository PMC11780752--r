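# Fragment-localized orbitals: Pipek-Mezey localization over fragment
# Mulliken populations, fragment assignment with the bond/antibond bias,
# Fock-block recanonicalization, quasi-energy active-space selection and
# frozen-core contraction of the integrals.

# gross Mulliken population of each orbital (columns of C) on each fragment
mulliken_populations <- function(C, S, ao_frag) {
  SC <- S %*% C
  w <- C * SC                      # per-AO contributions
  t(rowsum(w, ao_frag))            # orbitals x fragments
}

#' Pipek-Mezey localization over fragment populations
#'
#' Jacobi-sweep maximization of `sum_i sum_F Q_iF^2`, the sum of squared
#' gross Mulliken populations of each orbital on each fragment.  The metric
#' is non-decreasing at every rotation; sweeps stop when the total gain of a
#' sweep falls below `tol`.
#'
#' @param C_block orthonormal orbital coefficients (one occupation block)
#' @param S_AO AO overlap matrix
#' @param ao_frag character/factor: fragment label of each AO
#' @param tol convergence threshold on the metric gain per sweep
#' @param max_sweeps sweep cap
#' @return list with rotated coefficients `C`, final `metric` and the
#'   per-sweep metric trace
#' @export
pipek_mezey_localize <- function(C_block, S_AO, ao_frag, tol = 1e-10,
                                 max_sweeps = 300L) {
  k <- ncol(C_block)
  ortho <- max(abs(t(C_block) %*% S_AO %*% C_block - diag(k)))
  if (ortho > 1e-7) stop("input orbitals are not orthonormal (deviation ",
                         format(ortho), ")")
  if (k < 2) {
    pops <- mulliken_populations(C_block, S_AO, ao_frag)
    return(list(C = C_block, metric = sum(pops^2), trace = sum(pops^2)))
  }
  C <- C_block
  frg <- unique(ao_frag)
  SC <- S_AO %*% C
  metric <- function() {
    pops <- mulliken_populations(C, S_AO, ao_frag)
    sum(pops^2)
  }
  trace <- metric()
  for (sweep in seq_len(max_sweeps)) {
    gain_total <- 0
    for (s in 1:(k - 1)) for (t in (s + 1):k) {
      Qss <- Qtt <- Qst <- numeric(length(frg))
      for (fi in seq_along(frg)) {
        sel <- ao_frag == frg[fi]
        Qss[fi] <- sum(C[sel, s] * SC[sel, s])
        Qtt[fi] <- sum(C[sel, t] * SC[sel, t])
        Qst[fi] <- 0.5 * sum(C[sel, s] * SC[sel, t] + C[sel, t] * SC[sel, s])
      }
      A <- sum(Qst^2 - 0.25 * (Qss - Qtt)^2)
      B <- sum(Qst * (Qss - Qtt))
      r <- sqrt(A * A + B * B)
      gain <- A + r
      if (gain < 1e-14 || r < 1e-14) next
      alpha <- 0.25 * atan2(B, -A)
      cs <- cos(alpha); sn <- sin(alpha)
      Cs <- cs * C[, s] + sn * C[, t]
      Ct <- -sn * C[, s] + cs * C[, t]
      C[, s] <- Cs; C[, t] <- Ct
      SCs <- cs * SC[, s] + sn * SC[, t]
      SCt <- -sn * SC[, s] + cs * SC[, t]
      SC[, s] <- SCs; SC[, t] <- SCt
      gain_total <- gain_total + gain
    }
    trace <- c(trace, metric())
    if (gain_total < tol) break
  }
  list(C = C, metric = utils::tail(trace, 1), trace = trace)
}

#' Assign localized orbitals to fragments
#'
#' Each orbital goes to the fragment carrying the larger gross Mulliken
#' population.  Orbitals delocalized across the cut (largest population
#' below `ambiguous_threshold`, e.g. a sigma bond/antibond between the
#' fragments) are assigned to fragment A when `bias_first_fragment` is set,
#' removing the arbitrariness for covalently bonded fragments.
#'
#' @param C_loc localized orbital coefficients
#' @param S_AO AO overlap
#' @param ao_frag fragment label of each AO
#' @param bias_first_fragment assign ambiguous bond/antibond pairs to A
#' @param ambiguous_threshold population below which an orbital counts as
#'   delocalized across the cut
#' @return list with `fragment_of` (labels) and `population` (largest
#'   fragment population per orbital)
#' @export
assign_fragments <- function(C_loc, S_AO, ao_frag,
                             bias_first_fragment = TRUE,
                             ambiguous_threshold = 0.7) {
  pops <- mulliken_populations(C_loc, S_AO, ao_frag)
  frg <- colnames(pops)
  if (is.null(frg)) frg <- unique(ao_frag)
  rel <- pops / rowSums(pops)
  lab <- frg[max.col(rel, ties.method = "first")]
  pmax_ <- apply(rel, 1, max)
  if (bias_first_fragment) lab[pmax_ < ambiguous_threshold] <- "A"
  list(fragment_of = lab, population = pmax_, populations = rel)
}

#' Recanonicalize localized orbitals within fragment blocks
#'
#' Rotates the orbitals within each (fragment x occupation-block) subset so
#' the projected Fock matrix is diagonal; the eigenvalues become
#' quasi-energies and orbitals are ordered by them within each subset.
#'
#' @param F_AO converged AO Fock matrix
#' @param C_loc localized orbital coefficients
#' @param groups factor combining fragment and occupation block
#' @return list with rotated `C` and `quasi_energy`
#' @export
recanonicalize <- function(F_AO, C_loc, groups) {
  C <- C_loc
  qe <- numeric(ncol(C))
  for (gr in unique(groups)) {
    sel <- which(groups == gr)
    Fs <- t(C[, sel, drop = FALSE]) %*% F_AO %*% C[, sel, drop = FALSE]
    ev <- eigen((Fs + t(Fs)) / 2, symmetric = TRUE)
    ord <- order(ev$values)
    C[, sel] <- C[, sel, drop = FALSE] %*% ev$vectors[, ord]
    qe[sel] <- ev$values[ord]
  }
  list(C = C, quasi_energy = qe)
}

#' Build the fragment-localized orbital set
#'
#' Localizes the occupied block and the lowest `n_valence_virt` virtuals
#' separately (higher virtuals are never localized), assigns fragments with
#' the bias rule and recanonicalizes per fragment block.
#'
#' @param scf an [rhf()] result
#' @param atom_fragments list `A`/`B` of atom indices defining the fragments
#' @param n_valence_virt number of valence virtual orbitals to localize
#' @param bias_first_fragment see [assign_fragments()]
#' @return object of class `localized_orbital_set`
#' @export
localize_orbitals <- function(scf, atom_fragments, n_valence_virt,
                              bias_first_fragment = TRUE) {
  ints <- scf$ints
  atom_frag <- rep(NA_character_, length(ints$mol$symbols))
  atom_frag[atom_fragments$A] <- "A"
  atom_frag[atom_fragments$B] <- "B"
  if (anyNA(atom_frag)) stop("every atom must belong to a fragment")
  ao_frag <- atom_frag[ints$ao_atom]
  nocc <- scf$nocc
  nvv <- n_valence_virt
  if (nocc + nvv > ncol(scf$C)) stop("not enough virtual orbitals")
  occ <- pipek_mezey_localize(scf$C[, seq_len(nocc), drop = FALSE],
                              ints$S, ao_frag)
  vv <- pipek_mezey_localize(scf$C[, nocc + seq_len(nvv), drop = FALSE],
                             ints$S, ao_frag)
  C <- cbind(occ$C, vv$C)
  block <- rep(c("occupied", "valence_virtual"), c(nocc, nvv))
  asg <- assign_fragments(C, ints$S, ao_frag, bias_first_fragment)
  rec <- recanonicalize(scf$F_AO, C, paste(asg$fragment_of, block))
  # populations after recanonicalization
  asg2 <- assign_fragments(rec$C, ints$S, ao_frag, bias_first_fragment)
  structure(list(C = rec$C, fragment_of = asg$fragment_of,
                 quasi_energy = rec$quasi_energy, block = block,
                 population = asg2$population,
                 occ_class = rep(NA_character_, ncol(C)),
                 scf = scf, ao_frag = ao_frag,
                 pm_trace = list(occupied = occ$trace,
                                 valence_virtual = vv$trace)),
            class = "localized_orbital_set")
}

#' @export
print.localized_orbital_set <- function(x, ...) {
  for (f in c("A", "B")) for (b in c("occupied", "valence_virtual")) {
    sel <- x$fragment_of == f & x$block == b
    cat(sprintf("  %s %-16s %2d orbitals, quasi-energies [%s]\n", f, b,
                sum(sel), paste(sprintf("%.3f", x$quasi_energy[sel]),
                                collapse = ", ")))
  }
  invisible(x)
}

#' Select per-fragment active spaces by quasi-energy
#'
#' Per fragment, the `n_occ` highest-quasi-energy occupied and the `n_virt`
#' lowest valence-virtual orbitals become active; each fragment then holds
#' `2 n_occ` active electrons.  Remaining occupied orbitals form the frozen
#' core.
#'
#' @param orbs a [localize_orbitals()] result
#' @param active list `A = c(n_occ, n_virt)`, `B = c(n_occ, n_virt)`
#' @return list with `partition` (a [fragment_partition()]), `active_idx`
#'   (columns of `orbs$C`, A block then B block, each ordered by
#'   quasi-energy), `frozen_idx` and the annotated orbital set
#' @export
select_active_space <- function(orbs, active) {
  act_idx <- integer(0)
  frag_lab <- character(0)
  n_elec <- c(A = 0L, B = 0L)
  for (f in c("A", "B")) {
    spec <- active[[f]]
    n_occ <- spec[1]; n_virt <- spec[2]
    occ_f <- which(orbs$fragment_of == f & orbs$block == "occupied")
    vv_f <- which(orbs$fragment_of == f & orbs$block == "valence_virtual")
    if (length(occ_f) < n_occ || length(vv_f) < n_virt)
      stop("fragment ", f, " lacks orbitals for the requested active space")
    occ_sel <- occ_f[order(orbs$quasi_energy[occ_f],
                           decreasing = TRUE)][seq_len(n_occ)]
    occ_sel <- occ_sel[order(orbs$quasi_energy[occ_sel])]
    vv_sel <- vv_f[order(orbs$quasi_energy[vv_f])][seq_len(n_virt)]
    act_idx <- c(act_idx, occ_sel, vv_sel)
    frag_lab <- c(frag_lab, rep(f, n_occ + n_virt))
    n_elec[f] <- 2L * n_occ
  }
  frozen_idx <- setdiff(which(orbs$block == "occupied"), act_idx)
  orbs$occ_class <- ifelse(seq_len(ncol(orbs$C)) %in% act_idx, "active",
                           ifelse(orbs$block == "occupied", "core", "virtual"))
  list(partition = fragment_partition(frag_lab, n_elec),
       active_idx = act_idx, frozen_idx = frozen_idx, orbitals = orbs)
}

#' Active-space integrals with frozen-core contraction
#'
#' Transforms the AO integrals to the active orbital basis; the frozen-core
#' orbitals contribute a mean-field addition to the one-electron integrals
#' and a scalar core energy (plus nuclear repulsion).
#'
#' @param scf an [rhf()] result
#' @param C_active AO x n_active coefficients
#' @param C_frozen AO x n_frozen coefficients (may have zero columns)
#' @return an [active_hamiltonian()]
#' @export
build_active_integrals <- function(scf, C_active, C_frozen = NULL) {
  ints <- scf$ints
  n <- ints$nao
  hcore <- ints$hcore
  if (is.null(C_frozen) || ncol(C_frozen) == 0) {
    h1 <- t(C_active) %*% hcore %*% C_active
    e_core <- ints$e_nuc
  } else {
    Pfz <- 2 * tcrossprod(C_frozen)
    env <- list2env(ints, parent = emptyenv())
    jk <- jk_build(env, Pfz)
    Ffz <- hcore + jk$J - 0.5 * jk$K
    h1 <- t(C_active) %*% Ffz %*% C_active
    e_core <- ints$e_nuc + 0.5 * sum(Pfz * (hcore + Ffz))
  }
  g <- ao2mo(ints$eri, C_active)
  active_hamiltonian((h1 + t(h1)) / 2, symmetrize8(g), e_core)
}

#' Geometry-mode front end: localized fragment active-space Hamiltonian
#'
#' Full pipeline from an SCF solution to the fragment active-space problem:
#' localization, fragment assignment, recanonicalization, quasi-energy
#' selection and frozen-core integral transformation.
#'
#' @param scf an [rhf()] result
#' @param atom_fragments list `A`/`B` of atom indices
#' @param active list `A = c(n_occ, n_virt)`, `B = c(n_occ, n_virt)`
#' @param n_valence_virt virtual orbitals entering localization (default:
#'   total requested active virtuals)
#' @param bias_first_fragment bond/antibond bias (see [assign_fragments()])
#' @return list with `hamiltonian`, `partition`, `orbitals`, `selection`
#' @export
fragment_active_space <- function(scf, atom_fragments, active,
                                  n_valence_virt = NULL,
                                  bias_first_fragment = TRUE) {
  # a slightly wider window than the active request lets the localization
  # form clean fragment orbitals even when one fragment's antibonding
  # levels drop into the other's virtual manifold (e.g. stretched bonds)
  if (is.null(n_valence_virt))
    n_valence_virt <- min(active$A[2] + active$B[2] + 2L,
                          ncol(scf$C) - scf$nocc)
  orbs <- localize_orbitals(scf, atom_fragments, n_valence_virt,
                            bias_first_fragment)
  sel <- select_active_space(orbs, active)
  H <- build_active_integrals(scf, orbs$C[, sel$active_idx, drop = FALSE],
                              orbs$C[, sel$frozen_idx, drop = FALSE])
  list(hamiltonian = H, partition = sel$partition, orbitals = sel$orbitals,
       selection = sel)
}
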