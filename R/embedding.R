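# Self-consistent product-state embedding: each fragment's active space is
# solved exactly in the one-body mean field of the other fragment, iterating
# to the lowest-energy product state that conserves local charge and Sz.

# Generalized coulomb-exchange coupling W_abcd = (ab|cd) - 1/2 (ad|cb)
# as an (nA^2 x nB^2) matrix over (ab), (cd) pairs (column-major pair index).
interfragment_W <- function(H, partition) {
  iA <- partition$idx_A; iB <- partition$idx_B
  nA <- length(iA); nB <- length(iB)
  gJ <- H$g[iA, iA, iB, iB, drop = FALSE]
  gK <- aperm(H$g[iA, iB, iB, iA, drop = FALSE], c(1, 4, 3, 2))
  matrix(gJ - 0.5 * gK, nA * nA, nB * nB)
}

#' Effective fragment Hamiltonian in the partner's mean field
#'
#' Adds to the bare fragment one-electron integrals the one-body embedding
#' potential generated by the other fragment's 1-RDM through the generalized
#' coulomb-exchange coupling (coulomb minus half exchange), and reports the
#' double-counting scalar when the fragment's own 1-RDM is supplied.
#'
#' @param h_local bare one-electron integrals of the fragment
#' @param W coupling matrix from the interfragment integrals
#'   (`nA^2 x nB^2`, see [decompose_hamiltonian()])
#' @param gamma_other 1-RDM of the other fragment (local indexing)
#' @param side `"A"` (uses `W`) or `"B"` (uses `t(W)`)
#' @param gamma_self optional own 1-RDM; when given, `e_shift` is the
#'   mean-field double-counting scalar `gamma_self . W . gamma_other`
#' @return list with `h_eff`, `f` (the embedding potential) and `e_shift`
#' @export
build_effective_hamiltonian <- function(h_local, W, gamma_other,
                                        side = c("A", "B"),
                                        gamma_self = NULL) {
  side <- match.arg(side)
  n <- nrow(h_local)
  if (max(abs(gamma_other - t(gamma_other))) > 1e-8)
    stop("gamma_other is not hermitian")
  Wuse <- if (side == "A") W else t(W)
  if (ncol(Wuse) != length(gamma_other))
    stop("shape mismatch between W and gamma_other")
  f <- matrix(Wuse %*% as.numeric(gamma_other), n, n)
  f <- (f + t(f)) / 2
  e_shift <- if (is.null(gamma_self)) 0 else
    sum(as.numeric(gamma_self) * as.numeric(f))
  list(h_eff = h_local + f, f = f, e_shift = e_shift)
}

aufbau_rdm <- function(norb, na, nb) {
  d <- as.numeric(seq_len(norb) <= na) + as.numeric(seq_len(norb) <= nb)
  diag(d, norb)
}

#' Self-consistent fragment product state
#'
#' Alternating exact solves of the two coupled fragment Hamiltonians, each in
#' the frozen mean field of the other fragment, until the product-state
#' energy and both 1-RDMs are stationary.  Each half-step minimizes the total
#' energy over one fragment's CI vector, so the logged energy is
#' non-increasing; a non-monotone step (numerical) with no damping triggers
#' one retry with damping 0.5.
#'
#' @param H an [active_hamiltonian()]
#' @param partition a [fragment_partition()]
#' @param tol_e energy convergence threshold (Hartree)
#' @param tol_rdm max-abs 1-RDM change threshold
#' @param max_iter maximum sweeps
#' @param damping RDM damping d in `[0, 1)`: `gamma <- (1-d) new + d old`
#' @param fci_cap maximum sector dimension for the fragment solver
#' @param dense_cap dimension below which the fragment solver is dense
#' @return object of class `product_state`
#' @export
self_consistent_product_state <- function(H, partition, tol_e = 1e-9,
                                          tol_rdm = 1e-7, max_iter = 100L,
                                          damping = 0, fci_cap = 1e6,
                                          dense_cap = 2000) {
  stopifnot(H$n_orb == partition$n_orb, damping >= 0, damping < 1)
  iA <- partition$idx_A; iB <- partition$idx_B
  nA <- length(iA); nB <- length(iB)
  hA <- H$h[iA, iA, drop = FALSE]; gA <- H$g[iA, iA, iA, iA, drop = FALSE]
  hB <- H$h[iB, iB, drop = FALSE]; gB <- H$g[iB, iB, iB, iB, drop = FALSE]
  W <- interfragment_W(H, partition)
  secA <- fragment_sector(partition, "A")
  secB <- fragment_sector(partition, "B")
  spA <- sector_space(nA, secA[["na"]], secA[["nb"]])
  spB <- sector_space(nB, secB[["na"]], secB[["nb"]])
  tbA <- if (spA$dim <= dense_cap && spA$dim > 1) sector_two_body(gA, spA) else NULL
  tbB <- if (spB$dim <= dense_cap && spB$dim > 1) sector_two_body(gB, spB) else NULL

  solve_frag <- function(h_eff, g_loc, sec, n, tb) {
    fci_solve_sector(h_eff, g_loc, 0, n, sec[["na"]], sec[["nb"]],
                     n_roots = 1L, fci_cap = fci_cap, dense_cap = dense_cap,
                     two_body = tb)
  }

  run <- function(damping) {
    gmA <- aufbau_rdm(nA, secA[["na"]], secA[["nb"]])
    gmB <- aufbau_rdm(nB, secB[["na"]], secB[["nb"]])
    log <- data.frame(iter = integer(0), e0 = numeric(0),
                      d_e = numeric(0), d_rdm = numeric(0))
    e_prev <- NA_real_
    psiA <- NULL; psiB <- NULL
    for (it in seq_len(max_iter)) {
      effA <- build_effective_hamiltonian(hA, W, gmB, "A")
      psiA <- solve_frag(effA$h_eff, gA, secA, nA, tbA)
      gA_new <- rdm1(psiA)
      d_rdm_A <- max(abs(gA_new - gmA))
      gmA <- (1 - damping) * gA_new + damping * gmA
      effB <- build_effective_hamiltonian(hB, W, gmA, "B")
      psiB <- solve_frag(effB$h_eff, gB, secB, nB, tbB)
      gB_new <- rdm1(psiB)
      d_rdm_B <- max(abs(gB_new - gmB))
      gmB <- (1 - damping) * gB_new + damping * gmB
      # energy of the current product state (exact RDMs, not damped)
      eA_bare <- psiA$energy - sum(effA$f * gA_new)
      eB_bare <- psiB$energy - sum(effB$f * gB_new)
      cross <- as.numeric(t(as.numeric(gA_new)) %*% W %*% as.numeric(gB_new))
      e0 <- eA_bare + eB_bare + cross + H$e_core
      d_e <- if (is.na(e_prev)) Inf else e0 - e_prev
      log <- rbind(log, data.frame(iter = it, e0 = e0, d_e = d_e,
                                   d_rdm = max(d_rdm_A, d_rdm_B)))
      if (!is.na(e_prev) && abs(d_e) < tol_e &&
          max(d_rdm_A, d_rdm_B) < tol_rdm) {
        return(list(psiA = psiA, psiB = psiB, gmA = gA_new, gmB = gB_new,
                    e0 = e0, log = log, converged = TRUE,
                    monotone = all(log$d_e[-1] < 1e-10)))
      }
      e_prev <- e0
    }
    list(psiA = psiA, psiB = psiB, gmA = gA_new, gmB = gB_new, e0 = e_prev,
         log = log, converged = FALSE, monotone = all(log$d_e[-1] < 1e-10))
  }

  res <- run(damping)
  if (!res$converged || !res$monotone) {
    if (damping == 0) {
      res2 <- run(0.5)
      if (res2$converged && (!res$converged || res2$e0 <= res$e0 + 1e-12))
        res <- res2
    }
  }
  if (!res$converged)
    stop(structure(class = c("convergence_error", "error", "condition"),
                   list(message = paste0(
                     "product-state embedding did not converge in ",
                     max_iter, " sweeps (last |dE| = ",
                     format(utils::tail(abs(res$log$d_e), 1)), ")"),
                     call = sys.call(), log = res$log)))

  # final consistency pass with the converged partner RDMs
  effA <- build_effective_hamiltonian(hA, W, res$gmB, "A")
  psiA <- solve_frag(effA$h_eff, gA, secA, nA, tbA)
  gmA <- rdm1(psiA)
  effB <- build_effective_hamiltonian(hB, W, gmA, "B")
  psiB <- solve_frag(effB$h_eff, gB, secB, nB, tbB)
  gmB <- rdm1(psiB)
  psiA$fragment <- "A"; psiB$fragment <- "B"
  shift <- as.numeric(t(as.numeric(gmA)) %*% W %*% as.numeric(gmB))
  epsA <- psiA$energy   # <H_A + V_mf^A>
  epsB <- psiB$energy
  eA_bare <- epsA - sum(effA$f * gmA)
  eB_bare <- epsB - sum(effB$f * gmB)
  e0 <- eA_bare + eB_bare + shift + H$e_core

  # degeneracy diagnostic on the dense path
  gap <- NA_real_
  if (sector_space(nA, secA[["na"]], secA[["nb"]])$dim <= dense_cap ||
      sector_space(nB, secB[["na"]], secB[["nb"]])$dim <= dense_cap) {
    gap <- Inf
    for (side in c("A", "B")) {
      sp <- if (side == "A") spA else spB
      if (sp$dim < 2 || sp$dim > dense_cap) next
      roots <- fci_solve_sector(if (side == "A") effA$h_eff else effB$h_eff,
                                if (side == "A") gA else gB, 0,
                                sp$norb, sp$na, sp$nb, n_roots = 2L,
                                fci_cap = fci_cap, dense_cap = dense_cap,
                                two_body = if (side == "A") tbA else tbB)
      gap <- min(gap, roots[[2]]$energy - roots[[1]]$energy)
    }
    if (is.finite(gap) && gap < 1e-8)
      warning("near-degenerate fragment ground state (gap ", format(gap), ")")
  }

  structure(list(psi_A = psiA, psi_B = psiB,
                 gamma_A = gmA, gamma_B = gmB,
                 h_eff_A = effA$h_eff, h_eff_B = effB$h_eff,
                 f_A = effA$f, f_B = effB$f,
                 eps_A = epsA, eps_B = epsB,
                 e0 = e0, mf_shift = shift, e_core = H$e_core,
                 W = W, partition = partition,
                 iteration_log = res$log, gap = gap),
            class = "product_state")
}

#' @export
print.product_state <- function(x, ...) {
  cat(sprintf("<product_state> e0 = %.10f Hartree (%d sweeps, shift %.8f)\n",
              x$e0, nrow(x$iteration_log), x$mf_shift))
  invisible(x)
}

#' Energy of the single-determinant product reference
#'
#' Expectation value of the Hamiltonian on the aufbau determinant of each
#' fragment (the uncorrelated product reference bounding the embedding energy
#' from above).
#' @param H an [active_hamiltonian()]
#' @param partition a [fragment_partition()]
#' @return energy in Hartree
#' @export
reference_determinant_energy <- function(H, partition) {
  iA <- partition$idx_A; iB <- partition$idx_B
  secA <- fragment_sector(partition, "A")
  secB <- fragment_sector(partition, "B")
  det_state <- function(n, na, nb) {
    sp <- sector_space(n, na, nb)
    st <- sector_state(sp)
    ia <- match(sum(bitwShiftL(1L, seq_len(na) - 1L)), sp$astr)
    ib <- match(sum(bitwShiftL(1L, seq_len(nb) - 1L)), sp$bstr)
    st$coef[ia, ib] <- 1
    st
  }
  stA <- det_state(length(iA), secA[["na"]], secA[["nb"]])
  stB <- det_state(length(iB), secB[["na"]], secB[["nb"]])
  hA <- H$h[iA, iA, drop = FALSE]; gAl <- H$g[iA, iA, iA, iA, drop = FALSE]
  hB <- H$h[iB, iB, drop = FALSE]; gBl <- H$g[iB, iB, iB, iB, drop = FALSE]
  W <- interfragment_W(H, partition)
  gmA <- rdm1(stA); gmB <- rdm1(stB)
  sector_expectation_h(stA, hA, gAl) + sector_expectation_h(stB, hB, gBl) +
    as.numeric(t(as.numeric(gmA)) %*% W %*% as.numeric(gmB)) + H$e_core
}
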