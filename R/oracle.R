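# Brute-force references: full CASCI in the combined active space and dense
# uncontracted second-order perturbation theory.  Pure dense linear algebra,
# sharing no code with the factorized path beyond the type definitions.

#' Exact ground-state energy in the combined active space
#'
#' Full CI over all active orbitals at fixed total electron number and Sz.
#' Small spaces are diagonalized densely; larger ones use the compiled
#' Davidson solver.
#'
#' @param H an [active_hamiltonian()]
#' @param n_elec_total total electron count
#' @param ms2 total 2*Sz
#' @param fci_cap resource cap on the determinant count
#' @return list with `e_exact` and the sector dimension
#' @export
full_casci <- function(H, n_elec_total, ms2 = 0L, fci_cap = 2e6) {
  na <- (n_elec_total + ms2) %/% 2L
  nb <- (n_elec_total - ms2) %/% 2L
  wf <- fci_solve_sector(H$h, H$g, H$e_core, H$n_orb, na, nb,
                         fci_cap = fci_cap)
  list(e_exact = wf$energy, dim = wf$space$dim, wavefunction = wf)
}

#' Uncontracted second-order energies by dense resolvent
#'
#' For each requested channel: project `H'_c |Psi0>` on the orthogonal
#' complement of `Psi0`, solve `(H0 - E0) x = -Q H'_c Psi0` densely and
#' return `e2 = <Psi0| H'_c |x>`.  `channel = "all"` treats the summed
#' perturbation in one shot (including any cross-channel coupling).
#'
#' @param decomp a [decompose_hamiltonian()] result
#' @param psi0 a converged [self_consistent_product_state()] result
#' @param channel channel name, vector of names, or `"all"`
#' @param cap dense-space size guard
#' @return named vector of second-order energies (element `all` for the
#'   summed perturbation), with attribute `dim` (combined space size)
#' @export
uncontracted_pt2 <- function(decomp, psi0,
                             channel = c("dispersion", "ct1_AtoB",
                                         "ct1_BtoA", "ct2", "tt", "all"),
                             cap = 2e4) {
  part <- decomp$partition
  H <- decomp$hamiltonian
  na <- sum(vapply(c("A", "B"), function(f) fragment_sector(part, f)[["na"]], 0L))
  nb <- sum(vapply(c("A", "B"), function(f) fragment_sector(part, f)[["nb"]], 0L))
  space <- sector_space(H$n_orb, na, nb)
  if (space$dim > cap) stop("combined space too large for the dense oracle")
  H0 <- dense_h0_matrix(decomp, space)
  psi <- embed_product(as_state(psi0$psi_A), as_state(psi0$psi_B), H$n_orb)
  v0 <- as.numeric(psi$coef)
  v0 <- v0 / sqrt(sum(v0^2))
  e0 <- as.numeric(t(v0) %*% H0 %*% v0)
  A <- H0 - e0 * diag(space$dim) + tcrossprod(v0)
  # guard: smallest complement eigenvalue of (H0 - e0)
  evs <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(evs) < 1e-10)
    stop("(H0 - E0) is near-singular on the complement of Psi0 ",
         "(smallest eigenvalue ", format(min(evs)), ")")
  dense_channel <- function(ch) {
    if (ch == "all") {
      Reduce(`+`, lapply(decomp$channels, dense_operator_matrix,
                         space = space, cap = cap))
    } else {
      dense_operator_matrix(decomp$channels[[ch]], space, cap = cap)
    }
  }
  out <- stats::setNames(numeric(length(channel)), channel)
  for (ch in channel) {
    Hp <- dense_channel(ch)
    r <- as.numeric(Hp %*% v0)
    rq <- r - sum(r * v0) * v0
    x <- solve(A, -rq)
    out[ch] <- sum(r * x)
  }
  attr(out, "space_dim") <- space$dim
  out
}
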