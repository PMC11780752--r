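# Exact diagonalization in fixed (n_orb, n_alpha, n_beta) sectors, with
# reduced density matrices and transition densities.

#' Solve a determinant sector exactly
#'
#' Lowest eigenstate(s) of the spin-free Hamiltonian
#' `e_shift + sum h_pq E_pq + 1/2 sum (pq|rs) e_pqrs` in a fixed
#' (n_orb, n_alpha, n_beta) sector.  Small sectors are diagonalized densely;
#' larger ones use a Davidson solver (compiled).  The CI phase is fixed
#' deterministically: the largest-magnitude coefficient (ties broken by the
#' lexicographically smallest determinant, alpha-string major) is made
#' positive.
#'
#' @param h one-electron integrals (norb x norb), Hartree
#' @param g two-electron integrals (pq|rs), chemists' convention
#' @param e_shift scalar energy offset (core energy), Hartree
#' @param norb,na,nb sector definition
#' @param n_roots number of roots (dense path only for > 1 unless small)
#' @param fci_cap maximum sector dimension (resource guard)
#' @param dense_cap dimension below which dense diagonalization is used
#' @param two_body optional precomputed [sector_two_body()] matrix
#' @return for `n_roots = 1` a `sector_wavefunction`; otherwise a list of them
#' @export
fci_solve_sector <- function(h, g, e_shift, norb, na, nb, n_roots = 1L,
                             fci_cap = 1e6, dense_cap = 2000,
                             two_body = NULL) {
  space <- sector_space(norb, na, nb)
  if (is.null(space)) stop("empty sector: invalid electron counts")
  if (space$dim > fci_cap)
    stop("sector dimension ", space$dim, " exceeds fci_cap = ", fci_cap)
  if (space$dim == 1L) {
    st <- sector_state(space, matrix(1, 1, 1))
    e <- sector_expectation_h(st, h, g) + e_shift
    wf <- new_sector_wavefunction(st, e)
    return(if (n_roots > 1L) list(wf) else wf)
  }
  if (space$dim <= dense_cap) {
    H <- build_sector_hamiltonian(h, g, space, two_body = two_body)
    ev <- eigen(H, symmetric = TRUE)
    k <- min(n_roots, space$dim)
    roots <- lapply(seq_len(k), function(i) {
      v <- ev$vectors[, space$dim - i + 1L]
      st <- sector_state(space, matrix(v, space$n_astr, space$n_bstr))
      new_sector_wavefunction(fix_phase(st),
                              ev$values[space$dim - i + 1L] + e_shift)
    })
    return(if (n_roots > 1L) roots else roots[[1L]])
  }
  # iterative path
  res <- fci_davidson_cpp(h, as.numeric(g), norb, na, nb,
                          nroots = as.integer(n_roots),
                          tol = 1e-5, max_iter = 150L)
  roots <- lapply(seq_len(n_roots), function(i) {
    st <- sector_state(space, matrix(res$vectors[, i],
                                     space$n_astr, space$n_bstr))
    new_sector_wavefunction(fix_phase(st), res$values[i] + e_shift)
  })
  if (n_roots > 1L) roots else roots[[1L]]
}

# deterministic phase: largest |coef|, ties -> smallest linear index, positive
fix_phase <- function(state) {
  v <- as.numeric(state$coef)
  i <- which(abs(v) > max(abs(v)) - 1e-12)[1L]
  if (v[i] < 0) state$coef <- -state$coef
  state
}

new_sector_wavefunction <- function(state, energy, fragment = NA_character_) {
  structure(list(space = state$space, coef = state$coef, energy = energy,
                 fragment = fragment,
                 n_orb_local = state$space$norb,
                 n_alpha = state$space$na, n_beta = state$space$nb),
            class = "sector_wavefunction")
}

#' @export
print.sector_wavefunction <- function(x, ...) {
  cat(sprintf(
    "<sector_wavefunction>%s %d orbitals, (%d alpha, %d beta), dim %d, E = %.10f\n",
    if (is.na(x$fragment)) "" else paste0(" fragment ", x$fragment),
    x$n_orb_local, x$n_alpha, x$n_beta, x$space$dim, x$energy))
  invisible(x)
}

as_state <- function(wf) list(space = wf$space, coef = wf$coef)

# <psi| H(h,g) |psi> without the shift
sector_expectation_h <- function(state, h, g) {
  norb <- state$space$norb
  e <- 0
  for (p in seq_len(norb)) for (q in seq_len(norb)) {
    if (p > q) next
    x <- apply_Epq(state, p, q)
    w <- state_dot(state, x)
    e <- e + if (p == q) h[p, q] * w else 2 * h[p, q] * w
  }
  # two-body via 2-RDM
  G2 <- rdm2(state)
  e + 0.5 * sum(g * G2)
}

#' One-particle reduced density matrix
#'
#' Spatial (spin-summed) 1-RDM, `gamma_pq = <E_pq>`; trace equals the
#' electron count, eigenvalues lie in `[0, 2]`.
#' @param psi a `sector_wavefunction` or sector state
#' @return norb x norb matrix
#' @export
rdm1 <- function(psi) {
  st <- if (inherits(psi, "sector_wavefunction")) as_state(psi) else psi
  norb <- st$space$norb
  gmm <- matrix(0, norb, norb)
  for (p in seq_len(norb)) for (q in seq_len(norb)) {
    if (p > q) next
    x <- apply_Epq(st, p, q)
    gmm[p, q] <- state_dot(st, x)
    gmm[q, p] <- gmm[p, q]
  }
  gmm
}

#' Two-particle reduced density matrix
#'
#' Spatial 2-RDM in chemists' ordering: `Gamma_pqrs = <e_pqrs>` with
#' `e_pqrs = E_pq E_rs - delta_qr E_ps`, so that
#' `E_2body = 1/2 sum (pq|rs) Gamma_pqrs`.
#' @param psi a `sector_wavefunction` or sector state
#' @return norb^4 array
#' @export
rdm2 <- function(psi) {
  st <- if (inherits(psi, "sector_wavefunction")) as_state(psi) else psi
  norb <- st$space$norb
  n2 <- norb * norb
  # columns: E_rs |psi> for all rs
  X <- vector("list", n2)
  for (r in seq_len(norb)) for (s in seq_len(norb))
    X[[(r - 1L) * norb + s]] <- apply_Epq(st, r, s)
  G <- array(0, c(norb, norb, norb, norb))
  for (p in seq_len(norb)) for (q in seq_len(norb)) {
    Epq_dag_psi <- X[[(q - 1L) * norb + p]]  # E_pq^+ = E_qp
    for (r in seq_len(norb)) for (s in seq_len(norb)) {
      v <- state_dot(Epq_dag_psi, X[[(r - 1L) * norb + s]])
      if (q == r) v <- v - state_dot(st, X[[(p - 1L) * norb + s]])
      G[p, q, r, s] <- v
    }
  }
  G
}

#' General k-particle (transition) reduced density matrices
#'
#' Spin-orbital RDM elements
#' `<bra| a^+_{P1} ... a^+_{Pk} a_{Qk} ... a_{Q1} |ket>` for all index tuples;
#' bra and ket may live in different sectors (transition RDMs; sectors may
#' differ by up to two electrons).  Spin-orbitals are indexed 1..2*norb with
#' all alpha before all beta.  Guarded by a memory cap since the tensor has
#' `(2 norb)^(2k)` entries.
#'
#' @param bra,ket sector wavefunctions on the same orbital set
#' @param order k (1..4)
#' @param max_entries resource cap on the tensor size
#' @return array with 2k dimensions of extent 2*norb
#' @export
compute_rdms <- function(bra, ket = bra, order = 1L, max_entries = 2e6) {
  stopifnot(order >= 1L, order <= 4L)
  bst <- if (inherits(bra, "sector_wavefunction")) as_state(bra) else bra
  kst <- if (inherits(ket, "sector_wavefunction")) as_state(ket) else ket
  nso <- 2L * kst$space$norb
  if (nso^(2 * order) > max_entries)
    stop("k-RDM of order ", order, " on ", nso,
         " spin-orbitals exceeds the resource cap")
  so <- function(i) {
    # spin-orbital index -> (orbital, spin)
    norb <- kst$space$norb
    if (i <= norb) c(i, 1L) else c(i - norb, 2L)
  }
  dims <- rep(nso, 2 * order)
  G <- array(0, dims)
  idx <- as.matrix(expand.grid(rep(list(seq_len(nso)), 2 * order)))
  for (row in seq_len(nrow(idx))) {
    tup <- idx[row, ]
    ops <- matrix(0L, 0, 3)
    for (j in seq_len(order)) {
      pq <- so(tup[j])
      ops <- rbind(ops, c(pq[1], pq[2], 1L))
    }
    for (j in seq(2 * order, order + 1L)) {
      pq <- so(tup[j])
      ops <- rbind(ops, c(pq[1], pq[2], 0L))
    }
    x <- apply_opstring(kst, ops)
    if (!is.null(x)) G[row] <- state_dot(bst, x)
  }
  G
}
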