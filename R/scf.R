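# Restricted Hartree-Fock with DIIS, on top of the built-in AO integrals.

# J and K builds from the full in-core ERI tensor
jk_build <- function(ints, P) {
  n <- ints$nao
  gm <- matrix(ints$eri, n * n, n * n)
  J <- matrix(gm %*% as.numeric(P), n, n)
  if (is.null(ints$.gk)) {
    ints$.gk <- matrix(aperm(ints$eri, c(1, 3, 2, 4)), n * n, n * n)
  }
  K <- matrix(ints$.gk %*% as.numeric(P), n, n)
  list(J = J, K = K)
}

#' Restricted Hartree-Fock
#'
#' Closed-shell SCF with DIIS acceleration on the built-in integrals.
#'
#' @param mol a [molecule()] or `molecular_geometry`
#' @param basis basis-set name
#' @param ints optional precomputed [ao_integrals()]
#' @param tol convergence threshold on the Fock-density commutator residual
#' @param max_iter SCF iteration cap
#' @param diis_start iteration at which DIIS extrapolation begins
#' @param damp density damping factor applied before DIIS takes over
#' @param level_shift virtual-orbital level shift (Hartree); retried
#'   automatically with damping and a shift if the first attempt oscillates
#' @return object of class `scf_result`: orbital coefficients `C`, energies
#'   `eps`, total `energy`, converged Fock matrix and the integrals
#' @export
rhf <- function(mol = NULL, basis = "sto-3g", ints = NULL, tol = 1e-8,
                max_iter = 200L, diis_start = 2L, damp = 0,
                level_shift = 0) {
  if (is.null(ints)) ints <- ao_integrals(as_molecule(mol), basis)
  attempt <- function(...) tryCatch(rhf_run(ints, tol, max_iter, ...),
                                    error = function(e) e)
  out <- attempt(diis_start, damp, level_shift)
  if (inherits(out, "error")) {
    # retry ladder for oscillating cases (e.g. stretched bonds)
    out <- attempt(8L, 0.6, 0.3)
    if (inherits(out, "error")) out <- attempt(14L, 0.8, 1.0)
    if (inherits(out, "error")) stop(out)
  }
  out
}

rhf_run <- function(ints, tol = 1e-8, max_iter = 200L, diis_start = 2L,
                    damp = 0, level_shift = 0) {
  n <- ints$nao
  nelec <- ints$mol$n_elec
  # odd electron counts are handled as spherically/spin-averaged fractional
  # occupations of the frontier shell (used e.g. for atomic references)
  ne2 <- nelec / 2
  nocc <- as.integer(ceiling(ne2))
  S <- ints$S; H <- ints$hcore
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-9)
    warning("near-linear-dependent AO basis (smallest overlap eigenvalue ",
            format(min(es$values)), ")")
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  # core guess
  Fm <- H
  e_old <- Inf; P_old <- matrix(0, n, n)
  err_list <- list(); fock_list <- list()
  energy <- NA_real_; C <- NULL; eps <- NULL; P <- NULL
  # local mutable copy so jk_build can cache the exchange-permuted tensor
  ints_env <- list2env(ints, parent = emptyenv())
  Cp_occ <- NULL
  cur_shift <- level_shift
  best <- list(err = Inf)
  for (it in seq_len(max_iter)) {
    Fp <- t(X) %*% Fm %*% X
    Fp <- (Fp + t(Fp)) / 2
    if (cur_shift > 0 && !is.null(Cp_occ))
      Fp <- Fp + cur_shift * (diag(n) - tcrossprod(Cp_occ))
    ev <- eigen(Fp, symmetric = TRUE)
    ord <- order(ev$values)
    C <- X %*% ev$vectors[, ord]
    Cp_occ <- ev$vectors[, ord[seq_len(nocc)], drop = FALSE]
    eps <- ev$values[ord]
    if (cur_shift > 0 && it > 1)
      eps[-seq_len(nocc)] <- eps[-seq_len(nocc)] - cur_shift
    # fractional occupation of a degenerate frontier shell: a symmetric
    # guess (e.g. the bare-core Hamiltonian of N2) can place a degenerate
    # pair across the occupation boundary; integer filling would break the
    # spatial symmetry and converge to a saddle point
    shell <- which(abs(eps - eps[nocc]) < 1e-7)
    if (any(shell > nocc) || ne2 %% 1 != 0) {
      nfull <- min(shell) - 1L
      focc <- 2 * (ne2 - nfull) / length(shell)
      P <- 2 * tcrossprod(C[, seq_len(nfull), drop = FALSE]) +
        focc * tcrossprod(C[, shell, drop = FALSE])
    } else {
      P <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
    }
    if (damp > 0 && it > 1 && it < diis_start)
      P <- (1 - damp) * P + damp * P_old
    jk <- jk_build(ints_env, P)
    Fm <- H + jk$J - 0.5 * jk$K
    energy <- 0.5 * sum(P * (H + Fm)) + ints$e_nuc
    err <- Fm %*% P %*% S - S %*% P %*% Fm
    err <- t(X) %*% err %*% X
    # drop the level shift once the solution is nearly self-consistent;
    # keeping it active leaves DIIS hovering above tight convergence
    if (cur_shift > 0 && max(abs(err)) < 1e-3) cur_shift <- 0
    dP <- max(abs(P - P_old))
    # converge on the Fock residual (commutator): extrapolating DIIS below
    # this level makes its normal equations numerically singular
    if (max(abs(err)) < best$err)
      best <- list(err = max(abs(err)), C = C, eps = eps, P = P, Fm = Fm,
                   energy = energy, it = it)
    if (max(abs(err)) < tol && abs(energy - e_old) < 1e-9) break
    # oscillating cases are handed to the damped/level-shifted retry early
    if (it > 60 && max(abs(err)) > 1e-3) break
    e_old <- energy; P_old <- P
    # DIIS
    err_list[[length(err_list) + 1]] <- err
    fock_list[[length(fock_list) + 1]] <- Fm
    if (length(err_list) > 8) {
      err_list <- err_list[-1]; fock_list <- fock_list[-1]
    }
    m <- length(err_list)
    if (it >= diis_start && m >= 2) {
      B <- matrix(0, m + 1, m + 1)
      for (i in seq_len(m)) for (j in seq_len(m))
        B[i, j] <- sum(err_list[[i]] * err_list[[j]])
      B[m + 1, seq_len(m)] <- -1; B[seq_len(m), m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cf)) {
        Fm <- Reduce(`+`, Map(`*`, fock_list, cf))
      }
    }
  }
  if (max(abs(err)) > tol) {
    # DIIS can hover just above a tight threshold; accept the best iterate
    # if it is essentially converged, otherwise report failure
    if (best$err < 100 * tol) {
      C <- best$C; eps <- best$eps; P <- best$P; Fm <- best$Fm
      energy <- best$energy; it <- best$it
    } else {
      stop("SCF did not converge in ", it, " iterations (best residual ",
           format(best$err), ")")
    }
  }
  structure(list(C = C, eps = eps, energy = energy, nocc = nocc,
                 P = P, F_AO = Fm, ints = ints, mol = ints$mol,
                 basis = ints$basis, n_iter = it),
            class = "scf_result")
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("<scf_result> RHF/%s: E = %.10f Hartree (%d AOs, %d iter)\n",
              x$basis, x$energy, x$ints$nao, x$n_iter))
  invisible(x)
}

#' Transform two-electron integrals to an MO subset
#'
#' Standard four-step quarter transformation `(pq|rs) -> (ij|kl)` for the
#' columns of `C`.
#' @param eri AO ERI array
#' @param C AO x MO coefficient block
#' @return MO ERI array
#' @export
ao2mo <- function(eri, C) {
  n <- dim(eri)[1]; m <- ncol(C)
  x <- matrix(eri, n, n^3)                       # p | qrs
  x <- crossprod(C, x)                           # i | qrs
  x <- array(x, c(m, n, n, n))
  x <- aperm(x, c(2, 1, 3, 4))                   # q i r s
  x <- matrix(x, n, m * n * n)
  x <- crossprod(C, x)                           # j i r s
  x <- array(x, c(m, m, n, n))
  x <- aperm(x, c(3, 1, 2, 4))                   # r j i s
  x <- matrix(x, n, m * m * n)
  x <- crossprod(C, x)                           # k j i s
  x <- array(x, c(m, m, m, n))
  x <- aperm(x, c(4, 1, 2, 3))                   # s k j i
  x <- matrix(x, n, m^3)
  x <- crossprod(C, x)                           # l k j i
  x <- array(x, c(m, m, m, m))
  aperm(x, c(4, 3, 2, 1))                        # i j k l
}
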