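# Exact decomposition of the active-space Hamiltonian into intrafragment
# parts, a mean-field interfragment coupling, and the four perturbation
# channels (dispersion, directional single charge transfer, double charge
# transfer, triplet-triplet spin exchange).
#
# Derivation sketch (chemists' integrals, spin-free H):
#   * coulomb-like AB terms  sum_{ab in A, cd in B} (ab|cd) E_ab E_cd
#   * exchange-like AB terms reorder (one fermion swap, sign -1) into
#     one-body transfer pairs; their spin-singlet part joins the coulomb
#     terms as the generalized exchange contribution, giving
#       H_AB = sum W_abcd E_ab E_cd,   W_abcd = (ab|cd) - 1/2 (ad|cb)
#     whose mean-field decoupling E -> <E> + dE yields the one-body
#     embedding potentials, the scalar double-counting shift, and the
#     dispersion channel (fluctuation x fluctuation).
#   * the spin-triplet remainder of the exchange terms is the TT channel,
#     with m = +1/0/-1 tensor components.
#   * terms changing fragment A's electron count by +-1 / +-2 form the two
#     1CT directions / the 2CT channel; three-index operators are grouped
#     as a^+_{p sigma} E_rs (and mirror forms) so matrix elements factorize.
# Correctness of every coefficient and phase is enforced by the dense
# reconstruction invariant exercised in the test suite.

# ---- structured fragment operators -----------------------------------------
# A structured operator (sfop) is a small list: type + spatial orbital
# indices (GLOBAL, 1-based) + spins (1 alpha, 2 beta).  Types:
#   id            identity
#   one  (p,s,dag)            single creation/annihilation
#   E    (p,q)                spin-summed excitation E_pq
#   dE   (p,q,mean)           fluctuation E_pq - mean
#   D    (p,q)                spin-difference a+_pa a_qa - a+_pb a_qb
#   so11 (p,s1,q,s2)          a+_{p s1} a_{q s2}
#   cE   (p,s,r,q)            a+_{p s} E_rq
#   Ea   (r,q,p,s)            E_rq a_{p s}
#   cc   (p,s1,r,s2)          a+_{p s1} a+_{r s2}
#   aa   (p,s1,r,s2)          a_{p s1} a_{r s2}

sf_id   <- function() list(type = "id")
sf_one  <- function(p, s, dag) list(type = "one", p = p, s = s, dag = dag)
sf_E    <- function(p, q) list(type = "E", p = p, q = q)
sf_dE   <- function(p, q, mean) list(type = "dE", p = p, q = q, mean = mean)
sf_D    <- function(p, q) list(type = "D", p = p, q = q)
sf_so11 <- function(p, s1, q, s2) list(type = "so11", p = p, s1 = s1, q = q, s2 = s2)
sf_cE   <- function(p, s, r, q) list(type = "cE", p = p, s = s, r = r, q = q)
sf_Ea   <- function(r, q, p, s) list(type = "Ea", r = r, q = q, p = p, s = s)
sf_cc   <- function(p, s1, r, s2) list(type = "cc", p = p, s1 = s1, r = r, s2 = s2)
sf_aa   <- function(p, s1, r, s2) list(type = "aa", p = p, s1 = s1, r = r, s2 = s2)

# unique key for grouping identical operators
sfop_key <- function(op) paste(unlist(op), collapse = "_")

# expansion into elementary branches: list of (coef, ops matrix [p spin dag])
expand_sfop <- function(op) {
  mat <- function(...) {
    v <- c(...)
    if (is.null(v)) matrix(integer(0), ncol = 3)
    else matrix(as.integer(v), ncol = 3, byrow = TRUE)
  }
  switch(op$type,
    id   = list(list(coef = 1, ops = mat())),
    one  = list(list(coef = 1, ops = mat(op$p, op$s, op$dag))),
    E    = list(list(coef = 1, ops = mat(op$p, 1L, 1L, op$q, 1L, 0L)),
                list(coef = 1, ops = mat(op$p, 2L, 1L, op$q, 2L, 0L))),
    dE   = list(list(coef = 1, ops = mat(op$p, 1L, 1L, op$q, 1L, 0L)),
                list(coef = 1, ops = mat(op$p, 2L, 1L, op$q, 2L, 0L)),
                list(coef = -op$mean, ops = mat())),
    D    = list(list(coef = 1, ops = mat(op$p, 1L, 1L, op$q, 1L, 0L)),
                list(coef = -1, ops = mat(op$p, 2L, 1L, op$q, 2L, 0L))),
    so11 = list(list(coef = 1, ops = mat(op$p, op$s1, 1L, op$q, op$s2, 0L))),
    cE   = list(list(coef = 1, ops = mat(op$p, op$s, 1L,
                                         op$r, 1L, 1L, op$q, 1L, 0L)),
                list(coef = 1, ops = mat(op$p, op$s, 1L,
                                         op$r, 2L, 1L, op$q, 2L, 0L))),
    Ea   = list(list(coef = 1, ops = mat(op$r, 1L, 1L, op$q, 1L, 0L,
                                         op$p, op$s, 0L)),
                list(coef = 1, ops = mat(op$r, 2L, 1L, op$q, 2L, 0L,
                                         op$p, op$s, 0L))),
    cc   = list(list(coef = 1, ops = mat(op$p, op$s1, 1L, op$r, op$s2, 1L))),
    aa   = list(list(coef = 1, ops = mat(op$p, op$s1, 0L, op$r, op$s2, 0L))),
    stop("unknown structured operator type ", op$type))
}

# (d n_alpha, d n_beta) sector shift induced by the operator
sfop_shift <- function(op) {
  br <- expand_sfop(op)
  for (b in br) {
    if (nrow(b$ops) > 0) {
      d <- c(0L, 0L)
      for (i in seq_len(nrow(b$ops)))
        d[b$ops[i, 2]] <- d[b$ops[i, 2]] + if (b$ops[i, 3] == 1L) 1L else -1L
      return(d)
    }
  }
  c(0L, 0L)
}

# number of fermionic operators (parity decides the A-block crossing sign)
sfop_nops <- function(op) {
  br <- expand_sfop(op)
  for (b in br) if (nrow(b$ops) > 0) return(nrow(b$ops))
  0L
}

# apply a structured operator to a fragment sector state; `offset` maps
# global spatial indices to fragment-local ones
apply_sfop <- function(state, op, offset = 0L) {
  out <- NULL
  for (b in expand_sfop(op)) {
    ops <- b$ops
    if (nrow(ops) > 0) ops[, 1] <- ops[, 1] - offset
    x <- apply_opstring(state, ops)
    if (is.null(x)) next
    x$coef <- b$coef * x$coef
    out <- if (is.null(out)) x else { out$coef <- out$coef + x$coef; out }
  }
  out
}

# ---- term classification ----------------------------------------------------

#' Classify a Hamiltonian term by its fragment character
#'
#' One-electron terms are labelled by the fragments of (p, q); two-electron
#' chemists' terms `(pq|rs)` by the net particle-number change on fragment A
#' (creations p, r; annihilations q, s) and, for number-conserving
#' interfragment terms, by whether the charge pairs are fragment-local
#' (coulomb-like) or transfer pairs (spin-carrying).
#'
#' @param p,q,r,s orbital indices (1-based); omit `r`, `s` for a one-electron
#'   term
#' @param partition a [fragment_partition()]
#' @return one of `"intra_A"`, `"intra_B"`, `"coulomb_like_AB"`,
#'   `"spin_carrying_AB"`, `"ct1"`, `"ct2"`
#' @export
classify_term <- function(p, q, r = NULL, s = NULL, partition) {
  fr <- partition$fragment_of
  if (is.null(r)) {
    if (fr[p] == fr[q]) return(paste0("intra_", fr[p]))
    return("ct1")
  }
  inA <- fr[c(p, q, r, s)] == "A"
  dna <- sum(inA[c(1, 3)]) - sum(inA[c(2, 4)])
  if (abs(dna) == 1L) return("ct1")
  if (abs(dna) == 2L) return("ct2")
  if (all(inA)) return("intra_A")
  if (!any(inA)) return("intra_B")
  if (fr[p] == fr[q] && fr[r] == fr[s]) return("coulomb_like_AB")
  "spin_carrying_AB"
}

# ---- channel construction ---------------------------------------------------

new_channel <- function(name, terms) {
  structure(list(channel = name, terms = terms), class = "channel_operator_set")
}

#' @export
print.channel_operator_set <- function(x, ...) {
  cat(sprintf("<channel_operator_set> %s: %d terms\n", x$channel,
              length(x$terms)))
  invisible(x)
}

#' Decompose an active-space Hamiltonian over a fragment partition
#'
#' Splits `H` exactly into intrafragment Hamiltonians, one-body mean-field
#' embedding potentials built from the supplied fragment 1-RDMs (with the
#' scalar double-counting shift), and the four interaction channels.  The
#' identity `H = H_A + H_B + V_mf - shift + sum(channels)` holds as an
#' operator equation and is testable densely via [dense_operator_matrix()].
#'
#' @param H an [active_hamiltonian()]
#' @param partition a [fragment_partition()]
#' @param rdms list with elements `A`, `B`: fragment-local spatial 1-RDMs of
#'   the product-state factors (hermitian, trace = electron count)
#' @param member_tol channel terms with |coefficient| below this are omitted
#'   from the perturbing operator lists
#' @return object of class `hamiltonian_decomposition`
#' @export
decompose_hamiltonian <- function(H, partition, rdms, member_tol = 1e-12) {
  stopifnot(inherits(H, "active_hamiltonian"),
            inherits(partition, "fragment_partition"),
            H$n_orb == partition$n_orb)
  iA <- partition$idx_A; iB <- partition$idx_B
  nA <- length(iA); nB <- length(iB)
  gA_rdm <- rdms$A; gB_rdm <- rdms$B
  for (f in c("A", "B")) {
    gm <- rdms[[f]]
    ne <- partition$n_elec[[f]]
    if (max(abs(gm - t(gm))) > 1e-8)
      stop("fragment ", f, " 1-RDM is not hermitian")
    if (abs(sum(diag(gm)) - ne) > 1e-6)
      stop("fragment ", f, " 1-RDM trace does not match its electron count")
  }
  g <- H$g
  # W_abcd = (ab|cd) - 1/2 (ad|cb), a,b in A; c,d in B (local indices)
  gJ <- g[iA, iA, iB, iB, drop = FALSE]
  gK <- aperm(g[iA, iB, iB, iA, drop = FALSE], c(1, 4, 3, 2)) # (a,b,c,d) <- (a,d,c,b)
  W <- gJ - 0.5 * gK
  fA <- matrix(0, nA, nA); fB <- matrix(0, nB, nB)
  Wm <- matrix(W, nA * nA, nB * nB)
  fA[] <- Wm %*% as.numeric(gB_rdm)
  fB[] <- t(Wm) %*% as.numeric(gA_rdm)
  shift <- as.numeric(t(as.numeric(gA_rdm)) %*% Wm %*% as.numeric(gB_rdm))

  terms_disp <- list(); terms_tt <- list()
  kd <- 0L; kt <- 0L
  for (a in seq_len(nA)) for (b in seq_len(nA))
    for (c_ in seq_len(nB)) for (d in seq_len(nB)) {
      ga_ <- iA[a]; gb_ <- iA[b]; gc_ <- iB[c_]; gd_ <- iB[d]
      w <- W[a, b, c_, d]
      if (abs(w) > member_tol) {
        kd <- kd + 1L
        terms_disp[[kd]] <- list(opA = sf_dE(ga_, gb_, gA_rdm[a, b]),
                                 opB = sf_dE(gc_, gd_, gB_rdm[c_, d]),
                                 g = w, phase = 1)
      }
      x <- gK[a, b, c_, d]   # (ad|cb)
      if (abs(x) > member_tol) {
        kt <- kt + 1L
        terms_tt[[kt]] <- list(opA = sf_so11(ga_, 1L, gb_, 2L),
                               opB = sf_so11(gc_, 2L, gd_, 1L),
                               g = -x, phase = 1)
        kt <- kt + 1L
        terms_tt[[kt]] <- list(opA = sf_so11(ga_, 2L, gb_, 1L),
                               opB = sf_so11(gc_, 1L, gd_, 2L),
                               g = -x, phase = 1)
        kt <- kt + 1L
        terms_tt[[kt]] <- list(opA = sf_D(ga_, gb_), opB = sf_D(gc_, gd_),
                               g = -0.5 * x, phase = 1)
      }
    }

  # single charge transfer, direction B -> A (fragment A gains one electron)
  terms_ba <- list(); kba <- 0L
  for (gp in iA) for (gq in iB) for (s in 1:2) {
    if (abs(H$h[gp, gq]) > member_tol) {
      kba <- kba + 1L
      terms_ba[[kba]] <- list(opA = sf_one(gp, s, 1L), opB = sf_one(gq, s, 0L),
                              g = H$h[gp, gq], phase = 1)
    }
    for (gr in iA) for (gs in iA) {
      x <- g[gp, gq, gr, gs]
      if (abs(x) > member_tol) {
        kba <- kba + 1L
        terms_ba[[kba]] <- list(opA = sf_cE(gp, s, gr, gs),
                                opB = sf_one(gq, s, 0L), g = x, phase = 1)
      }
    }
    for (gr in iB) for (gs in iB) {
      x <- g[gp, gq, gr, gs]
      if (abs(x) > member_tol) {
        kba <- kba + 1L
        terms_ba[[kba]] <- list(opA = sf_one(gp, s, 1L),
                                opB = sf_Ea(gr, gs, gq, s), g = x, phase = 1)
      }
    }
  }

  # single charge transfer, direction A -> B (fragment A loses one electron)
  terms_ab <- list(); kab <- 0L
  for (gp in iB) for (gq in iA) for (s in 1:2) {
    if (abs(H$h[gp, gq]) > member_tol) {
      kab <- kab + 1L
      terms_ab[[kab]] <- list(opA = sf_one(gq, s, 0L), opB = sf_one(gp, s, 1L),
                              g = H$h[gp, gq], phase = -1)
    }
    for (gr in iA) for (gs in iA) {
      x <- g[gp, gq, gr, gs]
      if (abs(x) > member_tol) {
        kab <- kab + 1L
        terms_ab[[kab]] <- list(opA = sf_Ea(gr, gs, gq, s),
                                opB = sf_one(gp, s, 1L), g = x, phase = -1)
      }
    }
    for (gr in iB) for (gs in iB) {
      x <- g[gp, gq, gr, gs]
      if (abs(x) > member_tol) {
        kab <- kab + 1L
        terms_ab[[kab]] <- list(opA = sf_one(gq, s, 0L),
                                opB = sf_cE(gp, s, gr, gs), g = x, phase = -1)
      }
    }
  }

  # double charge transfer (both directions)
  terms_ct2 <- list(); k2 <- 0L
  for (gp in iA) for (gr in iA) for (gq in iB) for (gs in iB)
    for (s1 in 1:2) for (s2 in 1:2) {
      if (s1 == s2 && (gp == gr || gq == gs)) next
      x <- g[gp, gq, gr, gs]
      if (abs(x) <= 2 * member_tol) next
      k2 <- k2 + 1L
      terms_ct2[[k2]] <- list(opA = sf_cc(gp, s1, gr, s2),
                              opB = sf_aa(gs, s2, gq, s1),
                              g = 0.5 * x, phase = 1)
    }
  for (gp in iB) for (gr in iB) for (gq in iA) for (gs in iA)
    for (s1 in 1:2) for (s2 in 1:2) {
      if (s1 == s2 && (gp == gr || gq == gs)) next
      x <- g[gp, gq, gr, gs]
      if (abs(x) <= 2 * member_tol) next
      k2 <- k2 + 1L
      terms_ct2[[k2]] <- list(opA = sf_aa(gs, s2, gq, s1),
                              opB = sf_cc(gp, s1, gr, s2),
                              g = 0.5 * x, phase = 1)
    }

  structure(list(
    hamiltonian = H, partition = partition,
    hA = H$h[iA, iA, drop = FALSE], gA = g[iA, iA, iA, iA, drop = FALSE],
    hB = H$h[iB, iB, drop = FALSE], gB = g[iB, iB, iB, iB, drop = FALSE],
    fA = fA, fB = fB, shift = shift, W = Wm,
    gammaA = gA_rdm, gammaB = gB_rdm,
    channels = list(
      dispersion = new_channel("dispersion", terms_disp),
      ct1_AtoB = new_channel("ct1_AtoB", terms_ab),
      ct1_BtoA = new_channel("ct1_BtoA", terms_ba),
      ct2 = new_channel("ct2", terms_ct2),
      tt = new_channel("tt", terms_tt))),
    class = "hamiltonian_decomposition")
}

#' @export
print.hamiltonian_decomposition <- function(x, ...) {
  cat(sprintf("<hamiltonian_decomposition> %d orbitals (A %d | B %d), shift %.8f\n",
              x$hamiltonian$n_orb, length(x$partition$idx_A),
              length(x$partition$idx_B), x$shift))
  for (ch in x$channels)
    cat(sprintf("  %-10s %6d terms\n", ch$channel, length(ch$terms)))
  invisible(x)
}

# ---- dense oracle support ---------------------------------------------------

#' Dense matrix of an operator collection on a determinant sector
#'
#' Exact matrix representation (including all fermionic signs) of a channel
#' operator set, or of any list of `(opA, opB, g, phase)` terms, on the
#' combined determinant basis.  Brute-force test oracle; guarded by a size
#' cap.
#'
#' @param terms a `channel_operator_set` or list of terms
#' @param space combined-system sector from [sector_space()]
#' @param cap maximum sector dimension
#' @return dense matrix (dim x dim)
#' @export
dense_operator_matrix <- function(terms, space, cap = 2e4) {
  if (inherits(terms, "channel_operator_set")) terms <- terms$terms
  if (space$dim > cap) stop("combined space too large for the dense oracle")
  M <- matrix(0, space$dim, space$dim)
  for (tm in terms) {
    brA <- expand_sfop(tm$opA); brB <- expand_sfop(tm$opB)
    for (ba in brA) for (bb in brB) {
      ops <- rbind(ba$ops, bb$ops)
      m <- opstring_matrix(space, ops)
      if (is.null(m)) next
      cf <- tm$g * tm$phase * ba$coef * bb$coef
      M <- M + cf * as.matrix(m)
    }
  }
  M
}

# dense matrix of H0 = H_A + H_B + V_mf - shift (+ e_core) on a combined space
dense_h0_matrix <- function(decomp, space) {
  H <- decomp$hamiltonian
  iA <- decomp$partition$idx_A; iB <- decomp$partition$idx_B
  n <- H$n_orb
  h0 <- matrix(0, n, n)
  h0[iA, iA] <- decomp$hA + decomp$fA
  h0[iB, iB] <- decomp$hB + decomp$fB
  g0 <- array(0, rep(n, 4))
  g0[iA, iA, iA, iA] <- decomp$gA
  g0[iB, iB, iB, iB] <- decomp$gB
  build_sector_hamiltonian(h0, g0, space) +
    diag(H$e_core - decomp$shift, space$dim)
}

#' Embed a fragment product state in the combined determinant basis
#'
#' Maps `psi_A (x) psi_B` to a combined-sector CI vector, including the
#' fermionic reordering sign between the fragment-blocked and the global
#' (all alpha, all beta) spin-orbital orderings.
#'
#' @param psiA,psiB fragment sector wavefunctions (A uses local orbitals
#'   1..nA, B local 1..nB)
#' @param norb total orbital count (nA + nB)
#' @return list(space, coef) combined sector state
#' @export
embed_product <- function(psiA, psiB, norb) {
  nA <- psiA$space$norb
  spc <- sector_space(norb, psiA$space$na + psiB$space$na,
                      psiA$space$nb + psiB$space$nb)
  out <- sector_state(spc)
  # sign from moving the B alpha block past the A beta block
  sgn <- if (bitwAnd(psiA$space$nb * psiB$space$na, 1L) == 1L) -1 else 1
  astrA <- psiA$space$astr; astrB <- psiB$space$astr
  bstrA <- psiA$space$bstr; bstrB <- psiB$space$bstr
  for (ja in seq_along(astrB)) for (jb in seq_along(bstrB)) {
    ca <- match(bitwOr(astrA, bitwShiftL(astrB[ja], nA)), spc$astr)
    cb <- match(bitwOr(bstrA, bitwShiftL(bstrB[jb], nA)), spc$bstr)
    out$coef[ca, cb] <- out$coef[ca, cb] +
      sgn * psiA$coef * psiB$coef[ja, jb]
  }
  out
}
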