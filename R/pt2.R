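# Second-order interfragment perturbation theory in the partially contracted
# basis Phi_{mu nu} = O_mu^A O_nu^B |Psi0>.  All matrices factorize over
# fragments:
#   S = <O^A+ O'^A> <O^B+ O'^B>,
#   <Phi|H0 - E0|Phi'> = <O+ (H^A_eff - eps_A) O'> <O+O'>
#                      + <O+O'> <O+ (H^B_eff - eps_B) O'>
# so only small fragment Gram/Hamiltonian matrices over the distinct
# fragment operators are ever formed.

#' Build the partially contracted perturbing basis for one channel
#'
#' Applies every distinct fragment operator of the channel to its fragment's
#' CI vector, grouping members by the (charge/spin-shifted) target sector
#' pair.  Members are stored implicitly as pairs of fragment sector vectors
#' with their fermionic crossing phases; zero-norm members are flagged.
#'
#' @param decomp a [decompose_hamiltonian()] result
#' @param psi0 a converged [self_consistent_product_state()] result
#' @param channel channel name (`"dispersion"`, `"ct1_AtoB"`, `"ct1_BtoA"`,
#'   `"ct2"`, `"tt"`)
#' @return object of class `perturbing_basis`
#' @export
build_perturbing_basis <- function(decomp, psi0, channel) {
  terms <- decomp$channels[[channel]]$terms
  nA <- length(decomp$partition$idx_A)
  N_A <- decomp$partition$n_elec[["A"]]
  psiA <- as_state(psi0$psi_A); psiB <- as_state(psi0$psi_B)
  if (length(terms) == 0)
    return(structure(list(channel = channel, groups = list()),
                     class = "perturbing_basis"))
  shA <- vapply(terms, function(t) paste(sfop_shift(t$opA), collapse = ","), "")
  shB <- vapply(terms, function(t) paste(sfop_shift(t$opB), collapse = ","), "")
  gkey <- paste(shA, shB, sep = "|")
  groups <- list()
  for (gk in unique(gkey)) {
    sel <- terms[gkey == gk]
    keyA <- vapply(sel, function(t) sfop_key(t$opA), "")
    keyB <- vapply(sel, function(t) sfop_key(t$opB), "")
    uA <- !duplicated(keyA); uB <- !duplicated(keyB)
    opsA <- lapply(sel[uA], `[[`, "opA")
    opsB <- lapply(sel[uB], `[[`, "opB")
    a_idx <- match(keyA, keyA[uA])
    b_idx <- match(keyB, keyB[uB])
    vecA <- lapply(opsA, function(op) apply_sfop(psiA, op, offset = 0L))
    vecB <- lapply(opsB, function(op) apply_sfop(psiB, op, offset = nA))
    if (any(vapply(vecA, is.null, TRUE)) || any(vapply(vecB, is.null, TRUE)))
      next  # target fragment sector does not exist (e.g. fully filled)
    spaceA <- vecA[[1]]$space; spaceB <- vecB[[1]]$space
    UA <- vapply(vecA, function(v) as.numeric(v$coef), numeric(spaceA$dim))
    UB <- vapply(vecB, function(v) as.numeric(v$coef), numeric(spaceB$dim))
    UA <- matrix(UA, nrow = spaceA$dim); UB <- matrix(UB, nrow = spaceB$dim)
    gvec <- vapply(sel, `[[`, 0, "g")
    # fermionic phase: normal-ordering sign times the sign of the B operator
    # crossing fragment A's electrons in the ket
    nopsB <- sfop_nops(sel[[1]]$opB)
    cross <- if (bitwAnd(N_A * nopsB, 1L) == 1L) -1 else 1
    ph <- vapply(sel, `[[`, 0, "phase") * cross
    normA <- sqrt(colSums(UA^2)); normB <- sqrt(colSums(UB^2))
    zero_members <- normA[a_idx] * normB[b_idx] < 1e-14
    groups[[length(groups) + 1L]] <- list(
      key = gk, spaceA = spaceA, spaceB = spaceB,
      UA = UA, UB = UB, a_idx = a_idx, b_idx = b_idx,
      g = gvec, phase = ph, zero_members = zero_members,
      is_reference = identical(spaceA$key, psiA$space$key) &&
        identical(spaceB$key, psiB$space$key))
  }
  structure(list(channel = channel, groups = groups),
            class = "perturbing_basis")
}

#' @export
print.perturbing_basis <- function(x, ...) {
  nm <- sum(vapply(x$groups, function(g) length(g$a_idx), 0L))
  cat(sprintf("<perturbing_basis> %s: %d members in %d sector groups\n",
              x$channel, nm, length(x$groups)))
  invisible(x)
}

# dense effective fragment Hamiltonians on the needed sectors, cached
.heff_sector <- function(cache, psi0, decomp, side, space) {
  key <- paste(side, space$key)
  H <- cache[[key]]
  if (!is.null(H)) return(H)
  h <- if (side == "A") psi0$h_eff_A else psi0$h_eff_B
  g <- if (side == "A") decomp$gA else decomp$gB
  H <- build_sector_hamiltonian(h, g, space)
  assign(key, H, envir = cache)
  H
}

#' Assemble overlap, zeroth-order and right-hand-side matrices
#'
#' Per sector group of the basis: overlap `S`, zeroth-order matrix
#' `M = <Phi| H0 |Phi'>` and right-hand side `V = S g` (the contraction of
#' the overlaps with the channel coefficients), all built from fragment
#' factors.  When the group lives in the reference sector pair, members are
#' projected orthogonal to `Psi0` (rank-one metric correction; `M - E0 S` is
#' unaffected because `Psi0` is an `H0` eigenstate).
#'
#' @param basis a [build_perturbing_basis()] result
#' @param decomp the Hamiltonian decomposition
#' @param psi0 the converged product state
#' @return list of per-group lists with `S`, `M`, `W` (= `M - E0 S`), `V`
#' @export
assemble_matrices <- function(basis, decomp, psi0) {
  cache <- new.env(parent = emptyenv())
  e0 <- psi0$e0
  lapply(basis$groups, function(gr) {
    GA <- crossprod(gr$UA); GB <- crossprod(gr$UB)
    HdA <- .heff_sector(cache, psi0, decomp, "A", gr$spaceA)
    HdB <- .heff_sector(cache, psi0, decomp, "B", gr$spaceB)
    HA <- crossprod(gr$UA, HdA %*% gr$UA)
    HB <- crossprod(gr$UB, HdB %*% gr$UB)
    WA <- HA - psi0$eps_A * GA
    WB <- HB - psi0$eps_B * GB
    ai <- gr$a_idx; bi <- gr$b_idx
    pp <- outer(gr$phase, gr$phase)
    S <- GA[ai, ai, drop = FALSE] * GB[bi, bi, drop = FALSE] * pp
    W <- (WA[ai, ai, drop = FALSE] * GB[bi, bi, drop = FALSE] +
          GA[ai, ai, drop = FALSE] * WB[bi, bi, drop = FALSE]) * pp
    V <- as.numeric(S %*% gr$g)
    v0 <- NULL
    if (gr$is_reference) {
      oA <- as.numeric(crossprod(gr$UA, as.numeric(psi0$psi_A$coef)))
      oB <- as.numeric(crossprod(gr$UB, as.numeric(psi0$psi_B$coef)))
      v0 <- gr$phase * oA[ai] * oB[bi]
      e1 <- sum(gr$g * v0)
      S <- S - tcrossprod(v0)
      V <- V - v0 * e1
    }
    list(S = S, M = W + e0 * S, W = W, V = V, v0 = v0,
         n_members = length(ai), zero_members = gr$zero_members)
  })
}

#' Solve the contracted amplitude equations
#'
#' Canonical orthogonalization of the overlap metric (eigenvalues below
#' `metric_threshold` times the largest are discarded), then solves
#' `(M - e0 S) C = -V` in the surviving subspace.  A non-positive-definite
#' zeroth-order matrix in that subspace (intruder-state-like behavior)
#' raises a warning carrying the smallest eigenvalue.
#'
#' @param S overlap matrix
#' @param M zeroth-order matrix `<Phi|H0|Phi'>`
#' @param V right-hand side
#' @param e0 zeroth-order reference energy
#' @param metric_threshold relative metric eigenvalue cutoff
#' @return list with amplitudes `C`, `e2 = C.V`, subspace diagnostics
#' @export
solve_amplitudes <- function(S, M, V, e0, metric_threshold = 1e-10) {
  n <- nrow(S)
  if (n == 0 || max(abs(V)) == 0)
    return(list(C = numeric(n), e2 = 0, n_kept = 0L, n_dropped = n,
                min_eig = NA_real_, residual = 0,
                metric_range = c(NA_real_, NA_real_)))
  W <- M - e0 * S
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  smax <- max(es$values)
  keep <- es$values > metric_threshold * smax
  if (!any(keep))
    return(list(C = numeric(n), e2 = 0, n_kept = 0L, n_dropped = n,
                min_eig = NA_real_, residual = 0,
                metric_range = range(es$values)))
  X <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))
  Ws <- crossprod(X, W %*% X)
  Ws <- (Ws + t(Ws)) / 2
  ew <- eigen(Ws, symmetric = TRUE, only.values = TRUE)$values
  min_eig <- min(ew)
  if (min_eig < 1e-12)
    warning("zeroth-order operator not positive definite in the perturbing ",
            "subspace (smallest eigenvalue ", format(min_eig),
            "): intruder-state-like behavior")
  b <- -as.numeric(crossprod(X, V))
  y <- solve(Ws, b)
  C <- as.numeric(X %*% y)
  residual <- sqrt(sum((crossprod(X, W %*% C + V))^2))
  list(C = C, e2 = sum(C * V), n_kept = sum(keep), n_dropped = n - sum(keep),
       min_eig = min_eig, residual = residual,
       metric_range = range(es$values))
}

#' Per-channel second-order energy from amplitudes
#' @param C amplitude vector
#' @param V right-hand side vector
#' @return `e2 = C . V` (Hartree, non-positive up to roundoff)
#' @export
channel_energy <- function(C, V) sum(C * V)

#' First-order energies of all channels
#'
#' Expectation values `<Psi0| H'_c |Psi0>`; all five vanish on a converged
#' product state (charge-transfer channels by sector orthogonality,
#' dispersion by the fluctuation construction, spin exchange by spin
#' symmetry of the fragment states).
#'
#' @param decomp the Hamiltonian decomposition
#' @param psi0 the converged product state
#' @return named numeric vector over channels
#' @export
first_order_check <- function(decomp, psi0) {
  nA <- length(decomp$partition$idx_A)
  psiA <- as_state(psi0$psi_A); psiB <- as_state(psi0$psi_B)
  out <- c(dispersion = 0, ct1_AtoB = 0, ct1_BtoA = 0, ct2 = 0, tt = 0)
  cacheA <- new.env(parent = emptyenv())
  cacheB <- new.env(parent = emptyenv())
  expv <- function(st, op, offset, cache) {
    key <- sfop_key(op)
    v <- cache[[key]]
    if (!is.null(v)) return(v)
    if (any(sfop_shift(op) != 0L)) {
      v <- 0
    } else {
      x <- apply_sfop(st, op, offset)
      v <- if (is.null(x)) 0 else state_dot(st, x)
    }
    assign(key, v, envir = cache)
    v
  }
  for (ch in names(out)) {
    terms <- decomp$channels[[ch]]$terms
    e <- 0
    for (tm in terms) {
      a <- expv(psiA, tm$opA, 0L, cacheA)
      if (a == 0) next
      b <- expv(psiB, tm$opB, nA, cacheB)
      if (b == 0) next
      e <- e + tm$g * tm$phase * a * b
    }
    out[ch] <- e
  }
  out
}

#' Full second-order perturbative correction
#'
#' Runs [build_perturbing_basis()], [assemble_matrices()] and
#' [solve_amplitudes()] for every channel and sums the per-channel
#' second-order energies.
#'
#' @param decomp a [decompose_hamiltonian()] result
#' @param psi0 a converged [self_consistent_product_state()] result
#' @param metric_threshold relative metric cutoff for the canonical
#'   orthogonalization
#' @param channels channels to treat (default all five)
#' @return object of class `pt2_result` with per-channel energies `e2`,
#'   totals, first-order checks and solver diagnostics
#' @export
pt2_correction <- function(decomp, psi0, metric_threshold = 1e-10,
                           channels = c("dispersion", "ct1_AtoB",
                                        "ct1_BtoA", "ct2", "tt")) {
  e2 <- stats::setNames(numeric(length(channels)), channels)
  diag_ <- list()
  for (ch in channels) {
    basis <- build_perturbing_basis(decomp, psi0, ch)
    mats <- assemble_matrices(basis, decomp, psi0)
    tot <- 0
    gdiag <- list()
    for (i in seq_along(mats)) {
      m <- mats[[i]]
      sol <- solve_amplitudes(m$S, m$M, m$V, psi0$e0,
                              metric_threshold = metric_threshold)
      tot <- tot + sol$e2
      gdiag[[i]] <- list(n_members = m$n_members, n_kept = sol$n_kept,
                         n_dropped = sol$n_dropped, min_eig = sol$min_eig,
                         residual = sol$residual, e2 = sol$e2)
    }
    e2[ch] <- tot
    diag_[[ch]] <- gdiag
  }
  fo <- first_order_check(decomp, psi0)
  structure(list(e2 = e2, e2_total = sum(e2),
                 e0 = psi0$e0, e_total = psi0$e0 + sum(e2),
                 first_order = fo, diagnostics = diag_,
                 metric_threshold = metric_threshold),
            class = "pt2_result")
}

#' @export
print.pt2_result <- function(x, ...) {
  cat("<pt2_result>\n")
  cat(sprintf("  e0       = %.10f\n", x$e0))
  for (ch in names(x$e2))
    cat(sprintf("  e2[%-10s] = %14.10f\n", ch, x$e2[ch]))
  cat(sprintf("  e2_total = %.10f\n  e_total  = %.10f\n",
              x$e2_total, x$e_total))
  invisible(x)
}

#' Total second-order energy from per-channel results
#' @param results a `pt2_result`
#' @return list with `e2_total` and `e_total`
#' @export
total_pt2 <- function(results) {
  list(e2_total = results$e2_total, e_total = results$e_total)
}
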