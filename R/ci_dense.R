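# Sparse matrix representations of second-quantized operators on determinant
# sectors, and the dense sector Hamiltonian builder used by the fragment
# solvers and the brute-force oracles.
#
# CI vectors are vectorized column-major from the (alpha x beta) coefficient
# matrix: linear index = ia + (ib-1)*n_astr.

.so_mat_cache <- new.env(parent = emptyenv())

# Sparse matrix of a single creation/annihilation operator, mapping the given
# sector to its neighbor sector.  Returns NULL when the target sector is empty.
so_matrix <- function(space, p, spin, dagger) {
  key <- paste(space$key, p, spin, dagger, sep = "/")
  m <- .so_mat_cache[[key]]
  if (!is.null(m)) return(if (identical(m, "null")) NULL else m)
  bit <- bitwShiftL(1L, p - 1L)
  if (spin == 1L) {
    tsp <- sector_space(space$norb, space$na + if (dagger) 1L else -1L, space$nb)
  } else {
    tsp <- sector_space(space$norb, space$na, space$nb + if (dagger) 1L else -1L)
  }
  if (is.null(tsp)) {
    assign(key, "null", envir = .so_mat_cache)
    return(NULL)
  }
  if (spin == 1L) {
    occ <- bitwAnd(space$astr, bit) != 0L
    src <- which(if (dagger) !occ else occ)
    newstr <- bitwXor(space$astr[src], bit)
    sgn <- .parity_sign(space$astr[src], p)
    tgt <- match(newstr, tsp$astr)
    # block over beta strings (identical mapping in every beta column)
    nb <- space$n_bstr
    i <- rep(tgt, nb) + (rep(seq_len(nb), each = length(tgt)) - 1L) * tsp$n_astr
    j <- rep(src, nb) + (rep(seq_len(nb), each = length(src)) - 1L) * space$n_astr
    x <- rep(sgn, nb)
  } else {
    occ <- bitwAnd(space$bstr, bit) != 0L
    src <- which(if (dagger) !occ else occ)
    newstr <- bitwXor(space$bstr[src], bit)
    gs <- if (bitwAnd(space$na, 1L) == 1L) -1 else 1
    sgn <- gs * .parity_sign(space$bstr[src], p)
    tgt <- match(newstr, tsp$bstr)
    na_ <- space$n_astr
    i <- rep(seq_len(na_), length(tgt)) + (rep(tgt, each = na_) - 1L) * na_
    j <- rep(seq_len(na_), length(src)) + (rep(src, each = na_) - 1L) * na_
    x <- rep(sgn, each = na_)
  }
  m <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(tsp$dim, space$dim))
  assign(key, m, envir = .so_mat_cache)
  m
}

# Sparse matrix of an elementary operator string acting on `space`
# (rightmost operator first).  NULL if any intermediate sector is empty.
opstring_matrix <- function(space, ops) {
  m <- NULL
  cur <- space
  n <- nrow(ops)
  if (n == 0L)
    return(Matrix::Diagonal(space$dim))
  for (i in seq(n, 1L)) {
    s <- so_matrix(cur, ops[i, 1L], ops[i, 2L], ops[i, 3L])
    if (is.null(s)) return(NULL)
    m <- if (is.null(m)) s else s %*% m
    if (ops[i, 2L] == 1L) {
      cur <- sector_space(cur$norb, cur$na + if (ops[i, 3L]) 1L else -1L, cur$nb)
    } else {
      cur <- sector_space(cur$norb, cur$na, cur$nb + if (ops[i, 3L]) 1L else -1L)
    }
  }
  m
}

.Epq_cache <- new.env(parent = emptyenv())

# Sparse spin-summed excitation operator E_pq on a sector (square matrix).
Epq_matrix <- function(space, p, q) {
  key <- paste(space$key, p, q, sep = "/")
  m <- .Epq_cache[[key]]
  if (!is.null(m)) return(m)
  m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(space$dim, space$dim))
  for (s in 1:2) {
    x <- opstring_matrix(space, rbind(c(p, s, 1L), c(q, s, 0L)))
    if (!is.null(x)) m <- m + x
  }
  assign(key, m, envir = .Epq_cache)
  m
}

#' Dense Hamiltonian matrix on a determinant sector
#'
#' Builds the matrix of `sum_pq h_pq E_pq + 1/2 sum_pqrs (pq|rs) e_pqrs`
#' (chemists' convention, spin-free) on the sector basis.  Intended for
#' modest sector sizes; the iterative solver covers large ones.
#'
#' @param h one-electron integral matrix (norb x norb), Hartree
#' @param g two-electron integral array (norb^4), chemists' (pq|rs)
#' @param space sector space from [sector_space()]
#' @param two_body optional precomputed two-body matrix (see
#'   [sector_two_body()]), reused across calls when only `h` changes
#' @return dense symmetric matrix (dim x dim)
#' @keywords internal
build_sector_hamiltonian <- function(h, g, space, two_body = NULL) {
  norb <- space$norb
  stopifnot(nrow(h) == norb)
  if (is.null(two_body)) two_body <- sector_two_body(g, space)
  # one-body including the -1/2 sum_r (pr|rq) reordering correction folded in
  # sector_two_body (which uses E_pq E_rs products); correction applied there.
  H <- two_body
  for (p in seq_len(norb)) for (q in seq_len(norb)) {
    if (h[p, q] != 0)
      H <- H + h[p, q] * Epq_matrix(space, p, q)
  }
  M <- as.matrix(H)
  (M + t(M)) / 2
}

# Two-body part 1/2 sum_pqrs (pq|rs) (E_pq E_rs - delta_qr E_ps) as a sparse
# matrix on the sector.
sector_two_body <- function(g, space) {
  norb <- space$norb
  H <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(space$dim, space$dim))
  # correction: -1/2 sum_r (pr|rq) E_pq
  k <- matrix(0, norb, norb)
  for (p in seq_len(norb)) for (q in seq_len(norb))
    k[p, q] <- -0.5 * sum(g[p, , , q][cbind(seq_len(norb), seq_len(norb))])
  Em <- vector("list", norb * norb)
  for (p in seq_len(norb)) for (q in seq_len(norb))
    Em[[(p - 1L) * norb + q]] <- Epq_matrix(space, p, q)
  for (p in seq_len(norb)) for (q in seq_len(norb)) {
    Epq <- Em[[(p - 1L) * norb + q]]
    for (r in seq_len(norb)) for (s in seq_len(norb)) {
      w <- g[p, q, r, s]
      if (w != 0)
        H <- H + (0.5 * w) * (Epq %*% Em[[(r - 1L) * norb + s]])
    }
    if (k[p, q] != 0) H <- H + k[p, q] * Epq
  }
  H
}
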