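# Determinant-string machinery.
#
# A spin sector (n_orb, n_alpha, n_beta) is spanned by all pairs of occupation
# strings; strings are stored as integer bit masks (bit p-1 <-> spatial orbital
# p occupied by that spin).  CI vectors are (n alpha-strings) x (n beta-strings)
# coefficient matrices.  Spin-orbital ordering within a fragment is all alpha
# (ascending orbital) then all beta, so a beta operator crossing the alpha
# block picks up (-1)^n_alpha.

.pc16 <- local({
  x <- 0:65535L
  b <- 0L
  for (k in 0:15) b <- b + bitwAnd(bitwShiftR(x, k), 1L)
  as.integer(b)
})

popcount <- function(x) .pc16[x + 1L]

#' Enumerate occupation strings
#'
#' All bit masks with `k` of `n` bits set, in increasing numeric order.
#' @param n number of orbitals (<= 16)
#' @param k number of electrons of one spin
#' @return integer vector of bit masks
#' @keywords internal
gen_strings <- function(n, k) {
  stopifnot(n >= 0, n <= 16, k >= 0, k <= n)
  if (k == 0L) return(0L)
  cols <- utils::combn(n, k)
  masks <- as.integer(colSums(matrix(bitwShiftL(1L, cols - 1L), nrow = k)))
  sort(masks)
}

.sector_cache <- new.env(parent = emptyenv())

#' Sector space descriptor
#'
#' Cached basis of a fixed (n_orb, n_alpha, n_beta) determinant sector.
#' @keywords internal
sector_space <- function(norb, na, nb) {
  key <- paste(norb, na, nb, sep = ":")
  sp <- .sector_cache[[key]]
  if (!is.null(sp)) return(sp)
  if (na < 0 || nb < 0 || na > norb || nb > norb)
    return(NULL)
  astr <- gen_strings(norb, na)
  bstr <- gen_strings(norb, nb)
  sp <- list(norb = norb, na = na, nb = nb,
             astr = astr, bstr = bstr,
             n_astr = length(astr), n_bstr = length(bstr),
             dim = length(astr) * length(bstr), key = key)
  assign(key, sp, envir = .sector_cache)
  sp
}

sector_state <- function(space, coef = NULL) {
  if (is.null(coef)) coef <- matrix(0, space$n_astr, space$n_bstr)
  list(space = space, coef = coef)
}

state_zero_like <- function(space) sector_state(space)

state_dot <- function(x, y) {
  if (!identical(x$space$key, y$space$key)) return(0)
  sum(x$coef * y$coef)
}

state_norm <- function(x) sqrt(sum(x$coef^2))

state_axpy <- function(a, x, y) {
  # a*x + y, same sector
  y$coef <- y$coef + a * x$coef
  y
}

# sign picked up moving an operator for orbital p past occupied bits below p
.parity_sign <- function(str, p) {
  below <- bitwAnd(str, bitwShiftL(1L, p - 1L) - 1L)
  ifelse(bitwAnd(popcount(below), 1L) == 1L, -1, 1)
}

#' Apply a single creation/annihilation spin-orbital operator
#'
#' @param state sector state
#' @param p spatial orbital (1-based, fragment-local)
#' @param spin 1 = alpha, 2 = beta
#' @param dagger TRUE for creation
#' @return new sector state, or NULL when the target sector is empty
#' @keywords internal
apply_so <- function(state, p, spin, dagger) {
  sp <- state$space
  bit <- bitwShiftL(1L, p - 1L)
  if (spin == 1L) {
    tsp <- sector_space(sp$norb, sp$na + if (dagger) 1L else -1L, sp$nb)
    if (is.null(tsp)) return(NULL)
    occ <- bitwAnd(sp$astr, bit) != 0L
    keep <- if (dagger) !occ else occ
    out <- sector_state(tsp)
    if (!any(keep)) return(out)
    src <- which(keep)
    newstr <- bitwXor(sp$astr[src], bit)
    sgn <- .parity_sign(sp$astr[src], p)
    idx <- match(newstr, tsp$astr)
    out$coef[idx, ] <- sgn * state$coef[src, , drop = FALSE]
    out
  } else {
    tsp <- sector_space(sp$norb, sp$na, sp$nb + if (dagger) 1L else -1L)
    if (is.null(tsp)) return(NULL)
    occ <- bitwAnd(sp$bstr, bit) != 0L
    keep <- if (dagger) !occ else occ
    out <- sector_state(tsp)
    if (!any(keep)) return(out)
    src <- which(keep)
    newstr <- bitwXor(sp$bstr[src], bit)
    sgn <- .parity_sign(sp$bstr[src], p)
    # crossing the whole alpha block
    gsgn <- if (bitwAnd(sp$na, 1L) == 1L) -1 else 1
    idx <- match(newstr, tsp$bstr)
    out$coef[, idx] <- state$coef[, src, drop = FALSE] *
      rep(gsgn * sgn, each = nrow(state$coef))
    out
  }
}

# Apply an ordered elementary operator string o1 o2 ... ok (rightmost acts
# first).  ops: matrix with columns p, spin, dagger.
apply_opstring <- function(state, ops) {
  if (is.null(state)) return(NULL)
  n <- nrow(ops)
  if (n == 0L) return(state)
  for (i in seq(n, 1L)) {
    state <- apply_so(state, ops[i, 1L], ops[i, 2L], ops[i, 3L])
    if (is.null(state)) return(NULL)
  }
  state
}

# Spin-summed excitation E_pq = sum_s a^+_{ps} a_{qs}
apply_Epq <- function(state, p, q) {
  xa <- apply_opstring(state, rbind(c(p, 1L, 1L), c(q, 1L, 0L)))
  xb <- apply_opstring(state, rbind(c(p, 2L, 1L), c(q, 2L, 0L)))
  if (is.null(xa)) return(xb)
  if (is.null(xb)) return(xa)
  xa$coef <- xa$coef + xb$coef
  xa
}
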