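# Active-space Hamiltonian container, FCIDUMP interface, fragment partition.

#' Active-space Hamiltonian
#'
#' Container for a spin-free active-space Hamiltonian
#' `H = e_core + sum h_pq E_pq + 1/2 sum (pq|rs) e_pqrs` in chemists'
#' integral convention.  `h` must be symmetric and `g` must carry the 8-fold
#' permutational symmetry `(pq|rs) = (qp|rs) = (pq|sr) = (rs|pq)`.
#'
#' @param h one-electron integral matrix (Hartree)
#' @param g two-electron integral array, chemists' `(pq|rs)` (Hartree)
#' @param e_core scalar core energy (Hartree)
#' @param validate check symmetries (1e-10) and finiteness
#' @return object of class `active_hamiltonian`
#' @export
active_hamiltonian <- function(h, g, e_core = 0, validate = TRUE) {
  n <- nrow(h)
  stopifnot(n >= 1, identical(dim(g), as.integer(rep(n, 4))) ||
              identical(dim(g), rep(n, 4)))
  H <- structure(list(n_orb = n, e_core = as.numeric(e_core),
                      h = unname(as.matrix(h)), g = unname(g)),
                 class = "active_hamiltonian")
  if (validate) validate_hamiltonian(H)
  H
}

validate_hamiltonian <- function(H, tol = 1e-10) {
  stopifnot(all(is.finite(H$h)), all(is.finite(H$g)), is.finite(H$e_core))
  if (max(abs(H$h - t(H$h))) > tol)
    stop("one-electron integrals not symmetric")
  g <- H$g
  if (max(abs(g - aperm(g, c(2, 1, 3, 4)))) > tol ||
      max(abs(g - aperm(g, c(1, 2, 4, 3)))) > tol ||
      max(abs(g - aperm(g, c(3, 4, 1, 2)))) > tol)
    stop("two-electron integrals lack 8-fold permutational symmetry")
  invisible(TRUE)
}

#' @export
print.active_hamiltonian <- function(x, ...) {
  cat(sprintf("<active_hamiltonian> %d orbitals, e_core = %.8f\n",
              x$n_orb, x$e_core))
  invisible(x)
}

#' Fragment partition of an active space
#'
#' Assigns every active orbital to fragment A or B and fixes each fragment's
#' electron number and spin projection.  Orbital ordering convention: all A
#' orbitals precede all B orbitals.
#'
#' @param fragment_of character vector ("A"/"B"), one entry per orbital
#' @param n_elec named vector `c(A =, B =)` of electron counts
#' @param ms2 named vector `c(A =, B =)` of 2*Sz (integer)
#' @return object of class `fragment_partition`
#' @export
fragment_partition <- function(fragment_of, n_elec, ms2 = c(A = 0L, B = 0L)) {
  fragment_of <- as.character(fragment_of)
  stopifnot(all(fragment_of %in% c("A", "B")),
            all(c("A", "B") %in% names(n_elec)),
            all(c("A", "B") %in% names(ms2)))
  nA <- sum(fragment_of == "A"); nB <- sum(fragment_of == "B")
  if (nA == 0 || nB == 0) stop("both fragments must be non-empty")
  if (any(fragment_of != rep(c("A", "B"), c(nA, nB))))
    stop("all A orbitals must precede all B orbitals")
  for (f in c("A", "B")) {
    ne <- n_elec[[f]]; m <- ms2[[f]]
    no <- if (f == "A") nA else nB
    if (ne < 0 || ne > 2 * no)
      stop("electron count out of range for fragment ", f)
    if (abs(m) > ne || (ne - m) %% 2 != 0)
      stop("2*Sz incompatible with electron count for fragment ", f)
  }
  structure(list(fragment_of = fragment_of,
                 n_elec = c(A = as.integer(n_elec[["A"]]),
                            B = as.integer(n_elec[["B"]])),
                 ms2 = c(A = as.integer(ms2[["A"]]),
                         B = as.integer(ms2[["B"]])),
                 n_orb = length(fragment_of),
                 idx_A = seq_len(nA), idx_B = nA + seq_len(nB)),
            class = "fragment_partition")
}

#' @export
print.fragment_partition <- function(x, ...) {
  cat(sprintf(
    "<fragment_partition> A: %d orbitals, %d e-, 2Sz=%d | B: %d orbitals, %d e-, 2Sz=%d\n",
    length(x$idx_A), x$n_elec[["A"]], x$ms2[["A"]],
    length(x$idx_B), x$n_elec[["B"]], x$ms2[["B"]]))
  invisible(x)
}

# per-fragment (na, nb) from n_elec and ms2
fragment_sector <- function(partition, frag) {
  ne <- partition$n_elec[[frag]]
  m <- partition$ms2[[frag]]
  c(na = (ne + m) %/% 2L, nb = (ne - m) %/% 2L)
}

#' Read an FCIDUMP file
#'
#' Standard FCIDUMP text format: a `&FCI ... &END` (or `/`) namelist header
#' with NORB/NELEC/MS2, followed by `value p q r s` records (1-based).
#' Records with `r = s = 0` are one-electron integrals, `p q r s = 0` is the
#' core energy.  Stored unique elements are expanded to full 8-fold symmetry.
#'
#' @param path file path
#' @return list with `hamiltonian` (an [active_hamiltonian()]), `n_elec`,
#'   `ms2`
#' @export
read_fcidump <- function(path) {
  stopifnot(file.exists(path))
  txt <- readLines(path, warn = FALSE)
  hdr_end <- grep("(&END|/)\\s*$", toupper(txt))[1]
  if (is.na(hdr_end)) stop("malformed FCIDUMP: no namelist terminator")
  hdr <- paste(txt[seq_len(hdr_end)], collapse = " ")
  getkey <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "\\s*=\\s*-?[0-9]+"), hdr,
                                 ignore.case = TRUE))
    if (length(m) == 0) stop("malformed FCIDUMP header: missing ", key)
    as.integer(sub(".*=\\s*", "", m))
  }
  norb <- getkey("NORB"); nelec <- getkey("NELEC")
  ms2 <- tryCatch(getkey("MS2"), error = function(e) 0L)
  body <- txt[seq(hdr_end + 1L, length(txt))]
  body <- body[nzchar(trimws(body))]
  rec <- utils::read.table(text = body,
                           col.names = c("x", "p", "q", "r", "s"))
  h <- matrix(0, norb, norb)
  g <- array(0, rep(norb, 4))
  e_core <- 0
  for (i in seq_len(nrow(rec))) {
    p <- rec$p[i]; q <- rec$q[i]; r <- rec$r[i]; s <- rec$s[i]
    x <- rec$x[i]
    if (p == 0 && q == 0 && r == 0 && s == 0) {
      e_core <- x
    } else if (r == 0 && s == 0) {
      if (p < 1 || p > norb || q < 1 || q > norb)
        stop("FCIDUMP index out of range")
      h[p, q] <- x; h[q, p] <- x
    } else {
      if (any(c(p, q, r, s) < 1) || any(c(p, q, r, s) > norb))
        stop("FCIDUMP index out of range")
      for (pq in list(c(p, q), c(q, p))) for (rs in list(c(r, s), c(s, r))) {
        g[pq[1], pq[2], rs[1], rs[2]] <- x
        g[rs[1], rs[2], pq[1], pq[2]] <- x
      }
    }
  }
  list(hamiltonian = active_hamiltonian(h, g, e_core),
       n_elec = nelec, ms2 = ms2)
}

#' Write an FCIDUMP file
#'
#' @param H an [active_hamiltonian()]
#' @param path output path
#' @param n_elec total electron count for the header
#' @param ms2 2*Sz for the header
#' @param tol drop integrals smaller than this in magnitude
#' @export
write_fcidump <- function(H, path, n_elec, ms2 = 0L, tol = 1e-14) {
  n <- H$n_orb
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf(" &FCI NORB=%d,NELEC=%d,MS2=%d,", n, n_elec, ms2),
               paste0("  ORBSYM=", paste(rep(1L, n), collapse = ","), ","),
               "  ISYM=1,", " &END"), con)
  fmt <- function(x, p, q, r, s) sprintf("%23.16E %4d %4d %4d %4d", x, p, q, r, s)
  out <- character(0)
  for (p in 1:n) for (q in 1:p) for (r in 1:p) {
    smax <- if (r == p) q else r
    for (s in 1:smax) {
      x <- H$g[p, q, r, s]
      if (abs(x) > tol) out <- c(out, fmt(x, p, q, r, s))
    }
  }
  for (p in 1:n) for (q in 1:p) {
    if (abs(H$h[p, q]) > tol) out <- c(out, fmt(H$h[p, q], p, q, 0L, 0L))
  }
  out <- c(out, fmt(H$e_core, 0L, 0L, 0L, 0L))
  writeLines(out, con)
  invisible(path)
}

#' Read a fragment partition file
#'
#' Plain-text format: header lines `nelec <A|B> <count>` and `ms2 <A|B>
#' <2Sz>`, then one line per active orbital `"<index> <A|B>"` with 0-based
#' orbital indices.  Lines starting with `#` are comments.
#' @param path file path
#' @return a [fragment_partition()]
#' @export
read_partition <- function(path) {
  txt <- trimws(readLines(path, warn = FALSE))
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  ne <- c(A = NA_integer_, B = NA_integer_)
  m2 <- c(A = 0L, B = 0L)
  orb <- integer(0); lab <- character(0)
  for (line in txt) {
    f <- strsplit(line, "\\s+")[[1]]
    if (tolower(f[1]) == "nelec") {
      ne[[f[2]]] <- as.integer(f[3])
    } else if (tolower(f[1]) == "ms2") {
      m2[[f[2]]] <- as.integer(f[3])
    } else {
      orb <- c(orb, as.integer(f[1])); lab <- c(lab, f[2])
    }
  }
  if (any(is.na(ne))) stop("partition file missing nelec lines")
  o <- order(orb)
  if (!identical(orb[o], seq_along(orb) - 1L))
    stop("partition file must list every orbital 0..n-1 exactly once")
  fragment_partition(lab[o], ne, m2)
}

#' Write a fragment partition file
#' @param partition a [fragment_partition()]
#' @param path output path
#' @export
write_partition <- function(partition, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fragment partition: orbital index (0-based) -> fragment",
               sprintf("nelec A %d", partition$n_elec[["A"]]),
               sprintf("nelec B %d", partition$n_elec[["B"]]),
               sprintf("ms2 A %d", partition$ms2[["A"]]),
               sprintf("ms2 B %d", partition$ms2[["B"]]),
               sprintf("%d %s", seq_along(partition$fragment_of) - 1L,
                       partition$fragment_of)), con)
  invisible(path)
}

# extract fragment-local integrals
local_integrals <- function(H, partition, frag) {
  idx <- if (frag == "A") partition$idx_A else partition$idx_B
  list(h = H$h[idx, idx, drop = FALSE],
       g = H$g[idx, idx, idx, idx, drop = FALSE],
       idx = idx)
}

#' Swap fragment labels A and B
#'
#' Reorders orbitals so the former B block comes first and swaps the
#' partition metadata; used for label-invariance checks.
#' @param H an [active_hamiltonian()]
#' @param partition a [fragment_partition()]
#' @return list with permuted `hamiltonian` and `partition`
#' @export
swap_fragments <- function(H, partition) {
  perm <- c(partition$idx_B, partition$idx_A)
  h2 <- H$h[perm, perm]
  g2 <- H$g[perm, perm, perm, perm]
  p2 <- fragment_partition(rep(c("A", "B"),
                               c(length(partition$idx_B),
                                 length(partition$idx_A))),
                           n_elec = c(A = partition$n_elec[["B"]],
                                      B = partition$n_elec[["A"]]),
                           ms2 = c(A = partition$ms2[["B"]],
                                   B = partition$ms2[["A"]]))
  list(hamiltonian = active_hamiltonian(h2, g2, H$e_core), partition = p2)
}
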