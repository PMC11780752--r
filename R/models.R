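# Deterministic generators for test inputs: seeded synthetic two-fragment
# Hamiltonians and the benchmark geometries (parallel N2 dimer, s-trans
# butadiene, an idealized biaryl builder for qualitative scans).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

symmetrize8 <- function(g) {
  (g + aperm(g, c(2, 1, 3, 4)) + aperm(g, c(1, 2, 4, 3)) +
     aperm(g, c(2, 1, 4, 3)) + aperm(g, c(3, 4, 1, 2)) +
     aperm(g, c(4, 3, 1, 2)) + aperm(g, c(3, 4, 2, 1)) +
     aperm(g, c(4, 3, 2, 1))) / 8
}

#' Seeded synthetic two-fragment model Hamiltonian
#'
#' Deterministic random (or Hubbard-chain) two-fragment active-space
#' Hamiltonians with all interfragment one- and two-electron integrals
#' scaled by a coupling strength `lambda`; `lambda = 0` gives exactly
#' non-interacting fragments.  The random ensemble uses spread one-electron
#' diagonals and weak random off-diagonals/two-electron integrals so that
#' fragment ground states are generically non-degenerate closed-shell-like
#' singlets (see the package vignette).
#'
#' @param n_orb orbitals per fragment, `c(A =, B =)`
#' @param n_elec electrons per fragment, `c(A =, B =)`
#' @param ms2 2*Sz per fragment, `c(A =, B =)`
#' @param lambda interfragment coupling scale in `[0, 1]`
#' @param seed integer seed (identical spec -> bit-identical Hamiltonian)
#' @param style `"random_symmetric"` or `"hubbard_chain"`
#' @param t,U Hubbard hopping and on-site repulsion (chain style only)
#' @return list with `hamiltonian` and `partition`
#' @export
model_hamiltonian <- function(n_orb = c(A = 2L, B = 2L),
                              n_elec = c(A = 2L, B = 2L),
                              ms2 = c(A = 0L, B = 0L),
                              lambda = 0.1, seed = 1L,
                              style = c("random_symmetric", "hubbard_chain"),
                              t = 1, U = 4) {
  style <- match.arg(style)
  nA <- as.integer(n_orb[["A"]]); nB <- as.integer(n_orb[["B"]])
  n <- nA + nB
  frag <- rep(c("A", "B"), c(nA, nB))
  cross1 <- outer(frag, frag, `!=`)
  fr4 <- array(FALSE, rep(n, 4))
  for (p in 1:n) for (q in 1:n) for (r in 1:n) for (s in 1:n)
    fr4[p, q, r, s] <- !all(frag[c(p, q, r, s)] == frag[p])
  if (style == "random_symmetric") {
    # design: spread one-electron levels plus a dominant on-site repulsion
    # give every fragment a non-degenerate singlet ground state and a solid
    # charge gap, so the zeroth-order Hamiltonian has its ground state in
    # the reference sector and perturbation denominators stay positive
    hg <- with_seed(seed, {
      h <- matrix(stats::rnorm(n * n, sd = 0.08), n, n)
      h <- (h + t(h)) / 2
      # level ladders anchored at each fragment's own filling (HOMO ~ -1,
      # LUMO ~ 0) so interfragment charge transfer is uphill, as for
      # neutral molecular fragments
      noccA <- ceiling(n_elec[["A"]] / 2); noccB <- ceiling(n_elec[["B"]] / 2)
      diag(h) <- c((seq_len(nA) - noccA) * 1.0 - 1.0,
                   (seq_len(nB) - noccB) * 1.0 - 0.93)
      g <- array(stats::rnorm(n^4, sd = 0.04), rep(n, 4))
      g <- symmetrize8(g)
      for (p in 1:n) g[p, p, p, p] <- g[p, p, p, p] + 0.5
      list(h = h, g = g)
    })
    h <- hg$h; g <- hg$g
  } else {
    h <- matrix(0, n, n)
    for (p in seq_len(n - 1)) h[p, p + 1] <- h[p + 1, p] <- -t
    g <- array(0, rep(n, 4))
    for (p in 1:n) g[p, p, p, p] <- U
  }
  h[cross1] <- lambda * h[cross1]
  g[fr4] <- lambda * g[fr4]
  list(hamiltonian = active_hamiltonian(h, g, e_core = 0),
       partition = fragment_partition(frag, n_elec, ms2))
}

# ---- geometries -------------------------------------------------------------

new_geometry <- function(symbols, coords, fragment_atoms = NULL,
                         comment = "") {
  structure(list(symbols = symbols,
                 coords = matrix(coords, ncol = 3),
                 fragment_atoms = fragment_atoms, comment = comment),
            class = "molecular_geometry")
}

#' @export
print.molecular_geometry <- function(x, ...) {
  cat(sprintf("<molecular_geometry> %d atoms (%s)\n", length(x$symbols),
              x$comment))
  invisible(x)
}

#' Write a geometry in XYZ format (Angstrom)
#' @param geom a `molecular_geometry`
#' @param path output path
#' @export
write_xyz <- function(geom, path) {
  lines <- c(sprintf("%d", length(geom$symbols)), geom$comment,
             sprintf("%-2s %18.12f %18.12f %18.12f", geom$symbols,
                     geom$coords[, 1], geom$coords[, 2], geom$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ geometry file (Angstrom)
#' @param path file path
#' @return a `molecular_geometry`
#' @export
read_xyz <- function(path) {
  txt <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(txt[1]))
  rec <- utils::read.table(text = paste(txt[3:(2 + n)], collapse = "\n"),
                           col.names = c("sym", "x", "y", "z"))
  new_geometry(as.character(rec$sym), cbind(rec$x, rec$y, rec$z),
               comment = if (length(txt) >= 2) txt[2] else "")
}

#' Parallel N2 dimer geometry
#'
#' Two parallel N2 molecules with centers `separation` apart (perpendicular
#' to the molecular axes); the right molecule's bond length is the scan
#' variable.
#'
#' @param separation center-to-center distance (Angstrom)
#' @param bond_left left (fixed) N-N bond length (Angstrom)
#' @param bond_right right (scanned) N-N bond length (Angstrom)
#' @return a `molecular_geometry` with fragments = the two molecules
#' @export
n2_dimer_geometry <- function(separation = 2.0, bond_left = 1.2,
                              bond_right = bond_left) {
  stopifnot(separation > 0, bond_left > 0, bond_right > 0)
  coords <- rbind(c(0, 0, bond_left / 2), c(0, 0, -bond_left / 2),
                  c(separation, 0, bond_right / 2),
                  c(separation, 0, -bond_right / 2))
  new_geometry(rep("N", 4), coords,
               fragment_atoms = list(A = 1:2, B = 3:4),
               comment = sprintf(
                 "N2 dimer: sep %.3f A, bonds %.3f / %.3f A",
                 separation, bond_left, bond_right))
}

rot2 <- function(theta) matrix(c(cos(theta), sin(theta),
                                 -sin(theta), cos(theta)), 2, 2)

#' Planar s-trans butadiene geometry
#'
#' Idealized planar s-trans butadiene from standard bond lengths (C=C 1.34,
#' C-C 1.46, C-H 1.09 Angstrom, 120 degree angles).  `stretch` elongates the
#' terminal double bond of the second fragment (C3=C4) toward dissociation,
#' displacing the terminal CH2 group along the bond.
#'
#' @param stretch bond-length offset (Angstrom) added to one C=C
#' @return a `molecular_geometry`; fragments split the central C2-C3 bond
#' @export
butadiene_geometry <- function(stretch = 0) {
  dcc <- 1.46; dce <- 1.34; dch <- 1.09
  deg <- pi / 180
  C2 <- c(0, 0); C3 <- c(dcc, 0)
  C1 <- C2 + dce * c(cos(120 * deg), sin(120 * deg))
  C4 <- C3 + dce * c(cos(-60 * deg), sin(-60 * deg))
  unitv <- function(v) v / sqrt(sum(v^2))
  h_at <- function(atom, towards1, towards2 = NULL) {
    # hydrogen opposite the average of the bond directions
    d <- unitv(towards1 - atom)
    if (!is.null(towards2)) d <- unitv(d + unitv(towards2 - atom))
    atom - dch * d
  }
  # terminal CH2 on C1: two H at +-120 deg from the C1->C2 direction
  d12 <- unitv(C2 - C1)
  H1a <- C1 + dch * as.numeric(rot2(120 * deg) %*% d12)
  H1b <- C1 + dch * as.numeric(rot2(-120 * deg) %*% d12)
  H2 <- h_at(C2, C1, C3)
  H3 <- h_at(C3, C2, C4)
  d43 <- unitv(C3 - C4)
  H4a <- C4 + dch * as.numeric(rot2(120 * deg) %*% d43)
  H4b <- C4 + dch * as.numeric(rot2(-120 * deg) %*% d43)
  if (stretch != 0) {
    shift <- stretch * unitv(C4 - C3)
    C4 <- C4 + shift; H4a <- H4a + shift; H4b <- H4b + shift
  }
  xy <- rbind(C1, C2, H1a, H1b, H2, C3, C4, H3, H4a, H4b)
  coords <- cbind(xy, 0)
  new_geometry(c("C", "C", "H", "H", "H", "C", "C", "H", "H", "H"), coords,
               fragment_atoms = list(A = 1:5, B = 6:10),
               comment = sprintf("s-trans butadiene, C3=C4 stretched %+.3f A",
                                 stretch))
}

#' Idealized biaryl geometry (synthetic, non-reference)
#'
#' Two idealized benzene rings joined by a single C-C bond with a variable
#' dihedral angle.  This is a synthetic construction from textbook bond
#' lengths for qualitative dihedral scans only; it does not reproduce any
#' published biaryl geometry set.
#'
#' @param dihedral ring-ring dihedral angle (degrees)
#' @param rcc ring C-C bond length (Angstrom)
#' @param rlink inter-ring C-C bond length (Angstrom)
#' @param rch C-H bond length (Angstrom)
#' @return a `molecular_geometry`; fragments = the two rings
#' @export
biaryl_geometry <- function(dihedral = 45, rcc = 1.40, rlink = 1.48,
                            rch = 1.09) {
  deg <- pi / 180
  ring <- function() {
    ang <- (0:5) * 60 * deg
    r <- rcc
    cbind(r * cos(ang), r * sin(ang), 0)
  }
  # each ring with its ipso carbon (index 1) at the origin; ring A extends
  # toward -x, ring B is mirrored toward +x before translation to the link
  A <- ring()
  A <- A - matrix(A[1, ], 6, 3, byrow = TRUE)
  cenA <- colMeans(A)
  HA <- t(apply(A[2:6, ], 1, function(p) {
    d <- p - cenA; p + rch * d / sqrt(sum(d^2))
  }))
  B <- ring()
  B <- B - matrix(B[1, ], 6, 3, byrow = TRUE)
  B[, 1] <- -B[, 1]
  cenB <- colMeans(B)
  HB <- t(apply(B[2:6, ], 1, function(p) {
    d <- p - cenB; p + rch * d / sqrt(sum(d^2))
  }))
  # rotate ring B about the link axis (x) by the dihedral, then translate
  Rd <- matrix(c(1, 0, 0,
                 0, cos(dihedral * deg), sin(dihedral * deg),
                 0, -sin(dihedral * deg), cos(dihedral * deg)), 3, 3)
  B <- B %*% Rd; HB <- HB %*% Rd
  B[, 1] <- B[, 1] + rlink; HB[, 1] <- HB[, 1] + rlink
  coords <- rbind(A, HA, B, HB)
  new_geometry(rep(c("C", "H", "C", "H"), c(6, 5, 6, 5)), coords,
               fragment_atoms = list(A = 1:11, B = 12:22),
               comment = sprintf(
                 "idealized biaryl (synthetic), dihedral %.1f deg", dihedral))
}
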