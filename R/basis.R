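# Basis-set loading and molecule/AO-integral plumbing for the built-in
# mean-field backend.

.elements <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
               F = 9, Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15,
               S = 16, Cl = 17, Ar = 18)

ANG2BOHR <- 1.8897259886

#' Build a molecule object
#'
#' @param symbols element symbols
#' @param coords n x 3 matrix of coordinates in Angstrom
#' @param charge total charge
#' @return object of class `molecule`
#' @export
molecule <- function(symbols, coords, charge = 0L) {
  Z <- unname(.elements[symbols])
  if (anyNA(Z)) stop("unknown element(s): ",
                     paste(symbols[is.na(Z)], collapse = ", "))
  xyz <- matrix(coords, ncol = 3) * ANG2BOHR
  n_elec <- sum(Z) - charge
  enuc <- 0
  n <- length(Z)
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      enuc <- enuc + Z[i] * Z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  structure(list(symbols = symbols, Z = as.numeric(Z), xyz = xyz,
                 charge = charge, n_elec = n_elec, e_nuc = enuc),
            class = "molecule")
}

as_molecule <- function(geom, charge = 0L) {
  if (inherits(geom, "molecule")) return(geom)
  molecule(geom$symbols, geom$coords, charge)
}

dfact_r <- function(l) if (l <= 0) 1 else prod(seq(2 * l - 1, 1, by = -2))

#' Load a basis set definition
#'
#' Parses the plain-text basis files shipped under `inst/extdata/basis`
#' (STO-3G, 6-31G, cc-pVDZ in the Cartesian convention), normalizes the
#' primitives and renormalizes every contracted function to unit self
#' overlap.  The pre-normalization deviation of each contraction from unity
#' is kept as a transcription diagnostic.
#'
#' @param name basis name (file name without extension) or a file path
#' @return named list element -> list of shells `(l, exps, coefs)`
#' @export
load_basis <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "basis", paste0(tolower(name), ".bas"),
                package = "fragpt2")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown basis set: ", name)
  txt <- trimws(readLines(path, warn = FALSE))
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  out <- list()
  cur <- NULL; el <- NULL
  shell_l <- c(S = 0L, P = 1L, D = 2L, F = 3L)
  i <- 1
  flush_shell <- function(cur, lchr, rows) {
    rows <- do.call(rbind, rows)
    if (lchr == "SP") {
      cur[[length(cur) + 1]] <- list(l = 0L, exps = rows[, 1], coefs = rows[, 2])
      cur[[length(cur) + 1]] <- list(l = 1L, exps = rows[, 1], coefs = rows[, 3])
    } else {
      cur[[length(cur) + 1]] <- list(l = shell_l[[lchr]], exps = rows[, 1],
                                     coefs = rows[, 2])
    }
    cur
  }
  lchr <- NULL; rows <- list()
  for (line in txt) {
    f <- strsplit(line, "\\s+")[[1]]
    if (tolower(f[1]) == "element") {
      el <- f[2]; cur <- list(); lchr <- NULL; rows <- list()
    } else if (tolower(f[1]) == "end") {
      if (!is.null(lchr)) cur <- flush_shell(cur, lchr, rows)
      out[[el]] <- cur; cur <- NULL; lchr <- NULL; rows <- list()
    } else if (toupper(f[1]) %in% c("S", "P", "D", "F", "SP")) {
      if (!is.null(lchr)) cur <- flush_shell(cur, lchr, rows)
      lchr <- toupper(f[1]); rows <- list()
    } else {
      rows[[length(rows) + 1]] <- as.numeric(f)
    }
  }
  # normalize
  for (el in names(out)) {
    for (k in seq_along(out[[el]])) {
      sh <- out[[el]][[k]]
      l <- sh$l; a <- sh$exps; c0 <- sh$coefs
      nprim <- (2 * a / pi)^0.75 * sqrt((4 * a)^l / dfact_r(l))
      cs <- c0 * nprim
      p <- outer(a, a, `+`)
      Sij <- (pi / p)^1.5 * dfact_r(l) / (2 * p)^l
      norm <- as.numeric(t(cs) %*% Sij %*% cs)
      out[[el]][[k]]$coefs_scaled <- cs / sqrt(norm)
      # tabulated coefficients should already be near-normalized; a large
      # deviation flags a transcription error
      out[[el]][[k]]$norm_deviation <- abs(norm - 1)
    }
  }
  out
}

#' AO integrals for a molecule
#'
#' Overlap, kinetic, nuclear-attraction and two-electron repulsion integrals
#' over contracted Cartesian Gaussians, computed by the compiled
#' McMurchie-Davidson engine.
#'
#' @param mol a [molecule()] (or `molecular_geometry`)
#' @param basis basis-set name
#' @return list with `S`, `T`, `V`, `eri` (chemists' `(pq|rs)` array),
#'   `hcore`, `nao`, `ao_atom` (AO -> atom map) and `e_nuc`
#' @export
ao_integrals <- function(mol, basis = "sto-3g") {
  mol <- as_molecule(mol)
  bs <- load_basis(basis)
  lv <- integer(0); np <- integer(0); ex <- numeric(0); cf <- numeric(0)
  centers <- NULL; ao_atom <- integer(0)
  for (ia in seq_along(mol$symbols)) {
    el <- mol$symbols[ia]
    if (is.null(bs[[el]]))
      stop("basis has no entry for element ", el)
    for (sh in bs[[el]]) {
      lv <- c(lv, sh$l); np <- c(np, length(sh$exps))
      ex <- c(ex, sh$exps); cf <- c(cf, sh$coefs_scaled)
      centers <- rbind(centers, mol$xyz[ia, ])
      ao_atom <- c(ao_atom, rep(ia, (sh$l + 1) * (sh$l + 2) / 2))
    }
  }
  res <- ao_integrals_cpp(lv, np, ex, cf, centers, mol$Z, mol$xyz,
                          do_eri = TRUE)
  nao <- res$nao
  eri <- res$eri
  dim(eri) <- rep(nao, 4)
  list(S = res$S, T = res$T, V = res$V, eri = eri,
       hcore = res$T + res$V, nao = nao, ao_atom = ao_atom,
       e_nuc = mol$e_nuc, mol = mol, basis = basis)
}
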