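#!/usr/bin/env Rscript
# OPTIONAL long-running benchmark (not part of the default test suite, not
# run by scripts/acceptance.R): dihedral scan of the idealized biaryl dimer
# with the pi systems of the two rings as fragment active spaces, comparing
# the fragment-embedding energy and its perturbative correction against the
# full CASCI(12,12) reference.
#
# The geometry is the package's synthetic idealized biaryl builder (textbook
# bond lengths), NOT any published biaryl geometry set, so the numbers are
# qualitative.  Expect ~10-30 min per dihedral point.
#
#   Rscript scripts/benchmark_biaryl.R [dihedrals...]   (default 0 45 90)

suppressMessages(library(fragpt2))

args <- commandArgs(trailingOnly = TRUE)
dihedrals <- if (length(args)) as.numeric(args) else c(0, 45, 90)

for (phi in dihedrals) {
  t0 <- Sys.time()
  geom <- biaryl_geometry(dihedral = phi)
  rec <- run_pipeline(list(geometry = geom, basis = "sto-3g",
                           active = list(A = c(3, 3), B = c(3, 3)),
                           oracle = TRUE))
  corr <- rec$e_hf_reference - rec$e_exact
  frac0 <- (rec$e_hf_reference - rec$e0) / corr
  frac2 <- (rec$e_hf_reference - rec$e_total) / corr
  cat(sprintf(paste0(
    "phi %5.1f: E_HF %.6f  E0 %.6f  E0+E2 %.6f  Eexact %.6f | ",
    "corr. recovered: %5.1f%% (embedding) %5.1f%% (with PT2) | %.0fs\n"),
    phi, rec$e_hf_reference, rec$e0, rec$e_total, rec$e_exact,
    100 * frac0, 100 * frac2, as.numeric(Sys.time()) - as.numeric(t0)))
}
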