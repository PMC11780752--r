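# Seeded model generators and benchmark geometries.

test_that("model generation is deterministic and symmetric", {
  m1 <- model_hamiltonian(lambda = 0.3, seed = 42)
  m2 <- model_hamiltonian(lambda = 0.3, seed = 42)
  expect_identical(m1$hamiltonian$h, m2$hamiltonian$h)
  expect_identical(m1$hamiltonian$g, m2$hamiltonian$g)
  m3 <- model_hamiltonian(lambda = 0.3, seed = 43)
  expect_gt(max(abs(m1$hamiltonian$h - m3$hamiltonian$h)), 1e-6)
  expect_silent(fragpt2:::validate_hamiltonian(m1$hamiltonian))
  # generation does not disturb the session RNG stream
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(model_hamiltonian(seed = 9)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("coupling scale multiplies exactly the interfragment blocks", {
  m0 <- model_hamiltonian(lambda = 0, seed = 7)
  m5 <- model_hamiltonian(lambda = 0.5, seed = 7)
  m1 <- model_hamiltonian(lambda = 1, seed = 7)
  iA <- 1:2; iB <- 3:4
  expect_identical(m0$hamiltonian$h[iA, iA], m1$hamiltonian$h[iA, iA])
  expect_equal(max(abs(m0$hamiltonian$h[iA, iB])), 0)
  expect_equal(m5$hamiltonian$h[iA, iB], 0.5 * m1$hamiltonian$h[iA, iB])
  expect_equal(m5$hamiltonian$g[1, 2, 3, 4], 0.5 * m1$hamiltonian$g[1, 2, 3, 4])
  expect_identical(m5$hamiltonian$g[iA, iA, iA, iA],
                   m1$hamiltonian$g[iA, iA, iA, iA])
})

test_that("Hubbard chain matches an independently built Hamiltonian", {
  m <- model_hamiltonian(n_orb = c(A = 2L, B = 2L), n_elec = c(A = 2L, B = 2L),
                         lambda = 1, seed = 1, style = "hubbard_chain",
                         t = 1, U = 4)
  ex <- full_casci(m$hamiltonian, 4, 0)
  # independent dense construction: spin-orbital occupation-number vectors
  # (orbital-major: site1a..4a, site1b..4b), first-quantized enumeration
  occs <- expand.grid(rep(list(0:1), 8))
  occs <- occs[rowSums(occs[, 1:4]) == 2 & rowSums(occs[, 5:8]) == 2, ]
  occs <- as.matrix(occs)
  nd <- nrow(occs)
  Hm <- matrix(0, nd, nd)
  key <- apply(occs, 1, paste, collapse = "")
  sgn_ann <- function(v, i) (-1)^sum(v[seq_len(i - 1)])
  for (d in seq_len(nd)) {
    v <- occs[d, ]
    Hm[d, d] <- 4 * sum(v[1:4] * v[5:8])
    for (sp in c(0L, 4L)) for (bond in 1:3) {
      i <- bond + sp; j <- bond + 1L + sp
      for (pair in list(c(i, j), c(j, i))) {
        a <- pair[1]; b <- pair[2]   # hop b -> a
        if (v[b] == 1 && v[a] == 0) {
          w <- v; s1 <- sgn_ann(w, b); w[b] <- 0
          s2 <- sgn_ann(w, a); w[a] <- 1
          dd <- match(paste(w, collapse = ""), key)
          Hm[dd, d] <- Hm[dd, d] - 1 * s1 * s2
        }
      }
    }
  }
  expect_equal(min(eigen(Hm, symmetric = TRUE, only.values = TRUE)$values),
               ex$e_exact, tolerance = 1e-10)
})

test_that("nitrogen dimer geometries have the requested metrics", {
  g <- n2_dimer_geometry()
  expect_equal(nrow(g$coords), 4)
  d12 <- sqrt(sum((g$coords[1, ] - g$coords[2, ])^2))
  d34 <- sqrt(sum((g$coords[3, ] - g$coords[4, ])^2))
  cen <- colMeans(g$coords[1:2, ]) - colMeans(g$coords[3:4, ])
  expect_equal(d12, 1.2, tolerance = 1e-12)
  expect_equal(d34, 1.2, tolerance = 1e-12)
  expect_equal(sqrt(sum(cen^2)), 2.0, tolerance = 1e-12)
  # axes parallel
  a1 <- g$coords[1, ] - g$coords[2, ]; a2 <- g$coords[3, ] - g$coords[4, ]
  expect_equal(abs(sum(a1 * a2)) / (sqrt(sum(a1^2)) * sqrt(sum(a2^2))), 1,
               tolerance = 1e-12)
  # equal bonds -> symmetric under fragment swap (mirror through the
  # midplane maps fragment A onto B)
  gs <- n2_dimer_geometry(2.0, 1.15, 1.15)
  mir <- gs$coords; mir[, 1] <- 2.0 - mir[, 1]
  expect_equal(mir[1:2, ], gs$coords[3:4, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # scan grid
  grid <- seq(0.9, 2.1, by = 0.1)
  expect_length(grid, 13)
  bonds <- vapply(grid, function(b) {
    gg <- n2_dimer_geometry(bond_right = b)
    sqrt(sum((gg$coords[3, ] - gg$coords[4, ])^2))
  }, 0)
  expect_equal(bonds, grid, tolerance = 1e-12)
})

test_that("butadiene geometry is planar with standard and stretched bonds", {
  g0 <- butadiene_geometry(0)
  expect_equal(nrow(g0$coords), 10)
  expect_equal(max(abs(g0$coords[, 3])), 0)
  d <- function(g, i, j) sqrt(sum((g$coords[i, ] - g$coords[j, ])^2))
  expect_equal(d(g0, 1, 2), 1.34, tolerance = 1e-12)  # C1=C2
  expect_equal(d(g0, 2, 6), 1.46, tolerance = 1e-12)  # C2-C3
  expect_equal(d(g0, 6, 7), 1.34, tolerance = 1e-12)  # C3=C4
  g1 <- butadiene_geometry(1.5)
  expect_equal(d(g1, 6, 7), 1.34 + 1.5, tolerance = 1e-12)
  expect_equal(d(g1, 1, 2), 1.34, tolerance = 1e-12)  # other bond untouched
  # C-H bond lengths
  expect_equal(d(g0, 1, 3), 1.09, tolerance = 1e-12)
  expect_equal(d(g0, 7, 9), 1.09, tolerance = 1e-12)
})

test_that("XYZ files round-trip", {
  g <- butadiene_geometry(0.3)
  p <- tempfile(fileext = ".xyz")
  write_xyz(g, p)
  rd <- read_xyz(p)
  expect_equal(rd$symbols, g$symbols)
  expect_equal(rd$coords, g$coords, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the idealized biaryl builder produces sane rings", {
  g <- biaryl_geometry(dihedral = 60)
  expect_equal(length(g$symbols), 22)
  d <- function(i, j) sqrt(sum((g$coords[i, ] - g$coords[j, ])^2))
  expect_equal(d(1, 12), 1.48, tolerance = 1e-10)   # link bond
  # ring bond lengths
  expect_equal(d(1, 2), 1.40, tolerance = 1e-10)
  # no steric collapse
  dm <- as.matrix(dist(g$coords))
  diag(dm) <- Inf
  expect_gt(min(dm), 0.9)
})
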