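# Self-consistent product-state embedding (mean-field decoupling).

test_that("effective Hamiltonian reduces to the bare one without coupling", {
  m <- model_hamiltonian(lambda = 0.3, seed = 6)
  W <- fragpt2:::interfragment_W(m$hamiltonian, m$partition)
  hA <- m$hamiltonian$h[1:2, 1:2]
  eff0 <- build_effective_hamiltonian(hA, W, matrix(0, 2, 2), "A")
  expect_equal(eff0$h_eff, hA)
  expect_equal(eff0$e_shift, 0)
  # non-interacting integrals: any gamma leaves h_eff bare
  m0 <- model_hamiltonian(lambda = 0, seed = 6)
  W0 <- fragpt2:::interfragment_W(m0$hamiltonian, m0$partition)
  effg <- build_effective_hamiltonian(hA, W0, diag(1, 2), "A",
                                      gamma_self = diag(1, 2))
  expect_equal(effg$h_eff, hA)
  expect_equal(effg$e_shift, 0)
  expect_error(build_effective_hamiltonian(hA, W, matrix(0, 3, 3), "A"),
               "mismatch")
})

test_that("non-interacting fragments converge immediately to the FCI sum", {
  m <- model_hamiltonian(lambda = 0, seed = 8)
  ps <- self_consistent_product_state(m$hamiltonian, m$partition)
  eA <- fci_solve_sector(m$hamiltonian$h[1:2, 1:2],
                         m$hamiltonian$g[1:2, 1:2, 1:2, 1:2], 0, 2, 1, 1)
  eB <- fci_solve_sector(m$hamiltonian$h[3:4, 3:4],
                         m$hamiltonian$g[3:4, 3:4, 3:4, 3:4], 0, 2, 1, 1)
  expect_equal(ps$e0, eA$energy + eB$energy, tolerance = 1e-12)
  expect_lte(nrow(ps$iteration_log), 2)
  expect_equal(ps$mf_shift, 0)
})

test_that("the product-state energy identity holds densely", {
  sol <- solve_model(13, lambda = 0.2)
  space <- combined_space(sol$partition)
  H0 <- fragpt2:::dense_h0_matrix(sol$dec, space)
  Hd <- dense_full_h(sol$H, space)
  v <- embed_product(fragpt2:::as_state(sol$ps$psi_A),
                     fragpt2:::as_state(sol$ps$psi_B), sol$H$n_orb)
  vv <- as.numeric(v$coef)
  expect_equal(sum(vv^2), 1, tolerance = 1e-12)
  # <Psi0|H0|Psi0> = eps_A + eps_B - shift + e_core = e0
  expect_equal(as.numeric(t(vv) %*% H0 %*% vv), sol$ps$e0, tolerance = 1e-10)
  expect_equal(sol$ps$eps_A + sol$ps$eps_B - sol$ps$mf_shift +
                 sol$H$e_core, sol$ps$e0, tolerance = 1e-10)
  # and equals <Psi0|H|Psi0> (vanishing first order)
  expect_equal(as.numeric(t(vv) %*% Hd %*% vv), sol$ps$e0, tolerance = 1e-10)
})

test_that("converged fragment states are effective-Hamiltonian eigenstates", {
  sol <- solve_model(21, lambda = 0.3, n_orb = c(A = 3L, B = 3L),
                     n_elec = c(A = 2L, B = 4L))
  for (side in c("A", "B")) {
    psi <- if (side == "A") sol$ps$psi_A else sol$ps$psi_B
    h_eff <- if (side == "A") sol$ps$h_eff_A else sol$ps$h_eff_B
    g_loc <- if (side == "A") sol$dec$gA else sol$dec$gB
    Hd <- fragpt2:::build_sector_hamiltonian(h_eff, g_loc, psi$space)
    v <- as.numeric(psi$coef)
    eps <- if (side == "A") sol$ps$eps_A else sol$ps$eps_B
    expect_lt(sqrt(sum((Hd %*% v - eps * v)^2)), 1e-7)
  }
})

test_that("variational sandwich: exact <= product state <= determinant", {
  for (seed in c(1, 2, 3, 7)) {
    sol <- solve_model(seed, lambda = 0.3)
    ex <- full_casci(sol$H, sum(sol$partition$n_elec),
                     sum(sol$partition$ms2))
    eref <- reference_determinant_energy(sol$H, sol$partition)
    expect_lte(ex$e_exact, sol$ps$e0 + 1e-10)
    expect_lte(sol$ps$e0, eref + 1e-10)
  }
})

test_that("weak coupling: embedding error is second order in lambda", {
  lam <- 0.05
  sol <- solve_model(17, lambda = lam)
  ex <- full_casci(sol$H, 4, 0)
  expect_gte(sol$ps$e0 - ex$e_exact, -1e-12)
  expect_lte(sol$ps$e0 - ex$e_exact, 2 * lam^2)
})

test_that("embedding energy is invariant under intra-fragment rotations", {
  sol <- solve_model(19, lambda = 0.25)
  th <- 0.37
  U <- diag(4)
  U[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  h2 <- t(U) %*% sol$H$h %*% U
  g2 <- fragpt2:::ao2mo(sol$H$g, U)
  H2 <- active_hamiltonian((h2 + t(h2)) / 2, fragpt2:::symmetrize8(g2),
                           sol$H$e_core)
  ps2 <- self_consistent_product_state(H2, sol$partition, tol_e = 1e-11,
                                       tol_rdm = 1e-9)
  expect_equal(ps2$e0, sol$ps$e0, tolerance = 1e-9)
})

test_that("fragment relabeling leaves the embedding energy unchanged", {
  sol <- solve_model(23, lambda = 0.3, n_orb = c(A = 3L, B = 2L),
                     n_elec = c(A = 4L, B = 2L))
  sw <- swap_fragments(sol$H, sol$partition)
  ps2 <- self_consistent_product_state(sw$hamiltonian, sw$partition,
                                       tol_e = 1e-11, tol_rdm = 1e-9)
  expect_equal(ps2$e0, sol$ps$e0, tolerance = 1e-10)
})

test_that("non-convergence raises a condition carrying the iteration log", {
  m <- model_hamiltonian(lambda = 0.3, seed = 31)
  err <- tryCatch(
    self_consistent_product_state(m$hamiltonian, m$partition,
                                  tol_e = 0, tol_rdm = 0, max_iter = 3L),
    error = function(e) e)
  expect_s3_class(err, "convergence_error")
  expect_true(is.data.frame(err$log))
  expect_equal(nrow(err$log), 3L)
})
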