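# Partially contracted second-order perturbation theory: basis construction,
# factorized matrix assembly, amplitude equations, channel energies.

test_that("implicit basis members equal densely constructed ones (signs!)", {
  sol <- solve_model(3, lambda = 0.3)
  space <- combined_space(sol$partition)
  psi <- embed_product(fragpt2:::as_state(sol$ps$psi_A),
                       fragpt2:::as_state(sol$ps$psi_B), sol$H$n_orb)
  v0 <- as.numeric(psi$coef)
  N_A <- sol$partition$n_elec[["A"]]
  nA <- length(sol$partition$idx_A)
  for (ch in names(sol$dec$channels)) {
    terms <- sol$dec$channels[[ch]]$terms
    if (length(terms) == 0) next
    set.seed(7)
    pick <- sample(length(terms), min(6, length(terms)))
    for (k in pick) {
      tm <- terms[[k]]
      # dense: phase * O_A O_B |Psi0> in the combined space (g stripped)
      tm1 <- tm; tm1$g <- 1
      dense_vec <- as.numeric(dense_operator_matrix(list(tm1), space) %*% v0)
      # factorized: (O_A psi_A) (x) (O_B psi_B) with the crossing sign
      uA <- fragpt2:::apply_sfop(fragpt2:::as_state(sol$ps$psi_A), tm$opA, 0L)
      uB <- fragpt2:::apply_sfop(fragpt2:::as_state(sol$ps$psi_B), tm$opB, nA)
      if (is.null(uA) || is.null(uB)) {
        expect_lt(max(abs(dense_vec)), 1e-12)
        next
      }
      emb <- embed_product(uA, uB, sol$H$n_orb)
      cross <- if (N_A %% 2 == 1 &&
                   fragpt2:::sfop_nops(tm$opB) %% 2 == 1) -1 else 1
      fact_vec <- tm$phase * cross * as.numeric(emb$coef)
      expect_lt(max(abs(dense_vec - fact_vec)), 1e-10)
    }
  }
})

test_that("dispersion members are orthogonal to the reference", {
  sol <- solve_model(5, lambda = 0.2)
  basis <- build_perturbing_basis(sol$dec, sol$ps, "dispersion")
  gr <- basis$groups[[1]]
  oA <- crossprod(gr$UA, as.numeric(sol$ps$psi_A$coef))
  oB <- crossprod(gr$UB, as.numeric(sol$ps$psi_B$coef))
  ov <- abs(oA[gr$a_idx] * oB[gr$b_idx])
  expect_lt(max(ov), 1e-12)
})

test_that("overlap metric is PSD; amplitude solver handles edge cases", {
  sol <- solve_model(5, lambda = 0.2)
  basis <- build_perturbing_basis(sol$dec, sol$ps, "ct1_BtoA")
  mats <- assemble_matrices(basis, sol$dec, sol$ps)
  for (m in mats) {
    ev <- eigen((m$S + t(m$S)) / 2, symmetric = TRUE, only.values = TRUE)
    expect_gt(min(ev$values), -1e-10)
  }
  # V = 0 gives zero amplitudes and energy
  m1 <- mats[[1]]
  sol0 <- solve_amplitudes(m1$S, m1$M, rep(0, nrow(m1$S)), sol$ps$e0)
  expect_equal(sol0$e2, 0)
  expect_equal(max(abs(sol0$C)), 0)
  # duplicated member (singular S): energy unchanged
  n <- nrow(m1$S)
  S2 <- rbind(cbind(m1$S, m1$S[, n]), c(m1$S[n, ], m1$S[n, n]))
  M2 <- rbind(cbind(m1$M, m1$M[, n]), c(m1$M[n, ], m1$M[n, n]))
  V2 <- c(m1$V, m1$V[n])
  a1 <- solve_amplitudes(m1$S, m1$M, m1$V, sol$ps$e0)
  a2 <- solve_amplitudes(S2, M2, V2, sol$ps$e0)
  expect_equal(a2$e2, a1$e2, tolerance = 1e-10)
  expect_equal(a2$n_dropped, a1$n_dropped + 1L)
  # single-member basis: closed form -V^2 / (M - e0 S) scaled by the metric
  s <- m1$S[1, 1]; mm <- m1$M[1, 1]; v <- m1$V[1]
  a3 <- solve_amplitudes(matrix(s), matrix(mm), v, sol$ps$e0)
  expect_equal(a3$e2, -v^2 / (mm - sol$ps$e0 * s), tolerance = 1e-12)
})

test_that("assembled S and M match dense matrix elements", {
  sol <- solve_model(2, lambda = 0.25)
  space <- combined_space(sol$partition)
  H0d <- fragpt2:::dense_h0_matrix(sol$dec, space)
  psi <- embed_product(fragpt2:::as_state(sol$ps$psi_A),
                       fragpt2:::as_state(sol$ps$psi_B), sol$H$n_orb)
  v0 <- as.numeric(psi$coef)
  for (ch in c("dispersion", "ct1_AtoB", "ct2", "tt")) {
    basis <- build_perturbing_basis(sol$dec, sol$ps, ch)
    mats <- assemble_matrices(basis, sol$dec, sol$ps)
    for (gi in seq_along(basis$groups)) {
      gr <- basis$groups[[gi]]
      terms <- sol$dec$channels[[ch]]$terms
      shA <- vapply(terms, function(t)
        paste(fragpt2:::sfop_shift(t$opA), collapse = ","), "")
      shB <- vapply(terms, function(t)
        paste(fragpt2:::sfop_shift(t$opB), collapse = ","), "")
      sel <- which(paste(shA, shB, sep = "|") == gr$key)
      # dense member vectors, Psi0-projected when in the reference sector
      Phi <- vapply(sel, function(k) {
        tm <- terms[[k]]; tm$g <- 1
        as.numeric(dense_operator_matrix(list(tm), space) %*% v0)
      }, numeric(space$dim))
      if (gr$is_reference)
        Phi <- Phi - v0 %*% (t(v0) %*% Phi)
      Sd <- crossprod(Phi)
      Md <- crossprod(Phi, H0d %*% Phi)
      expect_lt(max(abs(Sd - mats[[gi]]$S)), 1e-9)
      expect_lt(max(abs(Md - mats[[gi]]$M)), 1e-9)
    }
  }
})

test_that("channel energies match the dense Hylleraas minimum", {
  for (seed in c(2, 9)) {
    sol <- solve_model(seed, lambda = 0.25)
    pt <- pt2_correction(sol$dec, sol$ps)
    for (ch in names(pt$e2)) {
      expect_equal(pt$e2[[ch]], dense_hylleraas(sol, ch), tolerance = 1e-9)
    }
  }
})

test_that("first-order energies vanish (factorized and dense)", {
  sol <- solve_model(4, lambda = 0.3)
  fo <- first_order_check(sol$dec, sol$ps)
  expect_lt(max(abs(fo)), 1e-10)
  space <- combined_space(sol$partition)
  psi <- embed_product(fragpt2:::as_state(sol$ps$psi_A),
                       fragpt2:::as_state(sol$ps$psi_B), sol$H$n_orb)
  v0 <- as.numeric(psi$coef)
  for (ch in names(sol$dec$channels)) {
    Hp <- dense_operator_matrix(sol$dec$channels[[ch]], space)
    expect_lt(abs(as.numeric(t(v0) %*% Hp %*% v0)), 1e-12)
  }
})

test_that("non-interacting model gives empty bases and zero correction", {
  sol <- solve_model(1, lambda = 0)
  for (ch in names(sol$dec$channels)) {
    basis <- build_perturbing_basis(sol$dec, sol$ps, ch)
    expect_length(basis$groups, 0)
  }
  pt <- pt2_correction(sol$dec, sol$ps)
  expect_equal(unname(pt$e2), rep(0, 5))
  expect_equal(pt$e_total, sol$ps$e0)
})

test_that("contracted energies are bounded by the uncontracted oracle", {
  for (seed in c(1, 6, 14)) {
    sol <- solve_model(seed, lambda = 0.25, n_orb = c(A = 3L, B = 3L),
                       n_elec = c(A = 4L, B = 2L))
    pt <- pt2_correction(sol$dec, sol$ps)
    unc <- uncontracted_pt2(sol$dec, sol$ps)
    for (ch in names(pt$e2)) {
      expect_lte(pt$e2[[ch]], 1e-12)
      expect_gte(pt$e2[[ch]], unc[[ch]] - 1e-10)
    }
    expect_equal(pt$e2_total, sum(pt$e2))
  }
})

test_that("uncontracted residual scales as the third power of the coupling", {
  lams <- 10^seq(-3, -1, length.out = 5)
  res <- vapply(lams, function(l) {
    sol <- solve_model(11, lambda = l, tol_e = 1e-13, tol_rdm = 1e-11)
    unc <- uncontracted_pt2(sol$dec, sol$ps, channel = "all")
    ex <- full_casci(sol$H, 4, 0)
    abs(ex$e_exact - sol$ps$e0 - unc[["all"]])
  }, 0)
  slope <- coef(stats::lm(log(res) ~ log(lams)))[2]
  expect_gte(slope, 2.5)
})

test_that("relabeling fragments swaps the charge-transfer directions only", {
  sol <- solve_model(23, lambda = 0.3, n_orb = c(A = 3L, B = 2L),
                     n_elec = c(A = 4L, B = 2L))
  pt <- pt2_correction(sol$dec, sol$ps)
  sw <- swap_fragments(sol$H, sol$partition)
  ps2 <- self_consistent_product_state(sw$hamiltonian, sw$partition,
                                       tol_e = 1e-11, tol_rdm = 1e-9)
  dec2 <- decompose_hamiltonian(sw$hamiltonian, sw$partition,
                                rdms = list(A = ps2$gamma_A, B = ps2$gamma_B))
  pt2b <- pt2_correction(dec2, ps2)
  expect_equal(pt2b$e2[["dispersion"]], pt$e2[["dispersion"]],
               tolerance = 1e-10)
  expect_equal(pt2b$e2[["tt"]], pt$e2[["tt"]], tolerance = 1e-10)
  expect_equal(pt2b$e2[["ct2"]], pt$e2[["ct2"]], tolerance = 1e-10)
  expect_equal(pt2b$e2[["ct1_AtoB"]], pt$e2[["ct1_BtoA"]], tolerance = 1e-10)
  expect_equal(pt2b$e2[["ct1_BtoA"]], pt$e2[["ct1_AtoB"]], tolerance = 1e-10)
})
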