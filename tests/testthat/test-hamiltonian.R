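# Active-space Hamiltonian container, FCIDUMP/partition files, term
# classification and the exact channel decomposition.

test_that("FCIDUMP files round-trip and validate", {
  # one-orbital direct echo
  p1 <- tempfile(fileext = ".fcidump")
  H1 <- active_hamiltonian(matrix(-1.0, 1, 1), array(0.5, c(1, 1, 1, 1)), 0.2)
  write_fcidump(H1, p1, n_elec = 2)
  rd <- read_fcidump(p1)
  expect_equal(rd$hamiltonian$h[1, 1], -1.0)
  expect_equal(rd$hamiltonian$g[1, 1, 1, 1], 0.5)
  expect_equal(rd$hamiltonian$e_core, 0.2)
  expect_equal(rd$n_elec, 2L)

  # random symmetric Hamiltonian round-trips to 1e-12
  m <- model_hamiltonian(n_orb = c(A = 3L, B = 2L),
                         n_elec = c(A = 4L, B = 2L), lambda = 0.4, seed = 9)
  p2 <- tempfile(fileext = ".fcidump")
  write_fcidump(m$hamiltonian, p2, n_elec = 6, ms2 = 0)
  rd2 <- read_fcidump(p2)
  expect_lt(max(abs(rd2$hamiltonian$h - m$hamiltonian$h)), 1e-12)
  expect_lt(max(abs(rd2$hamiltonian$g - m$hamiltonian$g)), 1e-12)

  # malformed header and bad indices fail loudly
  bad <- tempfile(); writeLines(c("no header here", "1.0 1 1 0 0"), bad)
  expect_error(read_fcidump(bad), "malformed|terminator")
  bad2 <- tempfile()
  writeLines(c(" &FCI NORB=2,NELEC=2,MS2=0,", " &END",
               " 1.0    5    1    0    0"), bad2)
  expect_error(read_fcidump(bad2), "range")
})

test_that("validator rejects broken integral symmetry", {
  h <- matrix(c(0, 0.1, 0.2, 0), 2, 2)          # asymmetric
  g <- array(0, rep(2, 4))
  expect_error(active_hamiltonian(h, g), "symmetric")
  h2 <- diag(2)
  g2 <- array(0, rep(2, 4)); g2[1, 2, 1, 1] <- 0.3  # breaks (pq|rs)=(qp|rs)
  expect_error(active_hamiltonian(h2, g2), "symmetry")
})

test_that("partition files round-trip and invariants are enforced", {
  part <- fragment_partition(c("A", "A", "B", "B"), c(A = 2L, B = 2L))
  p <- tempfile()
  write_partition(part, p)
  rd <- read_partition(p)
  expect_equal(rd$fragment_of, part$fragment_of)
  expect_equal(rd$n_elec, part$n_elec)
  expect_error(fragment_partition(c("A", "B", "A"), c(A = 2L, B = 1L)),
               "precede")
  expect_error(fragment_partition(c("A", "B"), c(A = 5L, B = 1L)), "range")
  expect_error(fragment_partition(c("A", "B"), c(A = 1L, B = 1L),
                                  ms2 = c(A = 2L, B = 0L)), "Sz")
  expect_error(fragment_partition(c("A", "A"), c(A = 2L, B = 0L)),
               "non-empty")
})

test_that("terms classify by fragment pattern and brute-force dN_A agrees", {
  part <- fragment_partition(c("A", "A", "B", "B"), c(A = 2L, B = 2L))
  expect_equal(classify_term(1, 2, 1, 2, partition = part), "intra_A")
  expect_equal(classify_term(1, 1, 3, 3, partition = part), "coulomb_like_AB")
  expect_equal(classify_term(1, 3, 4, 4, partition = part), "ct1")
  expect_equal(classify_term(1, 3, 2, 4, partition = part), "ct2")
  expect_equal(classify_term(1, 3, 4, 2, partition = part),
               "spin_carrying_AB")
  expect_equal(classify_term(3, 4, partition = part), "intra_B")
  expect_equal(classify_term(2, 3, partition = part), "ct1")

  # brute force: apply e_pqrs as a dense matrix to a product-sector state
  # and measure the change in fragment A's electron number
  space <- fragpt2:::sector_space(4, 2, 2)
  NA_op <- Reduce(`+`, lapply(1:2, function(p)
    as.matrix(fragpt2:::Epq_matrix(space, p, p))))
  set.seed(1)
  for (rep in 1:20) {
    idx <- sample(4, 4, replace = TRUE)
    p <- idx[1]; q <- idx[2]; r <- idx[3]; s <- idx[4]
    ops_a <- rbind(c(p, 1L, 1L), c(r, 2L, 1L), c(s, 2L, 0L), c(q, 1L, 0L))
    M <- fragpt2:::opstring_matrix(space, ops_a)
    if (is.null(M) || max(abs(M)) == 0) next
    M <- as.matrix(M)
    dn <- NA_op %*% M - M %*% NA_op
    # measure dN_A on the image: <x| N_A |x> - <y| N_A |y> for x = M y
    y <- rnorm(space$dim); y <- y / sqrt(sum(y^2))
    # pick y in an N_A eigenspace: project onto N_A = 2
    ev <- eigen(NA_op, symmetric = TRUE)
    sel <- abs(ev$values - 2) < 1e-8
    y <- ev$vectors[, sel] %*% crossprod(ev$vectors[, sel], y)
    x <- M %*% y
    if (sqrt(sum(x^2)) < 1e-10) next
    meas <- as.numeric(t(x) %*% NA_op %*% x) / sum(x^2) - 2
    lab <- classify_term(p, q, r, s, partition = part)
    expected <- switch(lab, intra_A = 0, intra_B = 0, coulomb_like_AB = 0,
                       spin_carrying_AB = 0, ct1 = 1, ct2 = 2)
    expect_equal(abs(round(meas)), expected)
    expect_lt(abs(meas - round(meas)), 1e-8)
  }
})

test_that("non-interacting Hamiltonians decompose with empty channels", {
  m <- model_hamiltonian(lambda = 0, seed = 2)
  ps <- self_consistent_product_state(m$hamiltonian, m$partition)
  dec <- decompose_hamiltonian(m$hamiltonian, m$partition,
                               rdms = list(A = ps$gamma_A, B = ps$gamma_B))
  for (ch in dec$channels) expect_length(ch$terms, 0)
  expect_equal(dec$shift, 0)
  expect_equal(max(abs(dec$fA)), 0)
  expect_equal(max(abs(dec$fB)), 0)
})

test_that("decomposition reconstructs the Hamiltonian densely", {
  for (cfg in list(list(seed = 1, n_orb = c(A = 2L, B = 2L),
                        n_elec = c(A = 2L, B = 2L)),
                   list(seed = 5, n_orb = c(A = 3L, B = 3L),
                        n_elec = c(A = 2L, B = 4L)))) {
    sol <- solve_model(cfg$seed, lambda = 0.25, n_orb = cfg$n_orb,
                       n_elec = cfg$n_elec)
    space <- combined_space(sol$partition)
    Hd <- dense_full_h(sol$H, space)
    H0 <- fragpt2:::dense_h0_matrix(sol$dec, space)
    Hch <- Reduce(`+`, lapply(sol$dec$channels, dense_operator_matrix,
                              space = space))
    expect_lt(max(abs(Hd - (H0 + Hch))), 1e-10)
  }
})

test_that("decomposition validates the supplied 1-RDMs", {
  m <- model_hamiltonian(seed = 1)
  bad <- matrix(c(1, 0.5, -0.5, 1), 2, 2)
  expect_error(decompose_hamiltonian(m$hamiltonian, m$partition,
                                     rdms = list(A = bad, B = diag(2))),
               "hermitian")
  expect_error(decompose_hamiltonian(m$hamiltonian, m$partition,
                                     rdms = list(A = diag(2),
                                                 B = diag(0.3, 2))),
               "trace")
})

test_that("channels are disjoint and shift sectors as advertised", {
  sol <- solve_model(3, lambda = 0.3)
  # disjointness: no elementary Hamiltonian term appears in two channels
  keys <- lapply(sol$dec$channels, function(ch)
    vapply(ch$terms, function(tm)
      paste(fragpt2:::sfop_key(tm$opA), fragpt2:::sfop_key(tm$opB)), ""))
  for (i in seq_along(keys)) for (j in seq_along(keys)) {
    if (i < j) expect_length(intersect(keys[[i]], keys[[j]]), 0)
  }
  # symmetry action: each channel's dense matrix maps a sharp (N_A, Sz_A)
  # state into the advertised sector offsets
  space <- combined_space(sol$partition)
  NAop <- Reduce(`+`, lapply(sol$partition$idx_A, function(p)
    as.matrix(fragpt2:::Epq_matrix(space, p, p))))
  ev <- eigen(NAop, symmetric = TRUE)
  sel <- abs(ev$values - 2) < 1e-8
  P2 <- ev$vectors[, sel]
  set.seed(4)
  y <- P2 %*% crossprod(P2, rnorm(space$dim))
  y <- y / sqrt(sum(y^2))
  dn_expect <- c(dispersion = 0, ct1_AtoB = -1, ct1_BtoA = 1, tt = 0)
  for (ch in names(dn_expect)) {
    M <- dense_operator_matrix(sol$dec$channels[[ch]], space)
    x <- M %*% y
    if (sqrt(sum(x^2)) < 1e-10) next
    meas <- as.numeric(t(x) %*% NAop %*% x) / sum(x^2) - 2
    if (ch == "ct2") next
    expect_lt(abs(meas - dn_expect[[ch]]), 1e-8)
  }
  # ct2 mixes +2 and -2: check the image has no dN_A = 0, +-1 component
  M <- dense_operator_matrix(sol$dec$channels$ct2, space)
  x <- M %*% y
  for (dv in c(-1, 0, 1)) {
    seld <- abs(ev$values - (2 + dv)) < 1e-8
    if (!any(seld)) next
    expect_lt(max(abs(crossprod(ev$vectors[, seld, drop = FALSE], x))), 1e-9)
  }
})

test_that("fragment swap relabels without changing physics", {
  m <- model_hamiltonian(n_orb = c(A = 2L, B = 3L),
                         n_elec = c(A = 2L, B = 4L), lambda = 0.2, seed = 12)
  sw <- swap_fragments(m$hamiltonian, m$partition)
  expect_equal(length(sw$partition$idx_A), 3L)
  expect_equal(sw$partition$n_elec[["A"]], 4L)
  ex1 <- full_casci(m$hamiltonian, 6, 0)$e_exact
  ex2 <- full_casci(sw$hamiltonian, 6, 0)$e_exact
  expect_equal(ex1, ex2, tolerance = 1e-10)
})
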