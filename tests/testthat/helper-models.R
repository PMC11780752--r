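# Shared fixtures: seeded models, embedding/PT2 pipelines, dense oracles.
# Everything is generated in code; heavier shared computations are cached
# for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  v <- .fixture_cache[[key]]
  if (is.null(v)) {
    v <- force(expr)
    assign(key, v, envir = .fixture_cache)
  }
  v
}

# full embedding + decomposition + pt2 for a seeded model
solve_model <- function(seed, lambda = 0.2, n_orb = c(A = 2L, B = 2L),
                        n_elec = c(A = 2L, B = 2L), tol_e = 1e-11,
                        tol_rdm = 1e-9, ...) {
  m <- model_hamiltonian(n_orb = n_orb, n_elec = n_elec, lambda = lambda,
                         seed = seed, ...)
  ps <- self_consistent_product_state(m$hamiltonian, m$partition,
                                      tol_e = tol_e, tol_rdm = tol_rdm)
  dec <- decompose_hamiltonian(m$hamiltonian, m$partition,
                               rdms = list(A = ps$gamma_A, B = ps$gamma_B))
  list(H = m$hamiltonian, partition = m$partition, ps = ps, dec = dec)
}

combined_space <- function(partition) {
  na <- sum(vapply(c("A", "B"),
                   function(f) fragpt2:::fragment_sector(partition, f)[["na"]],
                   integer(1)))
  nb <- sum(vapply(c("A", "B"),
                   function(f) fragpt2:::fragment_sector(partition, f)[["nb"]],
                   integer(1)))
  fragpt2:::sector_space(partition$n_orb, na, nb)
}

dense_full_h <- function(H, space) {
  fragpt2:::build_sector_hamiltonian(H$h, H$g, space) +
    diag(H$e_core, space$dim)
}

# dense Hylleraas minimum of one channel over the span of its partially
# contracted members (independent of the factorized assembly path)
dense_hylleraas <- function(sol, channel) {
  space <- combined_space(sol$partition)
  H0 <- fragpt2:::dense_h0_matrix(sol$dec, space)
  psi <- embed_product(fragpt2:::as_state(sol$ps$psi_A),
                       fragpt2:::as_state(sol$ps$psi_B), sol$H$n_orb)
  v0 <- as.numeric(psi$coef)
  e0 <- as.numeric(t(v0) %*% H0 %*% v0)
  terms <- sol$dec$channels[[channel]]$terms
  if (length(terms) == 0) return(0)
  # member vectors Phi_k = g-stripped operators applied to Psi0
  cols <- lapply(terms, function(tm) {
    tm1 <- tm; tm1$g <- 1
    M <- dense_operator_matrix(list(tm1), space)
    as.numeric(M %*% v0)
  })
  Phi <- do.call(cbind, cols)
  # project out Psi0
  Phi <- Phi - v0 %*% (t(v0) %*% Phi)
  g <- vapply(terms, `[[`, 0, "g")
  Hp <- dense_operator_matrix(terms, space)
  r <- as.numeric(Hp %*% v0)
  r <- r - sum(r * v0) * v0
  S <- crossprod(Phi)
  W <- crossprod(Phi, (H0 - e0 * diag(space$dim)) %*% Phi)
  V <- as.numeric(crossprod(Phi, r))
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  keep <- es$values > 1e-10 * max(es$values)
  if (!any(keep)) return(0)
  X <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))
  y <- solve(crossprod(X, W %*% X), -as.numeric(crossprod(X, V)))
  sum((X %*% y) * V)
}

# N2 dimer pipeline points (cc-pVDZ, CAS(6,6) per fragment), cached; the
# heavy shared fixture behind the acceptance checks
n2_point <- function(bond_right) {
  key <- sprintf("n2_%0.2f", bond_right)
  cached(key, {
    geom <- n2_dimer_geometry(separation = 2.0, bond_left = 1.2,
                              bond_right = bond_right)
    run_pipeline(list(geometry = geom, basis = "cc-pvdz",
                      active = list(A = c(3, 3), B = c(3, 3)),
                      bias_first_fragment = FALSE, oracle = TRUE))
  })
}

n2_scan_points <- c(1.2, 1.6, 2.0)

expect_close <- function(a, b, tol) expect_lt(max(abs(a - b)), tol)
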