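test_that("assembled CEM matrix is symmetric with the constant vector in its nullspace", {
  sys <- coarse_system()
  K <- sys$K
  expect_lt(max(abs(K - Matrix::t(K))), 1e-15 * max(abs(K@x)))
  one <- rep(1, nrow(K))
  expect_lt(max(abs(as.numeric(K %*% one))), 1e-12 * max(abs(K@x)))
  # volume-block rows over interior (non-boundary) nodes sum to zero
  m <- coarse_head()
  interior <- setdiff(seq_len(nrow(m$nodes)), unique(as.vector(m$boundary_facets)))
  rs <- as.numeric(K %*% one)[interior]
  expect_lt(max(abs(rs)), 1e-12 * max(abs(K@x)))
})

test_that("single-tet volume stiffness matches an independently assembled element matrix", {
  m <- single_tet_mesh(a = 0.01)
  sys <- assemble_cem_system(m, c(brain = 2.5), montage = NULL)
  # oracle: shape-function gradients from the Vandermonde system
  X <- cbind(1, m$nodes)
  G <- solve(X, diag(4))[2:4, ]      # column j = grad phi_j
  V <- abs(det(cbind(m$nodes[2, ] - m$nodes[1, ], m$nodes[3, ] - m$nodes[1, ],
                     m$nodes[4, ] - m$nodes[1, ]))) / 6
  Ko <- 2.5 * V * t(G) %*% G
  expect_equal(as.matrix(sys$K), Ko, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("solver honours compatibility, linearity and the tolerance contract", {
  sys <- coarse_system()
  expect_error(solve_system(sys, injection_rhs(sys, c(1e-3, rep(0, 63)))),
               "incompatible")

  z <- solve_system(sys, numeric(sys$n_nodes + sys$n_electrodes))
  expect_identical(z$potentials, numeric(sys$n_nodes))

  cur <- numeric(64); cur[5] <- 1e-3; cur[44] <- -1e-3
  s1 <- solve_system(sys, injection_rhs(sys, cur), tol = 1e-11)
  s2 <- solve_system(sys, injection_rhs(sys, 2 * cur), tol = 1e-11)
  expect_lte(s1$relres, 1e-11)
  expect_equal(s2$potentials, 2 * s1$potentials,
               tolerance = 1e-9)
})

test_that("element fields recover linear potentials and scale with conductivity", {
  sys <- coarse_system()
  sol <- list(potentials = coarse_head()$nodes[, 1],
              electrode_potentials = numeric(64), relres = 0, iterations = 0L)
  f <- element_fields(sys, sol)
  expect_equal(f$E[, 1], rep(-1, nrow(f$E)), tolerance = 1e-8)
  expect_lt(max(abs(f$E[, 2:3])), 1e-8)

  sys2 <- assemble_cem_system(coarse_head(), default_conductivities() * 2,
                              coarse_montage())
  f2 <- element_fields(sys2, sol)
  expect_equal(f2$J, 2 * f$J, tolerance = 1e-12)
})

test_that("solved patterns conserve current through every electrode contact", {
  sys <- coarse_system()
  cur <- numeric(64); cur[3] <- 1e-3; cur[50] <- -1e-3
  sol <- solve_system(sys, injection_rhs(sys, cur))
  flux <- electrode_current_flux(sys, sol)
  # injected electrodes reproduce the prescribed currents within 2%
  expect_lt(abs(flux[3] - 1e-3) / 1e-3, 0.02)
  expect_lt(abs(flux[50] + 1e-3) / 1e-3, 0.02)
  # and the whole montage balances
  expect_lt(abs(sum(flux)), 1e-9 * 1e-3)
})

test_that("discrete reciprocity holds to 0.1% for dipoles and electrode pairs", {
  sys <- coarse_system()
  set.seed(11)
  for (k in 1:2) {
    u <- runit()
    pos <- 0.07 * u
    mom <- 1e-8 * runit()
    pair <- sample(64, 2)
    v <- verify_reciprocity(sys, pos, mom, pair)
    expect_false(isTRUE(v$absolute))
    expect_lt(v$mismatch, 1e-3)
  }
})

test_that("isopotential electrode pairs deliver no directional density", {
  sys <- coarse_system()
  topo <- eeg_topography(sys, c(0, 0, 0.07), c(0, 0, 1e-8))
  phi <- topo$potentials
  # two electrodes with the most similar potentials approximate an
  # isopotential pair; compare with the pole pair
  o <- order(phi)
  gaps <- diff(phi[o])
  i <- which.min(gaps)
  iso <- c(o[i], o[i + 1])
  pole <- c(which.max(phi), which.min(phi))
  v_iso <- verify_reciprocity(sys, c(0, 0, 0.07), c(0, 0, 1e-8), iso)
  v_pole <- verify_reciprocity(sys, c(0, 0, 0.07), c(0, 0, 1e-8), pole)
  expect_lt(abs(v_iso$rhs), 0.05 * abs(v_pole$rhs))
})
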