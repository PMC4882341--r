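toy_transfer <- function(M, I_max = 1e-3) {
  structure(list(M = M, I_max = I_max, n_elements = nrow(M) / 3,
                 n_electrodes = ncol(M) + 1, cache = NULL),
            class = "transfer_matrix")
}

toy_target <- function(elements, direction, center = c(0, 0, 0)) {
  structure(list(elements = elements, direction = direction, center = center,
                 element = elements[1]), class = "tes_target")
}

test_that("targets from seeds have unit radial normals and the requested size", {
  m <- coarse_head()
  set.seed(41)
  for (k in 1:3) {
    u <- runit()
    tgt <- target_from_seed(m, 0.08 * u, n_elements = 12)
    expect_length(tgt$elements, 12)
    expect_equal(sqrt(sum(tgt$direction^2)), 1, tolerance = 1e-12)
    radial <- tgt$center / sqrt(sum(tgt$center^2))
    ang <- acos(min(1, sum(tgt$direction * radial))) * 180 / pi
    expect_lt(ang, 5)  # sphere normals are radial
  }
  expect_error(target_from_seed(layered_head(), c(0, 0, 0.002), 12),
               "near the seed")
})

test_that("LS coefficients match a dense pseudoinverse oracle on a printed fixture", {
  # T = 2 elements, L = 3 electrodes: 6 x 2 transfer fixture
  M <- matrix(c(
     0.31, -0.12,
    -0.05,  0.44,
     0.27,  0.09,
    -0.33,  0.21,
     0.15, -0.40,
     0.08,  0.26
  ), nrow = 6, byrow = TRUE)
  tm <- toy_transfer(M)
  d <- c(0, 0, 1)
  tgt <- toy_target(1, d)
  cfg <- targeting_config(I_max = 1e-3, cap = 1e-3, n_sources = 1)
  p <- ls_pattern(tm, tgt, cfg)
  e <- c(d, 0, 0, 0)
  c_oracle <- as.numeric(MASS::ginv(M) %*% e)
  expect_equal(attr(p, "coefficients"), c_oracle, tolerance = 1e-10)
  # budget contract
  expect_equal(sum(abs(p$currents)), 2e-3, tolerance = 1e-12)
  expect_equal(sum(p$currents[p$currents > 0]), 1e-3, tolerance = 1e-12)
  expect_lt(abs(sum(p$currents)), 1e-15)
  # scaling the objective leaves the pattern unchanged
  tgt2 <- toy_target(1, 7.5 * d)
  p2 <- ls_pattern(tm, tgt2, cfg)
  expect_equal(p2$currents, p$currents, tolerance = 1e-12)
})

test_that("LCMV satisfies its constraint and matches a KKT oracle", {
  set.seed(42)
  M <- matrix(rnorm(27 * 5), 27, 5)  # 9 elements, 5 patterns (L = 6)
  tm <- toy_transfer(M)
  d <- c(0.2, -1, 0.5)
  el <- 4
  cfg <- targeting_config(I_max = 1e-3, cap = 1e-3, n_sources = 1)
  p <- lcmv_pattern(tm, el, d, cfg)
  expect_lt(attr(p, "constraint_residual"), 1e-8)
  # KKT oracle for min ||Mc||^2 s.t. Tt c = d
  Tt <- M[3 * (el - 1) + 1:3, ]
  KKT <- rbind(cbind(2 * crossprod(M), t(Tt)), cbind(Tt, matrix(0, 3, 3)))
  sol <- solve(KKT, c(numeric(5), d))
  c_oracle <- sol[1:5]
  expect_equal(sum((M %*% attr(p, "coefficients"))^2),
               sum((M %*% c_oracle)^2), tolerance = 1e-8)
  expect_error(lcmv_pattern(tm, el, c(0, 0, 0), cfg), "degenerate")
})

test_that("one-source pattern sources the topography maximum", {
  cfg <- targeting_config(I_max = 1e-3)
  p <- one_source_pattern(c(3, 1, 0, -1, -3) * 1e-3, cfg)
  expect_equal(p$currents, c(1, -0.25, -0.25, -0.25, -0.25) * 1e-3)
  expect_lt(abs(sum(p$currents)), 1e-12 * 1e-3)
})

test_that("opposite pattern splits the budget over ranked sources and sinks", {
  set.seed(43)
  phi <- rnorm(64)
  cfg <- targeting_config(I_max = 1e-3)
  p <- opposite_pattern(phi, cfg)
  src <- which(p$currents > 0); snk <- which(p$currents < 0)
  expect_length(src, 10); expect_length(snk, 30)
  expect_equal(unique(p$currents[src]), 1e-4)
  expect_equal(unique(p$currents[snk]), -1e-3 / 30)
  expect_equal(max(abs(p$currents)), 1e-4)  # the I_max/10 cap, exactly
  expect_length(intersect(src, snk), 0)
  expect_setequal(src, order(-phi)[1:10])
  # affine re-referencing does not change the selection
  p2 <- opposite_pattern(2 * phi + 0.7, cfg)
  expect_identical(p2$currents, p$currents)
  # small montages: counts scale down, the budget is preserved
  p3 <- opposite_pattern(phi[1:20], cfg)
  expect_equal(sum(p3$currents[p3$currents > 0]), 1e-3, tolerance = 1e-15)
  expect_lte(sum(abs(p3$currents) > 0), 20)
})

test_that("ring sinks encircle the sources; both respect the cap exactly", {
  sys <- coarse_system()
  mon <- coarse_montage()
  tgt <- target_from_seed(coarse_head(), c(0, 0, 0.08), 12)
  topo <- eeg_topography(sys, tgt$center, tgt$direction)
  cfg <- targeting_config(I_max = 2e-3)
  p_ring <- ring_pattern(topo, mon, cfg)
  p_opp <- opposite_pattern(topo, cfg)
  expect_identical(sum(abs(p_ring$currents) > 0), 20L)
  expect_equal(max(abs(p_ring$currents)), 2e-4)  # I_max/10 at I_max = 2 mA
  expect_equal(max(abs(p_opp$currents)), 2e-4)
  src <- which(p_ring$currents > 0)
  expect_length(intersect(src, which(p_ring$currents < 0)), 0)
  src_ctr <- colMeans(mon$centers[src, ])
  sink_ctr_ring <- colMeans(mon$centers[p_ring$currents < 0, ])
  sink_ctr_opp <- colMeans(mon$centers[p_opp$currents < 0, ])
  expect_lt(sum((sink_ctr_ring - src_ctr)^2), sum((sink_ctr_opp - src_ctr)^2))
})

test_that("ROADSS reproduces a hand-traced 6-electrode fixture", {
  centers <- rbind(
    c(0, 0, 1), c(1, 0, 0.5), c(-1.1, 0, 0.5),
    c(0, 1.05, 0.5), c(0, -1.02, 0.5), c(0, 0, -1)
  )
  mon <- structure(list(labels = paste0("E", 1:6), centers = centers,
                        contact_facets = as.list(1:6), contact_area = rep(1, 6),
                        z_l = rep(2, 6), contact_radius = 0.1),
                   class = "electrode_montage")
  topo <- c(5, 3, 1, 0, -2, -4) * 1e-3
  cfg <- targeting_config(I_max = 1e-3)  # scales to 1 source at L = 6
  # radial target: r = (0,0,0.8), d = +z. Steps: source = E1 at (0,0,1);
  # r_m = (0,0,1); d_rm = 0.2; r_s = (0,0,0.6); nearest non-source = E2.
  tgt_rad <- toy_target(1, c(0, 0, 1), center = c(0, 0, 0.8))
  p <- roadss_pattern(topo, mon, tgt_rad, cfg)
  expect_equal(p$currents, c(1e-3, -1e-3, 0, 0, 0, 0))
  # tangential target: d = +x -> r_s = (-0.2, 0, 0.8); nearest = E3.
  tgt_tan <- toy_target(1, c(1, 0, 0), center = c(0, 0, 0.8))
  p <- roadss_pattern(topo, mon, tgt_tan, cfg)
  expect_equal(p$currents, c(1e-3, 0, -1e-3, 0, 0, 0))
})

test_that("brute-force pair search is exhaustive and antisymmetric in d", {
  set.seed(44)
  M <- matrix(rnorm(9 * 2), 9, 2)  # 3 elements, L = 3: three pairs
  tm <- toy_transfer(M)
  d <- runit()
  bf <- brute_force_best_pair(tm, 2, d)
  # oracle: enumerate the three pairs with an independent decomposition
  P <- restim:::elementary_basis(3, 1e-3)
  best <- NULL; bestv <- -Inf
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    q <- numeric(3); q[pr[1]] <- 1e-3; q[pr[2]] <- -1e-3
    cf <- qr.solve(P, q)
    v <- -sum(d * (M[4:6, ] %*% cf)) / 1e-3
    if (v > bestv) { bestv <- v; best <- pr }
    if (-v > bestv) { bestv <- -v; best <- rev(pr) }
  }
  expect_identical(c(bf$A, bf$B), as.integer(best))
  bf_rev <- brute_force_best_pair(tm, 2, -d)
  expect_identical(c(bf_rev$A, bf_rev$B), c(bf$B, bf$A))
})

test_that("one-source beats random single-source patterns on the reciprocity objective", {
  sys <- coarse_system()
  tm <- coarse_transfer()
  m <- coarse_head()
  tgt <- target_from_seed(m, c(0.05, 0.02, 0.06), 12)
  topo <- eeg_topography(sys, tgt$center, tgt$direction)
  bf <- brute_force_best_pair(tm, tgt$element, tgt$direction)
  w <- bf$score
  p_one <- one_source_pattern(topo)
  v_one <- sum(w * p_one$currents)
  set.seed(45)
  for (k in 1:50) {
    # same budget, same distributed-sink rule, random source electrode
    s <- sample(64, 1)
    q <- rep(-1e-3 / 63, 64); q[s] <- 1e-3
    expect_gte(v_one, sum(w * q))
  }
})
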