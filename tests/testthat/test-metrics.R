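# mesh of small disjoint regular tets centred at given points (equal volumes
# unless edge varies); handy for hand-computable metric fixtures
point_cloud_mesh <- function(points, edges = 0.002) {
  if (length(edges) == 1) edges <- rep(edges, nrow(points))
  nodes <- do.call(rbind, lapply(seq_len(nrow(points)), function(i) {
    sweep(regular_tet_nodes(edges[i]), 2, points[i, ], "+")
  }))
  tets <- matrix(seq_len(4 * nrow(points)), ncol = 4, byrow = TRUE)
  restim:::build_tet_mesh(nodes, tets, tissue = rep(1L, nrow(points)),
                          tissue_labels = "brain")
}

test_that("target intensity is the volume-weighted ROI mean with its projections", {
  # two elements with different volumes (edge ratio 2 -> volume ratio 8)
  m <- point_cloud_mesh(rbind(c(0, 0, 0), c(0.01, 0, 0)), edges = c(0.002, 0.004))
  J <- rbind(c(1, 0, 0), c(0, 2, 0))
  tgt <- structure(list(elements = 1:2, direction = c(1, 0, 0),
                        center = c(0.005, 0, 0), element = 1),
                   class = "tes_target")
  v <- m$element_volumes
  Jbar <- (J[1, ] * v[1] + J[2, ] * v[2]) / sum(v)
  ti <- target_intensity(J, m, tgt)
  expect_equal(ti$intensity, sqrt(sum(Jbar^2)))
  expect_equal(ti$directional, Jbar[1])
  expect_equal(ti$directionality, Jbar[1] / sqrt(sum(Jbar^2)))
  expect_lte(abs(ti$directional), ti$intensity)
  # J aligned with d everywhere -> directionality 1; orthogonal -> 0
  Jal <- rbind(c(2, 0, 0), c(3, 0, 0))
  expect_equal(target_intensity(Jal, m, tgt)$directionality, 1)
  Jper <- rbind(c(0, 1, 0), c(0, 0, 2))
  expect_equal(target_intensity(Jper, m, tgt)$directional, 0)
})

test_that("global CoG targeting error matches hand computation and symmetry", {
  pts <- rbind(c(0, 0, 0.01), c(0, 0, -0.01), c(0.02, 0, 0))
  m <- point_cloud_mesh(pts)
  tgt <- structure(list(elements = 3L, direction = c(1, 0, 0),
                        center = c(0, 0, 0), element = 3L), class = "tes_target")
  # symmetric equal weights about the target, third element subthreshold
  J <- rbind(c(0, 0, 1), c(1, 0, 0), c(0.5, 0, 0))
  g <- global_cog_te(J, m, tgt)
  expect_equal(g$te, 0, tolerance = 1e-12)
  # hand-computed weighted average with all three suprathreshold
  J2 <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 0.9, 0))
  v <- m$element_volumes
  w <- sqrt(rowSums(J2^2)) * v
  cog <- colSums(pts * w) / sum(w)
  g2 <- global_cog_te(J2, m, tgt, threshold = 0.75)
  expect_equal(g2$cog, cog, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(g2$te, sqrt(sum(cog^2)), tolerance = 1e-9)
})

test_that("local CoG ignores hot-spots outside the neighbourhood", {
  pts <- rbind(c(0, 0, 0), c(0.05, 0, 0))   # second point 5 cm away
  m <- point_cloud_mesh(pts)
  tgt <- structure(list(elements = 1L, direction = c(1, 0, 0),
                        center = c(0, 0, 0), element = 1L), class = "tes_target")
  J <- rbind(c(0.5, 0, 0), c(5, 0, 0))      # strong distant spot
  lte <- local_cog_te(J, m, tgt, radius = 0.03)
  expect_equal(lte$te, 0, tolerance = 1e-12)
  gte <- global_cog_te(J, m, tgt)
  expect_gt(gte$te, 0.04)
  expect_lte(lte$te, 0.03)
})

test_that("global focality matches the analytic half-mass radius of a uniform ball", {
  m <- layered_head()
  Ju <- matrix(0, nrow(m$tets), 3); Ju[, 1] <- 1
  tgt <- target_from_seed(m, c(0, 0, 0.08), 12)
  r_fem <- global_focality(Ju, m, tgt)
  # oracle: Monte-Carlo half-mass distance from the pole of a uniform ball
  set.seed(46)
  p <- matrix(runif(3 * 4e5, -0.08, 0.08), ncol = 3)
  p <- p[rowSums(p^2) <= 0.08^2, ]
  r_mc <- unname(quantile(sqrt(rowSums(sweep(p, 2, tgt$center)^2)), 0.5))
  expect_lt(abs(r_fem - r_mc) / r_mc, 0.05)
})

test_that("focality is concentrated-mass small and monotone under distant mass", {
  pts <- rbind(c(0, 0, 0), c(0.06, 0, 0))
  m <- point_cloud_mesh(pts)
  tgt <- structure(list(elements = 1L, direction = c(1, 0, 0),
                        center = c(0, 0, 0), element = 1L), class = "tes_target")
  J0 <- rbind(c(1, 0, 0), c(0, 0, 0) + 1e-15)
  expect_lt(global_focality(J0, m, tgt), 0.005)
  J1 <- rbind(c(1, 0, 0), c(1, 0, 0))
  expect_gte(global_focality(J1, m, tgt), global_focality(J0, m, tgt))
})

test_that("F_loc is the two-sphere mass ratio", {
  # half the mass at the local CoG, half at 2.5 cm (outside the 1 cm sphere)
  pts <- rbind(c(0, 0, 0), c(0.025, 0, 0))
  m <- point_cloud_mesh(pts)
  tgt <- structure(list(elements = 1L, direction = c(1, 0, 0),
                        center = c(0, 0, 0), element = 1L), class = "tes_target")
  J <- rbind(c(1, 0, 0), c(1, 0, 0))
  expect_equal(f_loc(J, m, tgt, local_cog = c(0, 0, 0)), 0.5)
  # 4-element hand fixture
  pts4 <- rbind(c(0, 0, 0), c(0.005, 0, 0), c(0.02, 0, 0), c(0.05, 0, 0))
  m4 <- point_cloud_mesh(pts4)
  J4 <- rbind(c(2, 0, 0), c(1, 0, 0), c(3, 0, 0), c(10, 0, 0))
  v <- m4$element_volumes
  w <- sqrt(rowSums(J4^2)) * v
  # inner sphere (1 cm about origin): elements 1, 2; outer (3 cm): 1, 2, 3
  expect_equal(f_loc(J4, m4, tgt, local_cog = c(0, 0, 0)),
               (w[1] + w[2]) / (w[1] + w[2] + w[3]))
  # all mass inside both spheres -> ratio 1
  Jin <- rbind(c(1, 0, 0), c(1, 0, 0), 1e-18 * c(1, 0, 0), 1e-18 * c(1, 0, 0))
  expect_equal(f_loc(Jin, m4, tgt, local_cog = c(0, 0, 0)), 1, tolerance = 1e-12)
})

test_that("normal-component map projects on outward cortical normals", {
  m <- coarse_head()
  nc0 <- normal_component_map(matrix(0, nrow(m$tets), 3) + 1e-300, m)
  el <- nc0$element
  radial <- m$element_centroids[el, ] / sqrt(rowSums(m$element_centroids[el, ]^2))
  J <- matrix(0, nrow(m$tets), 3)
  J[el, ] <- 2 * radial
  nc <- normal_component_map(J, m)
  expect_equal(nc$jn, rep(2, length(el)), tolerance = 0.01)
  # tangential current has (nearly) no normal component
  tang <- cbind(-radial[, 2], radial[, 1], 0)
  tang <- tang / sqrt(rowSums(tang^2))
  Jt <- matrix(0, nrow(m$tets), 3); Jt[el, ] <- tang
  expect_lt(max(abs(normal_component_map(Jt, m)$jn)), 0.1)
  # sign flips with the current
  expect_equal(normal_component_map(-J, m)$jn, -nc$jn)
})

test_that("metrics scale correctly under global pattern rescaling", {
  m <- layered_head()
  sys <- layered_system()
  tgt <- target_from_seed(m, c(0, 0, 0.08), 12)
  topo <- eeg_topography(sys, tgt$center, tgt$direction)
  pat <- opposite_pattern(topo)
  sol <- solve_system(sys, injection_rhs(sys, pat))
  J <- element_fields(sys, sol)$J
  r1 <- evaluate_field(J, m, tgt)
  r3 <- evaluate_field(3 * J, m, tgt)
  expect_equal(r3$intensity, 3 * r1$intensity, tolerance = 1e-9)
  expect_equal(r3$directional, 3 * r1$directional, tolerance = 1e-9)
  for (col in c("directionality", "te_global", "te_local", "focality_global", "f_loc")) {
    expect_equal(r3[[col]], r1[[col]], tolerance = 1e-9)
  }
  expect_lte(r1$te_local, 0.03)
  expect_gte(r1$directionality, -1); expect_lte(r1$directionality, 1)
})
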