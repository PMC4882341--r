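test_that("layered-sphere mesh labels elements by the shell containing the centroid", {
  m <- coarse_head()
  rc <- sqrt(rowSums(m$element_centroids^2))
  shell <- findInterval(rc, default_radii) + 1L
  shell[shell > 4L] <- 4L
  expect_identical(m$tissue, shell)
  expect_setequal(unique(m$tissue_labels[m$tissue]), default_labels)
})

test_that("mesh volume matches the analytic ball volume and improves with resolution", {
  # single shell, 0.09 m radius; radial layering does not change the volume
  m <- generate_layered_sphere_mesh(0.09, "brain", 0.006, radial_spacing = 0.09)
  vol <- sum(m$element_volumes)
  exact <- 4 / 3 * pi * 0.09^3
  expect_lt(abs(vol - exact) / exact, 0.02)

  m2 <- generate_layered_sphere_mesh(0.09, "brain", 0.012, radial_spacing = 0.09)
  err_coarse <- abs(sum(m2$element_volumes) - exact) / exact
  expect_lt(abs(vol - exact) / exact, err_coarse)
})

test_that("every interior facet is shared by exactly two tets, boundary by one", {
  m <- coarse_head()
  ft <- restim:::tet_face_table(m$tets)
  key <- paste(ft$sorted[, 1], ft$sorted[, 2], ft$sorted[, 3])
  counts <- table(table(key))
  expect_setequal(names(counts), c("1", "2"))
  expect_identical(as.integer(counts[["1"]]), nrow(m$boundary_facets))
  # all 4T faces accounted for
  expect_identical(as.integer(counts[["1"]] + 2 * counts[["2"]]), 4L * nrow(m$tets))
})

test_that("mesh generation is reproducible and validates its inputs", {
  m1 <- generate_layered_sphere_mesh(c(0.05, 0.06), c("brain", "scalp"), 0.011)
  m2 <- generate_layered_sphere_mesh(c(0.05, 0.06), c("brain", "scalp"), 0.011)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)

  expect_error(generate_layered_sphere_mesh(c(0.06, 0.05), c("a", "b"), 0.01),
               "strictly increasing")
  expect_error(generate_layered_sphere_mesh(c(0.08, 0.094), c("a", "b"), 0.03),
               "outer radius / 5", fixed = TRUE)
  # 0.5 mm shell cannot be resolved at 18 mm edge; failure names the shell
  expect_error(generate_layered_sphere_mesh(c(0.08, 0.0805, 0.094),
                                            c("brain", "csf", "scalp"), 0.018),
               "shell 2")
})

test_that("electrode montage is quasi-uniform with disjoint contact patches", {
  m <- coarse_head()
  mon <- place_electrodes(m, 128, contact_radius = 0.009)
  expect_length(mon$labels, 128)
  expect_true(all(lengths(mon$contact_facets) >= 1))
  d <- as.matrix(dist(mon$centers))
  expect_gt(min(d[upper.tri(d)]), 0)
  all_facets <- unlist(mon$contact_facets)
  expect_identical(anyDuplicated(all_facets), 0L)
  # contact areas sum to less than the outer surface area
  surf <- sum(boundary_facet_geometry(m)$areas)
  expect_lt(sum(mon$contact_area), surf)
})

test_that("contact areas approximate the electrode disc area on a fine surface", {
  m <- generate_layered_sphere_mesh(0.094, "brain", 0.004, radial_spacing = 0.094)
  mon <- place_electrodes(m, 64, contact_radius = 0.004)
  disc <- pi * 0.004^2
  expect_true(all(abs(mon$contact_area - disc) / disc < 0.3))
})

test_that("lumped contact resistance converts to impedance per unit area", {
  # 8 mm diameter electrode at 40 kOhm -> 2.01 Ohm m^2
  expect_equal(contact_impedance_per_area(40e3, 0.008), 2.01, tolerance = 0.01 / 2.01)
  expect_error(contact_impedance_per_area(-1, 0.008), "positive")
})

test_that("stretch factor is 1 for regular tets, 0 for degenerate, counts slivers", {
  m <- single_tet_mesh()
  q <- stretch_factor(m)
  expect_equal(q$per_element, 1, tolerance = 1e-12)

  # four coplanar points
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_equal(tet_stretch_factors(flat, matrix(1:4, 1, 4)), 0)

  # 99 regular tets + 1 sliver below threshold -> 1% flagged
  nd <- regular_tet_nodes()
  nodes <- do.call(rbind, lapply(0:98, function(k) sweep(nd, 2, c(3 * k, 0, 0), "+")))
  sliver <- rbind(c(0, 0, 500), c(1, 0, 500), c(0, 1, 500), c(0.3, 0.3, 500.0001))
  nodes <- rbind(nodes, sliver)
  tets <- matrix(seq_len(400), ncol = 4, byrow = TRUE)
  mesh <- restim:::build_tet_mesh(nodes, tets, tissue = rep(1L, 100),
                                  tissue_labels = "brain")
  q <- stretch_factor(mesh, threshold = 0.05)
  expect_equal(q$fraction_below, 0.01)
})
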