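# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

default_radii <- c(0.08, 0.083, 0.088, 0.094)
default_labels <- c("brain", "csf", "skull", "scalp")

# coarse four-shell head: ~13k tets, quick to assemble and solve
coarse_head <- function() fixture("coarse_head", function() {
  generate_layered_sphere_mesh(default_radii, default_labels, 0.018)
})

coarse_montage <- function() fixture("coarse_montage", function() {
  place_electrodes(coarse_head(), 64, contact_radius = 0.008)
})

coarse_system <- function() fixture("coarse_system", function() {
  assemble_cem_system(coarse_head(), default_conductivities(), coarse_montage())
})

coarse_transfer <- function() fixture("coarse_transfer", function() {
  build_transfer_matrix(coarse_system())
})

# four-shell head with layered brain interior: better field metrics
layered_head <- function() fixture("layered_head", function() {
  generate_layered_sphere_mesh(default_radii, default_labels, 0.014,
                               radial_spacing = 0.009)
})

layered_montage <- function() fixture("layered_montage", function() {
  place_electrodes(layered_head(), 64, contact_radius = 0.008)
})

layered_system <- function() fixture("layered_system", function() {
  assemble_cem_system(layered_head(), default_conductivities(), layered_montage())
})

# a single regular tetrahedron as a minimal mesh (edge a, positive volume)
regular_tet_nodes <- function(a = 1) {
  a / (2 * sqrt(2)) * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
}

single_tet_mesh <- function(a = 1) {
  restim:::build_tet_mesh(regular_tet_nodes(a), matrix(1:4, 1, 4),
                          tissue = 1L, tissue_labels = "brain")
}

# random unit vector
runit <- function() {
  u <- stats::rnorm(3)
  u / sqrt(sum(u^2))
}

# tangent unit vector orthogonal to u
rtangent <- function(u) {
  v <- stats::rnorm(3)
  v <- v - sum(v * u) * u
  v / sqrt(sum(v^2))
}
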