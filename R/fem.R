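# ---------------------------------------------------------------------------
# Complete-electrode-model finite element core: assembly, solve, fields
# ---------------------------------------------------------------------------

# per-element shape-function gradients (constant on each tet):
# grad lambda_2 = (e3 x e4)/6V etc., grad lambda_1 = -(sum of others)
tet_gradients <- function(mesh) {
  nd <- mesh$nodes; tt <- mesh$tets
  x1 <- nd[tt[, 1], , drop = FALSE]
  e2 <- nd[tt[, 2], , drop = FALSE] - x1
  e3 <- nd[tt[, 3], , drop = FALSE] - x1
  e4 <- nd[tt[, 4], , drop = FALSE] - x1
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  v6 <- 6 * mesh$element_volumes
  g2 <- cr(e3, e4) / v6
  g3 <- cr(e4, e2) / v6
  g4 <- cr(e2, e3) / v6
  g1 <- -(g2 + g3 + g4)
  # T x 4 per component
  list(
    gx = cbind(g1[, 1], g2[, 1], g3[, 1], g4[, 1]),
    gy = cbind(g1[, 2], g2[, 2], g3[, 2], g4[, 2]),
    gz = cbind(g1[, 3], g2[, 3], g3[, 3], g4[, 3])
  )
}

#' Assemble the complete-electrode-model stiffness system
#'
#' First-order Galerkin discretisation of the quasi-static volume conduction
#' problem with complete-electrode boundary conditions. The system matrix is
#' the symmetric `(N + L) x (N + L)` block matrix: the volume stiffness plus
#' `1/z_l`-weighted contact-facet mass terms, the node-electrode coupling
#' block and the electrode diagonal block. Before grounding it is positive
#' semi-definite with the constant vector as its one-dimensional nullspace.
#'
#' @param mesh a `tet_mesh`.
#' @param cond named conductivities, S/m (see [default_conductivities()]);
#'   every tissue label in the mesh must be present.
#' @param montage an `electrode_montage` on the mesh boundary.
#' @return a `cem_system` holding the sparse matrix, the per-element
#'   conductivities and shape-function gradients, and a factorisation cache.
#' @export
assemble_cem_system <- function(mesh, cond, montage = NULL) {
  labels <- mesh$tissue_labels[mesh$tissue]
  sigma <- unname(cond[labels])
  if (anyNA(sigma)) {
    stop("missing conductivity for tissue label(s): ",
         paste(unique(labels[is.na(sigma)]), collapse = ", "))
  }
  if (any(sigma <= 0)) stop("conductivities must be positive")
  if (!is.null(montage) && any(montage$z_l <= 0)) stop("contact impedances must be positive")

  N <- nrow(mesh$nodes)
  L <- if (is.null(montage)) 0L else length(montage$labels)
  g <- tet_gradients(mesh)
  w <- sigma * mesh$element_volumes

  Tn <- nrow(mesh$tets)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  # volume stiffness: K_ij = sigma V g_i . g_j, 16 entries per element
  iv <- rep(seq_len(4), times = 4)
  jv <- rep(seq_len(4), each = 4)
  voli <- vector("list", 16); volj <- vector("list", 16); volx <- vector("list", 16)
  for (k in seq_len(16)) {
    a <- iv[k]; b <- jv[k]
    voli[[k]] <- mesh$tets[, a]
    volj[[k]] <- mesh$tets[, b]
    volx[[k]] <- w * (g$gx[, a] * g$gx[, b] + g$gy[, a] * g$gy[, b] +
                        g$gz[, a] * g$gz[, b])
  }
  ii <- unlist(voli); jj <- unlist(volj); xx <- unlist(volx)

  # CEM surface terms per contact facet: (1/z) * facet mass matrix,
  # -(1/z) * area/3 node-electrode coupling, +(1/z) * area electrode diagonal
  fa <- if (L > 0) triangle_areas(mesh$nodes, mesh$boundary_facets) else numeric(0)
  si <- list(); sj <- list(); sx <- list(); k <- 0
  for (l in seq_len(L)) {
    fx <- montage$contact_facets[[l]]
    tri <- mesh$boundary_facets[fx, , drop = FALSE]
    S <- fa[fx]
    zi <- 1 / montage$z_l[l]
    el <- rep.int(N + l, length(fx))
    for (a in 1:3) for (b in 1:3) {
      k <- k + 1
      si[[k]] <- tri[, a]; sj[[k]] <- tri[, b]
      sx[[k]] <- zi * S / 12 * (1 + (a == b))
    }
    for (a in 1:3) {
      k <- k + 1
      si[[k]] <- c(tri[, a], el); sj[[k]] <- c(el, tri[, a])
      sx[[k]] <- rep(-zi * S / 3, 2)
    }
    k <- k + 1
    si[[k]] <- N + l; sj[[k]] <- N + l; sx[[k]] <- zi * sum(S)
  }
  ii <- c(ii, unlist(si)); jj <- c(jj, unlist(sj)); xx <- c(xx, unlist(sx))

  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N + L, N + L))
  sys <- list(
    K = K, n_nodes = N, n_electrodes = L,
    mesh = mesh, montage = montage, sigma = sigma, grads = g,
    cache = new.env(parent = emptyenv())
  )
  class(sys) <- "cem_system"
  sys
}

#' @export
print.cem_system <- function(x, ...) {
  cat(sprintf("cem_system: %d node + %d electrode unknowns, %d nonzeros\n",
              x$n_nodes, x$n_electrodes, length(x$K@x)))
  invisible(x)
}

# sparse Cholesky of the grounded system (last electrode unknown pinned),
# cached inside the system object; used as the PCG preconditioner
grounded_factor <- function(system) {
  if (is.null(system$cache$chol)) {
    n <- system$n_nodes + system$n_electrodes
    Kg <- system$K[-n, -n]
    system$cache$chol <- Matrix::Cholesky(Matrix::forceSymmetric(Kg), LDL = FALSE, perm = TRUE)
  }
  system$cache$chol
}

#' Solve the CEM system for a right-hand side
#'
#' Preconditioned conjugate gradients on the singular (pure-Neumann + CEM)
#' system, iterated in the orthogonal complement of the constant nullspace
#' vector. The preconditioner is a cached sparse Cholesky factorisation of
#' the grounded matrix, so convergence takes very few iterations; the
#' reported relative residual is measured on the full assembled matrix.
#' Potentials are returned re-referenced to zero-mean electrode potential.
#'
#' @param system a `cem_system`.
#' @param rhs numeric vector of length `N + L`: volume (dipole) entries
#'   followed by per-electrode injected currents. Must sum to zero (current
#'   conservation); see [injection_rhs()] and [dipole_rhs()].
#' @param tol relative residual tolerance (default 1e-11).
#' @param maxit iteration cap.
#' @return a `field_solution`: `potentials` (node potentials, V),
#'   `electrode_potentials` (V, zero mean), `relres`, `iterations`.
#' @export
solve_system <- function(system, rhs, tol = 1e-11, maxit = 5000) {
  n <- system$n_nodes + system$n_electrodes
  if (length(rhs) != n) stop("rhs has wrong length")
  bnorm <- sqrt(sum(rhs^2))
  if (bnorm == 0) {
    sol <- list(potentials = numeric(system$n_nodes),
                electrode_potentials = numeric(system$n_electrodes),
                relres = 0, iterations = 0L)
    class(sol) <- "field_solution"
    return(sol)
  }
  if (abs(sum(rhs)) > 1e-8 * sum(abs(rhs))) {
    stop(sprintf("incompatible rhs: entries sum to %.3g (current not conserved)", sum(rhs)))
  }
  ch <- grounded_factor(system)
  K <- system$K
  proj <- function(v) v - mean(v)
  minv <- function(r) {
    y <- numeric(n)
    y[-n] <- as.numeric(Matrix::solve(ch, r[-n], system = "A"))
    proj(y)
  }
  b <- proj(rhs)
  x <- numeric(n)
  r <- b
  z <- minv(r)
  p <- z
  rz <- sum(r * z)
  it <- 0L
  relres <- sqrt(sum(r^2)) / bnorm
  while (relres > tol && it < maxit) {
    q <- proj(as.numeric(K %*% p))
    alpha <- rz / sum(p * q)
    x <- x + alpha * p
    r <- r - alpha * q
    it <- it + 1L
    relres <- sqrt(sum(r^2)) / bnorm
    if (relres <= tol) break
    z <- minv(r)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  if (relres > tol) {
    stop(sprintf("solver did not reach tol %.2g in %d iterations (relres %.3g)",
                 tol, it, relres))
  }
  # re-reference: zero-mean electrode potentials (all-node mean if no electrodes)
  if (system$n_electrodes > 0) {
    x <- x - mean(x[system$n_nodes + seq_len(system$n_electrodes)])
  }
  sol <- list(
    potentials = x[seq_len(system$n_nodes)],
    electrode_potentials = x[system$n_nodes + seq_len(system$n_electrodes)],
    relres = relres, iterations = it
  )
  class(sol) <- "field_solution"
  sol
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("field_solution: %d node potentials, %d electrodes, relres %.2g in %d iterations\n",
              length(x$potentials), length(x$electrode_potentials),
              x$relres, x$iterations))
  invisible(x)
}

#' Per-element electric field and current density
#'
#' With first-order elements the potential gradient is constant on each
#' tetrahedron: `E = -grad(psi)` and `J = sigma * E` element-wise.
#'
#' @param system a `cem_system`.
#' @param solution a `field_solution` from [solve_system()].
#' @return list with `E` and `J`, both `T x 3` matrices (V/m and A/m^2).
#' @export
element_fields <- function(system, solution) {
  g <- system$grads
  tt <- system$mesh$tets
  psi <- solution$potentials
  p <- cbind(psi[tt[, 1]], psi[tt[, 2]], psi[tt[, 3]], psi[tt[, 4]])
  E <- -cbind(rowSums(p * g$gx), rowSums(p * g$gy), rowSums(p * g$gz))
  list(E = E, J = E * system$sigma)
}

#' Electrode currents recovered from the solved fields
#'
#' Integrates the current density through each electrode's contact facets.
#' On the contact surface the boundary condition ties the normal current
#' density to the potential jump across the contact layer,
#' `sigma dpsi/dn = (V_l - psi) / z_l`, so the facet integral is evaluated
#' in that (exactly integrable) form. For a solved injection pattern this
#' reproduces the prescribed per-electrode currents; the agreement is a
#' current-conservation check of the solution. (The alternative estimate
#' from the adjacent elements' constant gradients converges very slowly
#' because the current density is singular at the contact edge.)
#'
#' @param system a `cem_system`.
#' @param solution a `field_solution`.
#' @return per-electrode currents, amperes (positive = into the head).
#' @export
electrode_current_flux <- function(system, solution) {
  mesh <- system$mesh
  mon <- system$montage
  fa <- triangle_areas(mesh$nodes, mesh$boundary_facets)
  psi <- solution$potentials
  vapply(seq_along(mon$labels), function(l) {
    ix <- mon$contact_facets[[l]]
    tri <- mesh$boundary_facets[ix, , drop = FALSE]
    psibar <- (psi[tri[, 1]] + psi[tri[, 2]] + psi[tri[, 3]]) / 3
    sum((solution$electrode_potentials[l] - psibar) * fa[ix]) / mon$z_l[l]
  }, numeric(1))
}

#' Right-hand side for a scalp current injection pattern
#'
#' @param system a `cem_system`.
#' @param currents per-electrode currents in amperes (length L, zero sum),
#'   or an `injection_pattern`.
#' @return numeric rhs of length `N + L`.
#' @export
injection_rhs <- function(system, currents) {
  if (inherits(currents, "injection_pattern")) currents <- currents$currents
  if (length(currents) != system$n_electrodes) stop("pattern length != electrode count")
  c(numeric(system$n_nodes), currents)
}
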