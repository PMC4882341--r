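# ---------------------------------------------------------------------------
# Injection patterns, transfer matrix, dipole sources, EEG topographies,
# and the discrete reciprocity check
# ---------------------------------------------------------------------------

new_injection_pattern <- function(currents, method, I_max, cap = NA_real_) {
  p <- list(currents = as.numeric(currents), method = method,
            I_max = I_max, cap = cap)
  class(p) <- "injection_pattern"
  p
}

#' @export
print.injection_pattern <- function(x, ...) {
  act <- sum(abs(x$currents) > 1e-15)
  cat(sprintf("injection_pattern [%s]: %d electrodes (%d active), sum %.2g A, l1 %.4g A, max |I| %.4g A\n",
              x$method, length(x$currents), act, sum(x$currents),
              sum(abs(x$currents)), max(abs(x$currents))))
  invisible(x)
}

#' Elementary current injection pattern
#'
#' Pattern `i` of the complete set: electrode `i` sources `I_max` and every
#' other electrode sinks `I_max / (L - 1)`. Any zero-sum injection decomposes
#' uniquely on the first `L - 1` of these patterns.
#'
#' @param i source electrode index (1-based, `1 <= i <= L`).
#' @param L number of electrodes (>= 2).
#' @param I_max total injected current budget, amperes.
#' @return an `injection_pattern`.
#' @examples
#' elementary_pattern(1, 4, 1e-3)$currents  # (1, -1/3, -1/3, -1/3) mA
#' @export
elementary_pattern <- function(i, L, I_max) {
  if (L < 2) stop("need at least 2 electrodes")
  if (i < 1 || i > L) stop("electrode index out of range")
  if (I_max <= 0) stop("I_max must be positive")
  cur <- rep(-I_max / (L - 1), L)
  cur[i] <- I_max
  new_injection_pattern(cur, "elementary", I_max)
}

# L x (L-1) matrix whose columns are the elementary patterns 1..L-1
elementary_basis <- function(L, I_max) {
  P <- matrix(-I_max / (L - 1), L, L - 1)
  P[cbind(seq_len(L - 1), seq_len(L - 1))] <- I_max
  P
}

#' Decompose a zero-sum pattern on the elementary basis
#'
#' Solves the (consistent, overdetermined) linear map from elementary-basis
#' coefficients to electrode currents by normal equations.
#'
#' @param currents zero-sum per-electrode currents, length L.
#' @param I_max budget used to build the elementary basis.
#' @return coefficient vector of length `L - 1`.
#' @export
decompose_pattern <- function(currents, I_max) {
  L <- length(currents)
  P <- elementary_basis(L, I_max)
  cf <- solve(crossprod(P), crossprod(P, currents))
  res <- max(abs(P %*% cf - currents))
  if (res > 1e-9 * max(abs(currents))) {
    stop("pattern does not lie in the zero-sum space (decomposition residual too large)")
  }
  as.numeric(cf)
}

#' Build the per-element transfer matrix
#'
#' Solves the forward problem for the `L - 1` elementary injection patterns
#' and stores the per-element electric field of each, flattened element-major
#' and component-minor (x, y, z for element 1, then element 2, ...): a dense
#' `3T x (L - 1)` matrix. The omitted electrode `L` is the implicit reference
#' of the elementary set.
#'
#' @param system a `cem_system`.
#' @param I_max elementary pattern budget, amperes (default 1 mA).
#' @param tol forward solver tolerance.
#' @return a `transfer_matrix`: fields `M` (3T x L-1), `I_max`, `n_elements`,
#'   and solver diagnostics per column.
#' @export
build_transfer_matrix <- function(system, I_max = 1e-3, tol = 1e-11) {
  L <- system$n_electrodes
  Tn <- nrow(system$mesh$tets)
  M <- matrix(0, 3 * Tn, L - 1)
  iters <- integer(L - 1)
  relres <- numeric(L - 1)
  for (j in seq_len(L - 1)) {
    pat <- elementary_pattern(j, L, I_max)
    sol <- tryCatch(solve_system(system, injection_rhs(system, pat), tol = tol),
                    error = function(e) {
                      stop(sprintf("forward solve failed for elementary pattern %d: %s",
                                   j, conditionMessage(e)))
                    })
    E <- element_fields(system, sol)$E
    M[, j] <- as.numeric(t(E))
    iters[j] <- sol$iterations
    relres[j] <- sol$relres
  }
  tm <- list(M = M, I_max = I_max, n_elements = Tn, n_electrodes = L,
             iterations = iters, relres = relres,
             cache = new.env(parent = emptyenv()))
  class(tm) <- "transfer_matrix"
  tm
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("transfer_matrix: 3T x (L-1) = %d x %d (T = %d elements, L = %d electrodes)\n",
              nrow(x$M), ncol(x$M), x$n_elements, x$n_electrodes))
  invisible(x)
}

# rows of the transfer matrix holding the field at one element
transfer_rows <- function(element) 3 * (element - 1) + 1:3

#' Locate the tetrahedron containing a point
#'
#' Deterministic: among all elements whose closed simplex contains the point
#' (barycentric coordinates >= -tol), the lowest element index is returned.
#'
#' @param mesh a `tet_mesh`.
#' @param point length-3 position, metres.
#' @param label optional tissue label the element must carry.
#' @param grads precomputed [tet_gradients()] (recomputed when omitted).
#' @return element index, or an error if no element contains the point.
#' @export
find_containing_tet <- function(mesh, point, label = NULL, grads = NULL) {
  g <- if (is.null(grads)) tet_gradients(mesh) else grads
  d <- sweep(mesh$element_centroids, 2, point)
  # lambda_j(r) = 1/4 + g_j . (r - centroid)
  tol <- 1e-9
  ok <- rep(TRUE, nrow(mesh$tets))
  for (j in 1:4) {
    lam <- 0.25 - (g$gx[, j] * d[, 1] + g$gy[, j] * d[, 2] + g$gz[, j] * d[, 3])
    ok <- ok & (lam >= -tol)
  }
  if (!is.null(label)) ok <- ok & (mesh$tissue_labels[mesh$tissue] == label)
  hit <- which(ok)
  if (!length(hit)) {
    stop(if (is.null(label)) "point lies outside the mesh"
         else sprintf("point lies outside the '%s' compartment", label))
  }
  min(hit)
}

#' FEM right-hand side of a current dipole (partial integration)
#'
#' The dipole at `position` with moment `moment` contributes
#' `f_n = moment . grad(phi_n)` for the four vertices of the containing
#' tetrahedron and zero elsewhere; shape-function gradients sum to zero in a
#' tet, so the entries conserve current exactly.
#'
#' @param system a `cem_system`.
#' @param position dipole location, metres; must lie in a brain-labelled
#'   element (labels `brain`, `gm` or `wm`).
#' @param moment dipole moment, A m.
#' @param brain_labels tissue labels accepted as brain compartment.
#' @return list: `rhs` (length N + L), `element` (containing tet index).
#' @export
dipole_rhs <- function(system, position, moment,
                       brain_labels = c("brain", "gm", "wm")) {
  mesh <- system$mesh
  labs <- mesh$tissue_labels[mesh$tissue]
  present <- intersect(brain_labels, unique(labs))
  if (!length(present)) stop("mesh has no brain-labelled elements")
  el <- NA_integer_
  for (bl in present) {
    hit <- tryCatch(find_containing_tet(mesh, position, label = bl,
                                        grads = system$grads),
                    error = function(e) NA_integer_)
    if (!is.na(hit)) el <- min(el, hit, na.rm = TRUE)
  }
  if (is.na(el)) stop("dipole position is not inside the brain compartment")
  g <- system$grads
  rhs <- numeric(system$n_nodes + system$n_electrodes)
  nodes <- mesh$tets[el, ]
  for (j in 1:4) {
    rhs[nodes[j]] <- rhs[nodes[j]] +
      moment[1] * g$gx[el, j] + moment[2] * g$gy[el, j] + moment[3] * g$gz[el, j]
  }
  list(rhs = rhs, element = el)
}

#' EEG topography of a cortical dipole
#'
#' Solves the EEG forward problem for a dipole and returns the electrode
#' potentials re-referenced to zero mean (the ranking used by the targeting
#' methods is invariant to the reference).
#'
#' @inheritParams dipole_rhs
#' @param tol forward solver tolerance.
#' @return an `eeg_topography`: `potentials` (length L, zero mean, volts),
#'   `dipole` (position, moment, containing element), solver diagnostics.
#' @export
eeg_topography <- function(system, position, moment, tol = 1e-11,
                           brain_labels = c("brain", "gm", "wm")) {
  dr <- dipole_rhs(system, position, moment, brain_labels)
  sol <- solve_system(system, dr$rhs, tol = tol)
  phi <- sol$electrode_potentials
  phi <- phi - mean(phi)
  topo <- list(potentials = phi, position = position, moment = moment,
               element = dr$element, relres = sol$relres,
               iterations = sol$iterations)
  class(topo) <- "eeg_topography"
  topo
}

#' @export
print.eeg_topography <- function(x, ...) {
  cat(sprintf("eeg_topography: %d electrodes, range [%.3g, %.3g] V, pole electrodes %d / %d\n",
              length(x$potentials), min(x$potentials), max(x$potentials),
              which.max(x$potentials), which.min(x$potentials)))
  invisible(x)
}

#' Verify the TES-EEG reciprocity identity on the discretisation
#'
#' Computes both sides of the reciprocity relation
#' `Phi(a) - Phi(b) = d . grad(psi_ab)(r) / I_ab`
#' on the same mesh: the left side from the dipole (EEG) solve, the right
#' side from a pair-injection solve and the potential gradient in the
#' element containing the dipole. Because the assembled matrix is symmetric
#' the two agree up to solver tolerance.
#'
#' @param system a `cem_system`.
#' @param position,moment dipole location (m) and moment (A m).
#' @param pair integer pair of distinct electrode indices `(a, b)`; current
#'   `+I_ab` enters at `a` and leaves at `b`.
#' @param I_ab pair current, amperes.
#' @param tol forward solver tolerance.
#' @return list: `lhs`, `rhs` (volts), `mismatch` (relative, or absolute with
#'   `absolute = TRUE` when `|lhs|` is below the noise floor).
#' @export
verify_reciprocity <- function(system, position, moment, pair, I_ab = 1e-3,
                               tol = 1e-11) {
  if (length(pair) != 2 || pair[1] == pair[2]) stop("need two distinct electrodes")
  topo <- eeg_topography(system, position, moment, tol = tol)
  lhs <- topo$potentials[pair[1]] - topo$potentials[pair[2]]

  cur <- numeric(system$n_electrodes)
  cur[pair[1]] <- I_ab
  cur[pair[2]] <- -I_ab
  sol <- solve_system(system, injection_rhs(system, cur), tol = tol)
  el <- topo$element
  g <- system$grads
  psi <- sol$potentials[system$mesh$tets[el, ]]
  grad <- c(sum(psi * g$gx[el, ]), sum(psi * g$gy[el, ]), sum(psi * g$gz[el, ]))
  rhs <- sum(moment * grad) / I_ab

  floor_v <- 1e-12 * max(abs(topo$potentials), I_ab)
  if (abs(lhs) < floor_v) {
    list(lhs = lhs, rhs = rhs, mismatch = abs(lhs - rhs), absolute = TRUE)
  } else {
    list(lhs = lhs, rhs = rhs, mismatch = abs(lhs - rhs) / abs(lhs),
         absolute = FALSE)
  }
}

#' Forward-solve economy of reciprocity-based lead fields
#'
#' Building the lead field of `n_dipoles` sources directly takes one forward
#' solve per dipole; via reciprocity it takes one solve per elementary
#' injection pattern (`L - 1`). This is pure counting; no solves are run.
#'
#' @param L number of electrodes.
#' @param n_dipoles number of dipole locations.
#' @return list: `direct_solves`, `reciprocal_solves`, `ratio`.
#' @export
lead_field_economy <- function(L, n_dipoles) {
  if (L < 2 || n_dipoles < 1) stop("need L >= 2 and n_dipoles >= 1")
  list(direct_solves = n_dipoles, reciprocal_solves = L - 1,
       ratio = n_dipoles / (L - 1))
}

#' Export an injection pattern as CSV
#'
#' Columns `electrode_label`, `current_A`.
#' @param pattern an `injection_pattern`.
#' @param labels electrode labels.
#' @param path output path.
#' @export
write_pattern_csv <- function(pattern, labels, path) {
  utils::write.csv(data.frame(electrode_label = labels,
                              current_A = pattern$currents),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
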