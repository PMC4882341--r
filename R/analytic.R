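# ---------------------------------------------------------------------------
# Closed-form layered-sphere solutions: independent oracles for the FEM path
# ---------------------------------------------------------------------------

#' Concentric-sphere conductor model
#'
#' @param radii ascending shell outer radii, metres.
#' @param conductivities shell conductivities, S/m (same length).
#' @return a `sphere_model`.
#' @export
sphere_model <- function(radii, conductivities) {
  if (any(diff(radii) <= 0) || any(radii <= 0)) stop("radii must be ascending and positive")
  if (length(conductivities) != length(radii) || any(conductivities <= 0)) {
    stop("need one positive conductivity per shell")
  }
  m <- list(radii = radii, sigma = conductivities)
  class(m) <- "sphere_model"
  m
}

# Legendre P_n(x) and the m=1 associated function without Condon-Shortley
# phase (P_n^1 = sqrt(1-x^2) dP_n/dx), for n = 1..nmax; x a vector.
legendre_table <- function(x, nmax) {
  P <- matrix(0, length(x), nmax + 1)
  P[, 1] <- 1
  if (nmax >= 1) P[, 2] <- x
  for (n in 2:max(2, nmax)) {
    if (n > nmax) break
    P[, n + 1] <- ((2 * n - 1) * x * P[, n] - (n - 1) * P[, n - 1]) / n
  }
  # dP_n/dx from (1-x^2) P_n' = n (P_{n-1} - x P_n)
  s <- sqrt(pmax(0, 1 - x^2))
  P1 <- matrix(0, length(x), nmax)
  for (n in seq_len(nmax)) {
    num <- n * (P[, n] - x * P[, n + 1])
    P1[, n] <- ifelse(s > 0, num / s, 0)
  }
  list(P = P[, -1, drop = FALSE], P1 = P1)  # columns n = 1..nmax
}

# Per-degree radial solution of the multilayer problem with a source term
# kappa * r^{-(n+1)} in the innermost shell and an insulating exterior.
# Scaled two-end basis keeps all coefficients O(1) at high n.
# Returns the surface value multiplier: psi(R_outer) for unit kappa.
multilayer_surface_gain <- function(model, n, b) {
  r <- model$radii; sg <- model$sigma
  M <- length(r)
  # source value at r_1 for unit kappa: r1^{-(n+1)}
  S1 <- r[1]^-(n + 1)
  if (M == 1) {
    # n*alpha - (n+1)*S1*... flux at R: sg*(n a - (n+1) S1)/R = 0
    a1 <- (n + 1) / n * S1
    return(a1 + S1)
  }
  nun <- 2 * M - 1
  A <- matrix(0, nun, nun)
  rhs <- numeric(nun)
  # unknown order: alpha_1, then (alpha_k, beta_k) for k = 2..M
  ai <- function(k) if (k == 1) 1L else as.integer(2 * k - 2)
  bi <- function(k) as.integer(2 * k - 1)  # k >= 2
  rho <- c(NA, r[-M] / r[-1])  # rho_k = r_{k-1}/r_k for k >= 2
  eq <- 0
  for (k in seq_len(M - 1)) {
    # interface at r_k: continuity of psi and of sigma r dpsi/dr
    eq <- eq + 1
    if (k == 1) {
      A[eq, ai(1)] <- 1
      rhs[eq] <- -S1
    } else {
      A[eq, ai(k)] <- 1
      A[eq, bi(k)] <- rho[k]^(n + 1)
    }
    A[eq, ai(k + 1)] <- -rho[k + 1]^n
    A[eq, bi(k + 1)] <- -1
    eq <- eq + 1
    if (k == 1) {
      A[eq, ai(1)] <- sg[1] * n
      rhs[eq] <- sg[1] * (n + 1) * S1
    } else {
      A[eq, ai(k)] <- sg[k] * n
      A[eq, bi(k)] <- -sg[k] * (n + 1) * rho[k]^(n + 1)
    }
    A[eq, ai(k + 1)] <- -sg[k + 1] * n * rho[k + 1]^n
    A[eq, bi(k + 1)] <- sg[k + 1] * (n + 1)
  }
  # outer boundary: flux zero at r_M
  eq <- eq + 1
  A[eq, ai(M)] <- n
  A[eq, bi(M)] <- -(n + 1) * rho[M]^(n + 1)
  x <- solve(A, rhs)
  x[ai(M)] + x[bi(M)] * rho[M]^(n + 1)
}

#' Surface potential of a dipole in a layered sphere (Legendre series)
#'
#' Closed-form series solution for a current dipole inside the innermost
#' shell of a concentric multi-layer conductor with insulating exterior,
#' evaluated at points on the outer surface and re-referenced to zero mean.
#' The series is truncated at `n_terms` or earlier once the term magnitude
#' falls below a tail criterion.
#'
#' @param model a `sphere_model`.
#' @param position dipole location, metres (strictly inside the first shell).
#' @param moment dipole moment, A m.
#' @param points matrix of evaluation points on (or very near) the outer
#'   surface, one row each.
#' @param n_terms maximum series degree (default 80).
#' @return potentials in volts, zero-mean over the supplied points.
#' @export
sphere_dipole_potential <- function(model, position, moment, points,
                                    n_terms = 80) {
  if (n_terms < 1) stop("n_terms must be >= 1")
  b <- sqrt(sum(position^2))
  if (b >= model$radii[1]) stop("dipole must lie strictly inside the innermost shell")
  R <- model$radii[length(model$radii)]
  s1 <- model$sigma[1]

  # frame: ez along the dipole position (z axis through the source);
  # for a central dipole use the moment direction itself
  if (b > 1e-12) {
    ez <- position / b
  } else {
    ez <- moment / sqrt(sum(moment^2))
  }
  m_r <- sum(moment * ez)
  mt_vec <- moment - m_r * ez
  m_t <- sqrt(sum(mt_vec^2))
  if (m_t > 1e-15 * sqrt(sum(moment^2))) {
    ex <- mt_vec / m_t
  } else {
    # arbitrary orthogonal axis (tangential part vanishes)
    ex <- if (abs(ez[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ex <- ex - sum(ex * ez) * ez
    ex <- ex / sqrt(sum(ex^2))
    m_t <- 0
  }
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  # note: want right-handed (ex, ey, ez): ey = ez x ex
  pr <- sqrt(rowSums(points^2))
  ct <- pmin(1, pmax(-1, (points %*% ez) / pr))
  xs <- points %*% ex
  ys <- points %*% ey
  st <- sqrt(pmax(0, 1 - ct^2))
  cphi <- ifelse(st > 0, xs / (pr * st), 0)

  lt <- legendre_table(as.numeric(ct), n_terms)
  pot <- numeric(nrow(points))
  ref <- 0
  for (n in seq_len(n_terms)) {
    gain <- multilayer_surface_gain(model, n, b)
    kap_r <- m_r * n * b^(n - 1) / (4 * pi * s1)
    kap_t <- m_t * b^(n - 1) / (4 * pi * s1)
    term <- gain * (kap_r * lt$P[, n] + kap_t * lt$P1[, n] * cphi)
    pot <- pot + term
    tm <- max(abs(term))
    ref <- max(ref, max(abs(pot)))
    if (n > 5 && tm < 1e-14 * ref) break
  }
  as.numeric(pot - mean(pot))
}

#' Potentials of a surface point-electrode current pair on a homogeneous sphere
#'
#' Series/closed-form solution for two point current sources `+I` and `-I`
#' on the surface of a single-shell conducting sphere with insulating
#' exterior. For strictly interior evaluation points the truncated Legendre
#' series `I/(4 pi sigma R) sum (2n+1)/n (r/R)^n P_n(cos gamma)` is used; on
#' the surface itself the series converges only conditionally, so its summed
#' closed form `I/(4 pi sigma R) [1/s - 2 - log(s (1 + s))]`, `s =
#' sin(gamma/2)`, is evaluated instead.
#'
#' @param model a single-shell `sphere_model`.
#' @param point_a,point_b injection sites on the outer surface, metres.
#' @param current pair current `I`, amperes.
#' @param points evaluation points (rows), metres.
#' @param n_terms series degree for interior points.
#' @return potentials in volts, zero-mean over the supplied points.
#' @export
sphere_pair_potential <- function(model, point_a, point_b, current, points,
                                  n_terms = 80) {
  if (length(model$radii) != 1) {
    stop("point-electrode oracle supports the homogeneous (single-shell) sphere only")
  }
  R <- model$radii[1]
  sg <- model$sigma[1]
  one_source <- function(site) {
    site <- site / sqrt(sum(site^2)) * R
    r <- sqrt(rowSums(points^2))
    cg <- pmin(1, pmax(-1, (points %*% site) / (r * R)))
    surf <- r > R * (1 - 1e-9)
    out <- numeric(nrow(points))
    if (any(surf)) {
      s <- sin(acos(cg[surf]) / 2)
      s <- pmax(s, 1e-12)
      out[surf] <- current / (4 * pi * sg * R) * (1 / s - 2 - log(s * (1 + s)))
    }
    if (any(!surf)) {
      lt <- legendre_table(as.numeric(cg[!surf]), n_terms)
      t_ratio <- r[!surf] / R
      acc <- numeric(sum(!surf))
      for (n in seq_len(n_terms)) {
        acc <- acc + (2 * n + 1) / n * t_ratio^n * lt$P[, n]
      }
      out[!surf] <- current / (4 * pi * sg * R) * acc
    }
    out
  }
  pot <- one_source(point_a) - one_source(point_b)
  as.numeric(pot - mean(pot))
}

#' Relative difference and magnitude measures between two potential patterns
#'
#' The standard forward-model validation measures: `rdm` is the norm of the
#' difference of the two unit-normalised patterns (0 = identical shape, worst
#' case 2); `mag` is the ratio of norms (1 = identical strength).
#'
#' @param u,v numeric vectors (e.g. FEM and analytic electrode potentials).
#' @return list with `rdm` and `mag`.
#' @export
pattern_measures <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero pattern")
  list(rdm = sqrt(sum((u / nu - v / nv)^2)), mag = nu / nv)
}
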