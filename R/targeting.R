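# ---------------------------------------------------------------------------
# Montage optimization: LS / LCMV references, reciprocity selection methods,
# and the exhaustive pole-pair search
# ---------------------------------------------------------------------------

#' Targeting configuration
#'
#' Budget and electrode-count parameters shared by the optimizers. At the
#' defaults the total current `I_max` is spread over `n_sources = 10` source
#' electrodes so the per-electrode safety cap is `I_max / 10`; 30 sinks are
#' used by the "opposite" configuration and 10 by the "ring" configuration.
#' For small montages (`L < n_sources + n_sinks_opposite`) the counts scale
#' down proportionally, the cap rising to keep the budget feasible.
#'
#' @param I_max total injected current, amperes (default 1 mA).
#' @param cap per-electrode current cap, amperes (default `I_max / 10`).
#' @param n_sources number of source electrodes (default 10).
#' @param n_sinks_opposite sinks for the "opposite" method (default 30).
#' @param n_sinks_ring sinks for the "ring" method (default 10).
#' @return a `targeting_config` list.
#' @export
targeting_config <- function(I_max = 1e-3, cap = I_max / 10,
                             n_sources = 10, n_sinks_opposite = 30,
                             n_sinks_ring = 10) {
  if (I_max <= 0 || cap <= 0) stop("I_max and cap must be positive")
  if (cap * n_sources < I_max * (1 - 1e-12)) {
    stop("infeasible budget: cap * n_sources < I_max")
  }
  cfg <- list(I_max = I_max, cap = cap, n_sources = as.integer(n_sources),
              n_sinks_opposite = as.integer(n_sinks_opposite),
              n_sinks_ring = as.integer(n_sinks_ring))
  class(cfg) <- "targeting_config"
  cfg
}

# shrink the source/sink counts proportionally for small montages
scale_config <- function(cfg, L) {
  need <- cfg$n_sources + cfg$n_sinks_opposite
  if (L >= need) return(cfg)
  s <- L / need
  ns <- max(1L, as.integer(floor(cfg$n_sources * s)))
  targeting_config(
    I_max = cfg$I_max, cap = cfg$I_max / ns, n_sources = ns,
    n_sinks_opposite = max(1L, as.integer(floor(cfg$n_sinks_opposite * s))),
    n_sinks_ring = min(max(1L, as.integer(floor(cfg$n_sinks_ring * s))), L - ns)
  )
}

#' Build a cortical target from a seed point
#'
#' The region of interest is the `n_elements` brain elements nearest the seed
#' among those with at least one facet on the brain outer interface. The
#' targeting orientation is the normalised average of the outward facet
#' normals over the ROI's interface facets (the cortical surface normal); the
#' target centre is the volume-weighted ROI centroid.
#'
#' @param mesh a `tet_mesh`.
#' @param seed position near the brain surface, metres.
#' @param n_elements ROI size in elements (default 12).
#' @param brain_label tissue label of the brain shell (default the first of
#'   `brain`, `gm`, `wm` present in the mesh).
#' @return a `tes_target`: `elements`, `center`, `direction` (unit outward
#'   normal), `element` (ROI element nearest the centre).
#' @export
target_from_seed <- function(mesh, seed, n_elements = 12, brain_label = NULL) {
  if (is.null(brain_label)) {
    brain_label <- intersect(c("brain", "gm", "wm"), mesh$tissue_labels)[1]
    if (is.na(brain_label)) stop("mesh has no brain-labelled shell")
  }
  surf <- interface_facets(mesh, brain_label)
  if (nrow(surf$facets) == 0) stop("no brain interface facets found")
  el <- unique(surf$element)
  cen <- mesh$element_centroids[el, , drop = FALSE]
  d2 <- rowSums(sweep(cen, 2, seed)^2)
  if (min(d2) > (4 * max(mesh$target_edge, 0.01))^2) {
    stop("no brain interface facets near the seed point")
  }
  roi <- el[order(d2, el)][seq_len(min(n_elements, length(el)))]

  fsel <- surf$element %in% roi
  nbar <- colMeans(surf$normals[fsel, , drop = FALSE])
  nbar <- nbar / sqrt(sum(nbar^2))
  vols <- mesh$element_volumes[roi]
  ctr <- colSums(mesh$element_centroids[roi, , drop = FALSE] * vols) / sum(vols)
  d2c <- rowSums(sweep(mesh$element_centroids[roi, , drop = FALSE], 2, ctr)^2)
  tg <- list(elements = roi, center = ctr, direction = nbar,
             element = roi[which.min(d2c)], label = brain_label)
  class(tg) <- "tes_target"
  tg
}

#' @export
print.tes_target <- function(x, ...) {
  cat(sprintf("tes_target: %d elements, centre (%.1f, %.1f, %.1f) mm, normal (%.2f, %.2f, %.2f)\n",
              length(x$elements), 1000 * x$center[1], 1000 * x$center[2],
              1000 * x$center[3], x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

# selection vector b (ones on the ROI) replicated with the orientation:
# e = b (x) d, a 3T vector
target_field_vector <- function(n_elements, target) {
  e <- numeric(3 * n_elements)
  for (el in target$elements) e[transfer_rows(el)] <- target$direction
  e
}

tm_crossprod <- function(tm) {
  if (is.null(tm$cache)) return(crossprod(tm$M))
  if (is.null(tm$cache$MtM)) tm$cache$MtM <- crossprod(tm$M)
  tm$cache$MtM
}

# l1 rescaling shared by LS and LCMV: sources end up summing to I_max
rescale_l1 <- function(currents, I_max) {
  l1 <- sum(abs(currents))
  if (l1 == 0) stop("zero pattern cannot be rescaled")
  2 * I_max * currents / l1
}

#' Least-squares injection pattern
#'
#' Unregularised least squares of the transfer matrix against the objective
#' field `e = b (x) d` (the desired orientation replicated on the ROI
#' elements, zero elsewhere over the whole head). The coefficient solution is
#' mapped through the elementary patterns and l1-rescaled so the total
#' injected (positive) current is `I_max`.
#'
#' @param tm a `transfer_matrix` spanning the whole head.
#' @param target a `tes_target`.
#' @param cfg a `targeting_config`.
#' @return an `injection_pattern` (attribute `coefficients` holds the LS
#'   solution before rescaling).
#' @export
ls_pattern <- function(tm, target, cfg = targeting_config()) {
  e <- target_field_vector(tm$n_elements, target)
  MtM <- tm_crossprod(tm)
  Mte <- crossprod(tm$M, e)
  cf <- tryCatch(solve(MtM, Mte),
                 error = function(err) stop("degenerate montage: normal equations are rank deficient"))
  q <- as.numeric(elementary_basis(tm$n_electrodes, tm$I_max) %*% cf)
  p <- new_injection_pattern(rescale_l1(q, cfg$I_max), "ls", cfg$I_max)
  attr(p, "coefficients") <- as.numeric(cf)
  p
}

#' Linearly constrained minimum variance injection pattern
#'
#' Minimises the overall squared electric field subject to the hard
#' constraint that the field at the target element equals `d` exactly
#' (closed-form solution of the equality-constrained quadratic program).
#' The pattern is then l1-rescaled to the current budget like the LS one.
#'
#' @param tm a `transfer_matrix`.
#' @param target_element element index at the target position.
#' @param d desired field direction at the element (nonzero length-3).
#' @param cfg a `targeting_config`.
#' @return an `injection_pattern`; attributes `coefficients` and
#'   `constraint_residual` (relative, before rescaling).
#' @export
lcmv_pattern <- function(tm, target_element, d, cfg = targeting_config()) {
  if (sqrt(sum(d^2)) == 0) stop("degenerate target direction d = 0")
  Tt <- tm$M[transfer_rows(target_element), , drop = FALSE]
  if (qr(Tt)$rank < 3) stop("reduced transfer matrix at the target is rank deficient")
  MtM <- tm_crossprod(tm)
  A <- solve(MtM, t(Tt))              # (L-1) x 3
  G <- Tt %*% A                       # 3 x 3
  cf <- tryCatch(as.numeric(A %*% solve(G, d)),
                 error = function(err) stop("singular 3x3 reduced system at the target"))
  resid <- sqrt(sum((Tt %*% cf - d)^2)) / sqrt(sum(d^2))
  q <- as.numeric(elementary_basis(tm$n_electrodes, tm$I_max) %*% cf)
  p <- new_injection_pattern(rescale_l1(q, cfg$I_max), "lcmv", cfg$I_max)
  attr(p, "coefficients") <- cf
  attr(p, "constraint_residual") <- resid
  p
}

# deterministic potential ranking: ties broken by electrode index
rank_desc <- function(phi) order(-phi, seq_along(phi))
rank_asc <- function(phi) order(phi, seq_along(phi))

topo_potentials <- function(topo) {
  if (inherits(topo, "eeg_topography")) topo$potentials else as.numeric(topo)
}

#' One-source reciprocity pattern
#'
#' The electrode with the maximum topography potential sources the full
#' budget; every other electrode sinks `I_max / (L - 1)`. This configuration
#' follows reciprocity exactly but does not honour the per-electrode safety
#' cap (by design, as a reference).
#'
#' @param topo an `eeg_topography` (or a bare potential vector).
#' @param cfg a `targeting_config`.
#' @return an `injection_pattern`.
#' @export
one_source_pattern <- function(topo, cfg = targeting_config()) {
  phi <- topo_potentials(topo)
  L <- length(phi)
  if (L < 2) stop("need at least 2 electrodes")
  src <- rank_desc(phi)[1]
  cur <- rep(-cfg$I_max / (L - 1), L)
  cur[src] <- cfg$I_max
  new_injection_pattern(cur, "one_source", cfg$I_max)
}

#' "Opposite" reciprocity pattern
#'
#' The `n_sources` electrodes with the highest topography potentials source
#' `I_max / n_sources` each; the `n_sinks_opposite` electrodes with the
#' lowest potentials sink `I_max / n_sinks_opposite` each. At the defaults
#' the maximum per-electrode current is exactly `I_max / 10`.
#'
#' @inheritParams one_source_pattern
#' @export
opposite_pattern <- function(topo, cfg = targeting_config()) {
  phi <- topo_potentials(topo)
  L <- length(phi)
  cfg <- scale_config(cfg, L)
  if (L < cfg$n_sources + cfg$n_sinks_opposite) {
    stop(sprintf("montage too small: need >= %d electrodes (reduce source/sink counts)",
                 cfg$n_sources + cfg$n_sinks_opposite))
  }
  src <- rank_desc(phi)[seq_len(cfg$n_sources)]
  snk <- rank_asc(phi)[seq_len(cfg$n_sinks_opposite)]
  cur <- numeric(L)
  cur[src] <- cfg$I_max / cfg$n_sources
  cur[snk] <- -cfg$I_max / cfg$n_sinks_opposite
  new_injection_pattern(cur, "opposite", cfg$I_max, cap = cfg$cap)
}

#' "Ring" reciprocity pattern
#'
#' Sources as in [opposite_pattern()]; the sinks are the `n_sinks_ring`
#' electrodes nearest the source-set centroid (3-D Euclidean distance,
#' excluding the sources), forming a ring around the source cluster so
#' nearly all current stays near the target.
#'
#' @inheritParams one_source_pattern
#' @param montage the `electrode_montage` (for electrode positions).
#' @export
ring_pattern <- function(topo, montage, cfg = targeting_config()) {
  phi <- topo_potentials(topo)
  L <- length(phi)
  cfg <- scale_config(cfg, L)
  if (L < cfg$n_sources + cfg$n_sinks_ring) {
    stop("montage too small for the requested ring configuration")
  }
  src <- rank_desc(phi)[seq_len(cfg$n_sources)]
  ctr <- colMeans(montage$centers[src, , drop = FALSE])
  d2 <- rowSums(sweep(montage$centers, 2, ctr)^2)
  cand <- setdiff(order(d2, seq_len(L)), src)
  snk <- cand[seq_len(cfg$n_sinks_ring)]
  cur <- numeric(L)
  cur[src] <- cfg$I_max / cfg$n_sources
  cur[snk] <- -cfg$I_max / cfg$n_sinks_ring
  new_injection_pattern(cur, "ring", cfg$I_max, cap = cfg$cap)
}

#' ROADSS reciprocity pattern
#'
#' Reciprocity Opposite Averaged Distance Sink Selection: sources as in
#' [opposite_pattern()]; then the mirror point
#' `r_s = r - |r_m - r| * d` (with `r_m` the source-centroid and `d` the
#' outward target orientation) selects the `n_sources` nearest non-source
#' electrodes as sinks. Radial targets give ring-like sinks, tangential
#' targets give opposite-like sinks, making the targeting error robust to
#' the target orientation.
#'
#' @inheritParams ring_pattern
#' @param target a `tes_target` (uses `center` and `direction`).
#' @export
roadss_pattern <- function(topo, montage, target, cfg = targeting_config()) {
  phi <- topo_potentials(topo)
  L <- length(phi)
  cfg <- scale_config(cfg, L)
  if (L < 2 * cfg$n_sources) stop("montage too small for ROADSS")
  src <- rank_desc(phi)[seq_len(cfg$n_sources)]
  r_m <- colMeans(montage$centers[src, , drop = FALSE])
  d_rm <- sqrt(sum((r_m - target$center)^2))
  r_s <- target$center - d_rm * target$direction
  d2 <- rowSums(sweep(montage$centers, 2, r_s)^2)
  cand <- setdiff(order(d2, seq_len(L)), src)
  snk <- cand[seq_len(cfg$n_sources)]
  cur <- numeric(L)
  cur[src] <- cfg$I_max / cfg$n_sources
  cur[snk] <- -cfg$I_max / cfg$n_sources
  p <- new_injection_pattern(cur, "roadss", cfg$I_max, cap = cfg$cap)
  attr(p, "r_s") <- r_s
  attr(p, "r_m") <- r_m
  p
}

#' Exhaustive search for the reciprocally optimal electrode pair
#'
#' Enumerates all `L (L - 1) / 2` electrode pairs; for each, the field at the
#' target element under unit pair injection is reconstructed from the
#' transfer matrix by linearity, and the pair maximising the directional
#' potential gradient `d . grad(psi_ab)` (the reciprocity objective) is
#' returned. By the reciprocity identity this pair coincides with the
#' maximum/minimum electrodes of the dipole topography for the same target.
#'
#' @param tm a `transfer_matrix`.
#' @param target_element element index of the target.
#' @param d unit target orientation.
#' @return list `A`, `B` (source and return electrode indices), `value`
#'   (directional gradient per unit current, V/m/A), and `score` per
#'   electrode.
#' @export
brute_force_best_pair <- function(tm, target_element, d) {
  L <- tm$n_electrodes
  P <- elementary_basis(L, tm$I_max)
  D <- solve(crossprod(P), t(P))          # currents -> coefficients
  Tt <- tm$M[transfer_rows(target_element), , drop = FALSE]
  # per-electrode unit-current directional gradient: -d' E = d . grad(psi)
  w <- as.numeric(-(t(d) %*% Tt) %*% D)
  best <- c(NA_integer_, NA_integer_); bestv <- -Inf
  for (a in seq_len(L - 1)) {
    for (b in seq((a + 1), L)) {
      v <- w[a] - w[b]
      if (v > bestv) { bestv <- v; best <- c(a, b) }
      if (-v > bestv) { bestv <- -v; best <- c(b, a) }
    }
  }
  list(A = best[1], B = best[2], value = bestv, score = w)
}
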