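# ---------------------------------------------------------------------------
# Performance metrics: intensity, directionality, targeting error, focality
# ---------------------------------------------------------------------------

brain_element_indices <- function(mesh, brain_labels = c("brain", "gm", "wm")) {
  which(mesh$tissue_labels[mesh$tissue] %in% brain_labels)
}

#' Current-density intensity and directionality at the target
#'
#' The current density is averaged (volume-weighted) over the ROI elements;
#' returned are its magnitude, its projection on the desired orientation and
#' the normalised dot product (directionality in `[-1, 1]`).
#'
#' @param J per-element current density, `T x 3` (A/m^2).
#' @param mesh a `tet_mesh` (for element volumes).
#' @param target a `tes_target`.
#' @return list: `intensity`, `directional` (both A/m^2), `directionality`.
#' @export
target_intensity <- function(J, mesh, target) {
  roi <- target$elements
  if (!length(roi)) stop("empty ROI")
  w <- mesh$element_volumes[roi]
  Jbar <- colSums(J[roi, , drop = FALSE] * w) / sum(w)
  mag <- sqrt(sum(Jbar^2))
  dirI <- sum(Jbar * target$direction)
  list(intensity = mag, directional = dirI,
       directionality = if (mag > 0) dirI / mag else 0)
}

# |J| V weights over a set of brain elements, with the suprathreshold rule
cog_of <- function(J, mesh, elements, threshold = 0.75) {
  jmag <- sqrt(rowSums(J[elements, , drop = FALSE]^2))
  keep <- jmag >= threshold * max(jmag)
  w <- jmag[keep] * mesh$element_volumes[elements][keep]
  x <- mesh$element_centroids[elements[keep], , drop = FALSE]
  colSums(x * w) / sum(w)
}

#' Global centre-of-gravity targeting error
#'
#' Centre of gravity of the suprathreshold imprinted current density over the
#' brain elements (weights `|J|_i V_i`, threshold 75% of the absolute
#' maximum), and its distance to the target centre.
#'
#' @inheritParams target_intensity
#' @param threshold suprathreshold fraction of the maximum (default 0.75).
#' @param brain_labels tissue labels counted as brain.
#' @return list: `cog` (m), `te` (m).
#' @export
global_cog_te <- function(J, mesh, target, threshold = 0.75,
                          brain_labels = c("brain", "gm", "wm")) {
  el <- brain_element_indices(mesh, brain_labels)
  if (!length(el)) stop("no brain elements")
  cog <- cog_of(J, mesh, el, threshold)
  list(cog = cog, te = sqrt(sum((cog - target$center)^2)))
}

#' Local centre-of-gravity targeting error
#'
#' As [global_cog_te()] but restricted to the brain elements within `radius`
#' (default 3 cm) of the target centre; the 75% threshold is applied within
#' that neighbourhood. By construction the local TE cannot exceed `radius`.
#'
#' @inheritParams global_cog_te
#' @param radius neighbourhood radius, metres (default 0.03).
#' @return list: `cog` (m), `te` (m).
#' @export
local_cog_te <- function(J, mesh, target, radius = 0.03, threshold = 0.75,
                         brain_labels = c("brain", "gm", "wm")) {
  el <- brain_element_indices(mesh, brain_labels)
  d2 <- rowSums(sweep(mesh$element_centroids[el, , drop = FALSE], 2, target$center)^2)
  el <- el[d2 <= radius^2]
  if (!length(el)) stop("no brain elements within the local neighbourhood")
  cog <- cog_of(J, mesh, el, threshold)
  list(cog = cog, te = sqrt(sum((cog - target$center)^2)))
}

#' Global focality radius
#'
#' Radius of the smallest sphere centred at the target containing half of the
#' total current density in the brain (mass `|J|_i V_i`, membership by
#' element centroid). Analogous to a half-width-at-half-maximum: smaller is
#' more focal.
#'
#' @inheritParams global_cog_te
#' @return radius, metres.
#' @export
global_focality <- function(J, mesh, target,
                            brain_labels = c("brain", "gm", "wm")) {
  el <- brain_element_indices(mesh, brain_labels)
  jm <- sqrt(rowSums(J[el, , drop = FALSE]^2))
  w <- jm * mesh$element_volumes[el]
  tot <- sum(w)
  if (tot <= 0) stop("zero current density in the brain")
  d <- sqrt(rowSums(sweep(mesh$element_centroids[el, , drop = FALSE], 2, target$center)^2))
  o <- order(d)
  cw <- cumsum(w[o])
  d[o][which(cw >= 0.5 * tot)[1]]
}

#' Local focality ratio F_loc
#'
#' Ratio of the current-density mass (`|J|_i V_i`) in a sphere of radius
#' `r_in` (default 1 cm) around the local centre of gravity to the mass in a
#' sphere of radius `r_out` (default 3 cm) around the target. Values near 1
#' mean the local maximum is sharp. When the local CoG sits far from the
#' target the inner sphere may leave the outer one and the ratio can exceed
#' 1; a warning is attached in that case.
#'
#' @inheritParams global_cog_te
#' @param local_cog the local centre of gravity (m), e.g. from
#'   [local_cog_te()]; computed when omitted.
#' @param r_in,r_out inner/outer radii, metres.
#' @return `F_loc` (unitless); `NA` with a warning if the denominator is zero.
#' @export
f_loc <- function(J, mesh, target, local_cog = NULL,
                  r_in = 0.01, r_out = 0.03,
                  brain_labels = c("brain", "gm", "wm")) {
  if (is.null(local_cog)) local_cog <- local_cog_te(J, mesh, target, radius = r_out,
                                                    brain_labels = brain_labels)$cog
  el <- brain_element_indices(mesh, brain_labels)
  jm <- sqrt(rowSums(J[el, , drop = FALSE]^2))
  w <- jm * mesh$element_volumes[el]
  cen <- mesh$element_centroids[el, , drop = FALSE]
  din <- rowSums(sweep(cen, 2, local_cog)^2) <= r_in^2
  dout <- rowSums(sweep(cen, 2, target$center)^2) <= r_out^2
  den <- sum(w[dout])
  if (den <= 0) {
    warning("zero current-density mass in the outer sphere; F_loc undefined")
    return(NA_real_)
  }
  ratio <- sum(w[din]) / den
  if (sqrt(sum((local_cog - target$center)^2)) > r_out - r_in && ratio > 1) {
    warning("local CoG far from target: inner sphere leaves the outer one, F_loc > 1")
  }
  ratio
}

#' Normal-to-cortex component of the current density
#'
#' Signed projection `J . n` of the per-element current density on the
#' outward cortical-surface normal, for the brain elements adjacent to the
#' brain interface.
#'
#' @param J per-element current density, `T x 3`.
#' @param mesh a `tet_mesh`.
#' @param brain_label label of the cortical shell.
#' @return list: `element` (interface-adjacent brain elements), `normal`
#'   (their outward normals, area-averaged over adjacent facets), `jn`
#'   (signed normal component, A/m^2).
#' @export
normal_component_map <- function(J, mesh, brain_label = NULL) {
  if (is.null(brain_label)) {
    brain_label <- intersect(c("brain", "gm", "wm"), mesh$tissue_labels)[1]
  }
  surf <- interface_facets(mesh, brain_label)
  el <- sort(unique(surf$element))
  nrm <- matrix(0, length(el), 3)
  for (k in seq_along(el)) {
    sel <- surf$element == el[k]
    v <- colSums(surf$normals[sel, , drop = FALSE] * surf$areas[sel])
    nrm[k, ] <- v / sqrt(sum(v^2))
  }
  jn <- rowSums(J[el, , drop = FALSE] * nrm)
  list(element = el, normal = nrm, jn = jn)
}

#' Evaluate a delivered field against a target: the full metric report
#'
#' @param J per-element current density, `T x 3` (A/m^2).
#' @param mesh a `tet_mesh`.
#' @param target a `tes_target`.
#' @param method name recorded in the report.
#' @param threshold suprathreshold fraction for the CoG metrics.
#' @param local_radius local neighbourhood radius, metres.
#' @param r_in inner F_loc radius, metres.
#' @return one-row `data.frame`: `method`, `intensity`, `directional`,
#'   `directionality`, `te_global`, `te_local`, `focality_global`, `f_loc`.
#' @export
evaluate_field <- function(J, mesh, target, method = "pattern",
                           threshold = 0.75, local_radius = 0.03,
                           r_in = 0.01) {
  ti <- target_intensity(J, mesh, target)
  gte <- global_cog_te(J, mesh, target, threshold)
  lte <- local_cog_te(J, mesh, target, local_radius, threshold)
  data.frame(
    method = method,
    intensity = ti$intensity,
    directional = ti$directional,
    directionality = ti$directionality,
    te_global = gte$te,
    te_local = lte$te,
    focality_global = global_focality(J, mesh, target),
    f_loc = f_loc(J, mesh, target, local_cog = lte$cog,
                  r_in = r_in, r_out = local_radius),
    stringsAsFactors = FALSE
  )
}

#' Solve a pattern and evaluate it against a target
#'
#' Convenience wrapper: forward-solves the injection pattern on the system,
#' derives the per-element current density and calls [evaluate_field()].
#'
#' @param system a `cem_system`.
#' @param pattern an `injection_pattern`.
#' @param target a `tes_target`.
#' @param tol forward solver tolerance.
#' @param ... passed to [evaluate_field()].
#' @export
evaluate_pattern <- function(system, pattern, target, tol = 1e-11, ...) {
  sol <- solve_system(system, injection_rhs(system, pattern), tol = tol)
  J <- element_fields(system, sol)$J
  evaluate_field(J, system$mesh, target, method = pattern$method, ...)
}
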