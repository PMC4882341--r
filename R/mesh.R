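#' @importFrom Matrix sparseMatrix Cholesky Diagonal
#' @importFrom stats setNames
#' @importFrom methods as
NULL

# ---------------------------------------------------------------------------
# Icosphere surface: subdivided icosahedron with vertices on the unit sphere.
# Deterministic: fixed vertex table, fixed subdivision order.
# ---------------------------------------------------------------------------

icosphere <- function(subdiv) {
  stopifnot(subdiv >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  # enforce outward (counter-clockwise seen from outside) orientation
  d <- v[f[, 1], 1] * (v[f[, 2], 2] * v[f[, 3], 3] - v[f[, 2], 3] * v[f[, 3], 2]) -
       v[f[, 1], 2] * (v[f[, 2], 1] * v[f[, 3], 3] - v[f[, 2], 3] * v[f[, 3], 1]) +
       v[f[, 1], 3] * (v[f[, 2], 1] * v[f[, 3], 2] - v[f[, 2], 2] * v[f[, 3], 1])
  flip <- d < 0
  f[flip, c(2, 3)] <- f[flip, c(3, 2)]

  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    ea <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
    uk <- unique(key)
    idx <- match(key, uk)
    first <- match(uk, key)
    mids <- (v[ea[first, 1], ] + v[ea[first, 2], ]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m12 <- nv + idx[seq_len(nrow(f))]
    m23 <- nv + idx[nrow(f) + seq_len(nrow(f))]
    m31 <- nv + idx[2 * nrow(f) + seq_len(nrow(f))]
    f <- rbind(
      cbind(f[, 1], m12, m31),
      cbind(f[, 2], m23, m12),
      cbind(f[, 3], m31, m23),
      cbind(m12, m23, m31)
    )
  }
  list(verts = v, faces = f)
}

# subdivision level needed so the surface edge length at radius r is <= target
icosphere_level <- function(r, target_edge) {
  # icosahedron edge / circumradius = 4 / sqrt(10 + 2*sqrt(5))
  edge0 <- 4 / sqrt(10 + 2 * sqrt(5))
  s <- 0
  while (r * edge0 / 2^s > target_edge && s < 7) s <- s + 1
  s
}

# ---------------------------------------------------------------------------
# Layered-sphere tetrahedral mesh
# ---------------------------------------------------------------------------

#' Generate a deterministic layered-sphere tetrahedral head mesh
#'
#' Builds a concentric multi-shell ball (e.g. brain/CSF/skull/scalp) as a
#' conforming tetrahedral mesh. Subdivided-icosahedron surfaces are placed at a
#' set of radial levels that contains every shell interface exactly; the
#' triangular prisms between consecutive levels are split into three
#' tetrahedra each using the smallest-global-index diagonal rule (which
#' guarantees matching faces between neighbours), and the innermost level is
#' fanned to the centre node. The construction involves no randomness, so the
#' mesh is bit-reproducible for fixed parameters.
#'
#' @param radii strictly increasing outer radii of the shells, metres.
#' @param labels character tissue label per shell (same length as `radii`).
#' @param target_edge requested surface edge length, metres. Controls the
#'   angular subdivision; must be smaller than a fifth of the outer radius.
#' @param radial_spacing requested radial distance between node levels,
#'   metres. Defaults to `4 * target_edge`; each shell always receives at
#'   least one element layer and its interfaces are honoured exactly.
#' @return an object of class `tet_mesh` with fields `nodes` (N x 3, metres),
#'   `tets` (T x 4, 1-based node indices), `tissue` (integer shell code per
#'   element), `tissue_labels` (code -> label), `element_volumes`,
#'   `element_centroids`, `boundary_facets` (node triples on the outer
#'   surface) and `boundary_tet` (owning element of each boundary facet).
#' @examples
#' m <- generate_layered_sphere_mesh(c(0.08, 0.094), c("brain", "scalp"), 0.035)
#' sum(m$element_volumes) / (4 / 3 * pi * 0.094^3)
#' @export
generate_layered_sphere_mesh <- function(radii, labels,
                                         target_edge,
                                         radial_spacing = 4 * target_edge) {
  if (length(radii) < 1 || any(diff(radii) <= 0) || any(radii <= 0)) {
    stop("`radii` must be strictly increasing and positive")
  }
  if (length(labels) != length(radii)) {
    stop("need one tissue label per shell")
  }
  outer <- radii[length(radii)]
  if (target_edge >= outer / 5) {
    stop("`target_edge` must be smaller than outer radius / 5")
  }
  thick <- diff(c(0, radii))
  bad <- which(thick < target_edge / 10)
  if (length(bad)) {
    stop(sprintf("shell %d (label '%s') is too thin (%.4g m) to resolve at target_edge %.4g m",
                 bad[1], labels[bad[1]], thick[bad[1]], target_edge))
  }

  s <- icosphere_level(outer, target_edge)
  ico <- icosphere(s)
  V <- nrow(ico$verts)
  Fc <- nrow(ico$faces)

  # radial levels: each shell [r_{k-1}, r_k] gets >= 1 uniform layer
  levels <- numeric(0)
  for (k in seq_along(radii)) {
    nk <- max(1L, as.integer(round(thick[k] / radial_spacing)))
    r0 <- if (k == 1) 0 else radii[k - 1]
    levels <- c(levels, r0 + thick[k] * seq_len(nk) / nk)
  }
  K <- length(levels)

  nodes <- matrix(0, nrow = 1 + K * V, ncol = 3)
  for (j in seq_len(K)) {
    nodes[1 + (j - 1) * V + seq_len(V), ] <- ico$verts * levels[j]
  }

  # central fan: centre node (index 1) to the first level
  lvl1 <- 1 + ico$faces
  tets_central <- cbind(1L, lvl1[, 1], lvl1[, 2], lvl1[, 3])

  # prisms between consecutive levels, 3 tets each
  prism_tets <- function(b1, b2, b3, V) {
    # rotate cyclically so the smallest global bottom index comes first
    amin <- max.col(-cbind(b1, b2, b3), ties.method = "first")
    v1 <- ifelse(amin == 1, b1, ifelse(amin == 2, b2, b3))
    v2 <- ifelse(amin == 1, b2, ifelse(amin == 2, b3, b1))
    v3 <- ifelse(amin == 1, b3, ifelse(amin == 2, b1, b2))
    t1 <- v1 + V; t2 <- v2 + V; t3 <- v3 + V
    case <- v2 < v3  # diagonal on the (v2,v3,t3,t2) quad from min(v2,v3)
    rbind(
      cbind(v1, v2, v3, ifelse(case, t3, t2)),
      cbind(v1, ifelse(case, v2, v3), ifelse(case, t3, t2), ifelse(case, t2, t3)),
      cbind(v1, t1, t2, t3)
    )
  }
  tl <- vector("list", K)
  tl[[1]] <- tets_central
  if (K > 1) {
    for (j in seq_len(K - 1)) {
      base <- 1 + (j - 1) * V
      fb <- base + ico$faces
      tl[[j + 1]] <- prism_tets(fb[, 1], fb[, 2], fb[, 3], V)
    }
  }
  tets <- do.call(rbind, tl)
  storage.mode(tets) <- "integer"

  mesh <- build_tet_mesh(nodes, tets, radii, labels)
  mesh$target_edge <- target_edge
  mesh$radii <- radii
  mesh
}

# assemble derived quantities, repair orientation, label elements by centroid
build_tet_mesh <- function(nodes, tets, radii = NULL, labels = NULL,
                           tissue = NULL, tissue_labels = NULL) {
  dimnames(nodes) <- NULL
  dimnames(tets) <- NULL
  p1 <- nodes[tets[, 1], , drop = FALSE]
  p2 <- nodes[tets[, 2], , drop = FALSE]
  p3 <- nodes[tets[, 3], , drop = FALSE]
  p4 <- nodes[tets[, 4], , drop = FALSE]
  vol6 <- signed_vol6(p1, p2, p3, p4)
  neg <- vol6 < 0
  if (any(neg)) {
    tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
    tmp <- p3[neg, , drop = FALSE]
    p3[neg, ] <- p4[neg, , drop = FALSE]
    p4[neg, ] <- tmp
    vol6 <- abs(vol6)
  }
  vols <- vol6 / 6
  if (any(vols <= 0)) stop("degenerate (zero-volume) element in mesh")
  cent <- (p1 + p2 + p3 + p4) / 4

  if (is.null(tissue)) {
    rc <- sqrt(rowSums(cent^2))
    shell <- findInterval(rc, radii) + 1L
    shell[shell > length(radii)] <- length(radii)  # guard roundoff at surface
    tissue <- shell
    tissue_labels <- labels
  }

  bf <- boundary_facet_table(tets)
  mesh <- list(
    nodes = nodes, tets = tets, tissue = as.integer(tissue),
    tissue_labels = tissue_labels,
    element_volumes = vols, element_centroids = cent,
    boundary_facets = bf$facets, boundary_tet = bf$tet
  )
  class(mesh) <- "tet_mesh"
  mesh
}

signed_vol6 <- function(p1, p2, p3, p4) {
  a <- p2 - p1; b <- p3 - p1; c <- p4 - p1
  a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
  a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
  a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
}

# all 4T faces with owning tet; sorted node triples for matching
tet_face_table <- function(tets) {
  Tn <- nrow(tets)
  faces <- rbind(
    tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
    tets[, c(1, 2, 4)], tets[, c(1, 2, 3)]
  )
  fs <- cbind(pmin(faces[, 1], faces[, 2], faces[, 3]),
              faces[, 1] + faces[, 2] + faces[, 3] -
                pmin(faces[, 1], faces[, 2], faces[, 3]) -
                pmax(faces[, 1], faces[, 2], faces[, 3]),
              pmax(faces[, 1], faces[, 2], faces[, 3]))
  list(sorted = fs, tet = rep(seq_len(Tn), 4))
}

# facets that belong to exactly one tet (the outer surface)
boundary_facet_table <- function(tets) {
  ft <- tet_face_table(tets)
  o <- order(ft$sorted[, 1], ft$sorted[, 2], ft$sorted[, 3])
  fs <- ft$sorted[o, , drop = FALSE]
  tt <- ft$tet[o]
  n <- nrow(fs)
  same_next <- c(fs[-n, 1] == fs[-1, 1] & fs[-n, 2] == fs[-1, 2] &
                   fs[-n, 3] == fs[-1, 3], FALSE)
  same_prev <- c(FALSE, same_next[-n])
  single <- !(same_next | same_prev)
  list(facets = fs[single, , drop = FALSE], tet = tt[single])
}

# interior facet pairing; returns facets with the two adjacent tets
interior_facet_table <- function(tets) {
  ft <- tet_face_table(tets)
  o <- order(ft$sorted[, 1], ft$sorted[, 2], ft$sorted[, 3])
  fs <- ft$sorted[o, , drop = FALSE]
  tt <- ft$tet[o]
  n <- nrow(fs)
  same_next <- c(fs[-n, 1] == fs[-1, 1] & fs[-n, 2] == fs[-1, 2] &
                   fs[-n, 3] == fs[-1, 3], FALSE)
  i <- which(same_next)
  list(facets = fs[i, , drop = FALSE], tet1 = tt[i], tet2 = tt[i + 1])
}

triangle_areas <- function(nodes, tris) {
  a <- nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 2], , drop = FALSE]
  c <- nodes[tris[, 3], , drop = FALSE]
  u <- b - a; v <- c - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

triangle_centroids <- function(nodes, tris) {
  (nodes[tris[, 1], , drop = FALSE] +
   nodes[tris[, 2], , drop = FALSE] +
   nodes[tris[, 3], , drop = FALSE]) / 3
}

# unit normals oriented away from the owning tet's centroid
facet_outward_normals <- function(mesh, facets, owner_tet) {
  a <- mesh$nodes[facets[, 1], , drop = FALSE]
  b <- mesh$nodes[facets[, 2], , drop = FALSE]
  c <- mesh$nodes[facets[, 3], , drop = FALSE]
  u <- b - a; v <- c - a
  nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  nrm <- cbind(nx, ny, nz)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  fc <- triangle_centroids(mesh$nodes, facets)
  outdir <- fc - mesh$element_centroids[owner_tet, , drop = FALSE]
  flip <- rowSums(nrm * outdir) < 0
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  nrm
}

# Facets on the interface between `label` tissue and anything else (or the
# outer boundary when the labelled region touches it). Normals point out of
# the labelled region.
interface_facets <- function(mesh, label) {
  code <- match(label, mesh$tissue_labels)
  if (is.na(code)) stop(sprintf("unknown tissue label '%s'", label))
  it <- interior_facet_table(mesh$tets)
  l1 <- mesh$tissue[it$tet1]; l2 <- mesh$tissue[it$tet2]
  sel <- (l1 == code) != (l2 == code)
  facets <- it$facets[sel, , drop = FALSE]
  owner <- ifelse(l1[sel] == code, it$tet1[sel], it$tet2[sel])
  bsel <- mesh$tissue[mesh$boundary_tet] == code
  facets <- rbind(facets, mesh$boundary_facets[bsel, , drop = FALSE])
  owner <- c(owner, mesh$boundary_tet[bsel])
  if (nrow(facets) == 0) {
    return(list(facets = facets, element = owner,
                normals = matrix(0, 0, 3), areas = numeric(0),
                centroids = matrix(0, 0, 3)))
  }
  list(
    facets = facets, element = owner,
    normals = facet_outward_normals(mesh, facets, owner),
    areas = triangle_areas(mesh$nodes, facets),
    centroids = triangle_centroids(mesh$nodes, facets)
  )
}

#' Geometry of the outer-surface facets
#'
#' @param mesh a `tet_mesh`.
#' @return list with `centroids` (B x 3) and `areas` (length B) of the
#'   boundary facets, in mesh order.
#' @export
boundary_facet_geometry <- function(mesh) {
  list(centroids = triangle_centroids(mesh$nodes, mesh$boundary_facets),
       areas = triangle_areas(mesh$nodes, mesh$boundary_facets))
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tetrahedra, %d boundary facets\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$boundary_facets)))
  tab <- table(factor(x$tissue_labels[x$tissue], levels = x$tissue_labels))
  for (l in names(tab)) cat(sprintf("  %-8s %d elements\n", l, tab[[l]]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Mesh quality
# ---------------------------------------------------------------------------

#' Tetrahedral stretch-factor quality metric
#'
#' The stretch factor of an element is the ratio of its inscribed-sphere
#' radius to its longest edge, normalised by `2*sqrt(6)` so a regular
#' tetrahedron scores exactly 1 and a degenerate (coplanar) element scores 0.
#' Elements below a small threshold (default 0.05) are slivers that degrade
#' the accuracy of potential-gradient computations.
#'
#' @param mesh a `tet_mesh`.
#' @param threshold quality threshold used for the reported fraction.
#' @return list with `per_element` stretch factors in `[0, 1]`, `fraction_below`
#'   the threshold, and the `threshold` itself.
#' @export
stretch_factor <- function(mesh, threshold = 0.05) {
  sf <- tet_stretch_factors(mesh$nodes, mesh$tets)
  list(per_element = sf,
       fraction_below = mean(sf < threshold),
       threshold = threshold)
}

#' Stretch factors from raw node/tet arrays
#'
#' Workhorse behind [stretch_factor()]; degenerate (zero-volume) elements map
#' to 0 without raising an error.
#'
#' @param nodes N x 3 coordinates.
#' @param tets T x 4 node indices.
#' @return stretch factors in `[0, 1]`.
#' @export
tet_stretch_factors <- function(nodes, tets) {
  tets <- matrix(as.integer(tets), ncol = 4)
  p <- lapply(1:4, function(i) nodes[tets[, i], , drop = FALSE])
  vol <- abs(signed_vol6(p[[1]], p[[2]], p[[3]], p[[4]])) / 6
  atot <- triangle_areas(nodes, tets[, c(2, 3, 4), drop = FALSE]) +
          triangle_areas(nodes, tets[, c(1, 3, 4), drop = FALSE]) +
          triangle_areas(nodes, tets[, c(1, 2, 4), drop = FALSE]) +
          triangle_areas(nodes, tets[, c(1, 2, 3), drop = FALSE])
  rin <- ifelse(atot > 0, 3 * vol / atot, 0)
  elen2 <- function(a, b) rowSums((a - b)^2)
  lmax <- sqrt(pmax(
    elen2(p[[1]], p[[2]]), elen2(p[[1]], p[[3]]), elen2(p[[1]], p[[4]]),
    elen2(p[[2]], p[[3]]), elen2(p[[2]], p[[4]]), elen2(p[[3]], p[[4]])
  ))
  sf <- 2 * sqrt(6) * rin / lmax
  sf[!is.finite(sf)] <- 0
  sf
}
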