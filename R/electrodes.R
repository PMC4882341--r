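# ---------------------------------------------------------------------------
# Scalp electrode montages on the outer mesh surface
# ---------------------------------------------------------------------------

# Deterministic quasi-uniform directions: Fibonacci spiral lattice.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  ga <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- ga * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

#' Place a quasi-uniform scalp electrode montage
#'
#' Distributes `n` electrode centres on the outer surface of the mesh using a
#' deterministic Fibonacci-spiral lattice, then assigns to each electrode the
#' boundary facets whose centroid lies within `contact_radius` of its centre.
#' Facets eligible for more than one electrode go to the nearest centre, so
#' contact patches are pairwise disjoint.
#'
#' @param mesh a `tet_mesh`.
#' @param n number of electrodes (>= 2), e.g. 64, 128, 256.
#' @param contact_radius electrode contact radius, metres (default 4 mm, an
#'   8 mm diameter disc typical of dense-array EEG nets).
#' @param z_contact contact impedance per unit area, Ohm m^2 (default 2.01,
#'   see [contact_impedance_per_area()]).
#' @param labels optional electrode labels (default `E1..En`).
#' @return an `electrode_montage`: per electrode label, centre position (on
#'   the scalp surface), contact facet indices into `mesh$boundary_facets`,
#'   contact area and `z_l`.
#' @export
place_electrodes <- function(mesh, n, contact_radius = 0.004,
                             z_contact = 2.01, labels = NULL) {
  if (n < 2) stop("need at least 2 electrodes")
  if (z_contact <= 0) stop("contact impedance must be positive")
  if (is.null(labels)) labels <- paste0("E", seq_len(n))
  fc <- triangle_centroids(mesh$nodes, mesh$boundary_facets)
  fa <- triangle_areas(mesh$nodes, mesh$boundary_facets)
  R <- mean(sqrt(rowSums(fc^2)))
  centers <- fibonacci_sphere(n) * R

  # nearest-electrode assignment restricted to the contact radius
  d2 <- outer(rowSums(fc^2), rep(1, n)) +
        outer(rep(1, nrow(fc)), rowSums(centers^2)) -
        2 * fc %*% t(centers)
  nearest <- max.col(-d2, ties.method = "first")
  mind2 <- d2[cbind(seq_len(nrow(fc)), nearest)]
  assigned <- mind2 <= contact_radius^2
  facet_of <- ifelse(assigned, nearest, NA_integer_)

  contact <- split(which(assigned), facet_of[assigned])
  empty <- setdiff(seq_len(n), as.integer(names(contact)))
  if (length(empty)) {
    stop(sprintf("electrode %s captured no boundary facet; refine the mesh or enlarge the contact radius",
                 labels[empty[1]]))
  }
  contact <- contact[order(as.integer(names(contact)))]
  areas <- vapply(contact, function(ix) sum(fa[ix]), numeric(1))

  montage <- list(
    labels = labels,
    centers = centers,
    contact_facets = unname(contact),
    contact_area = unname(areas),
    z_l = rep(z_contact, n),
    contact_radius = contact_radius
  )
  class(montage) <- "electrode_montage"
  montage
}

#' @export
print.electrode_montage <- function(x, ...) {
  cat(sprintf("electrode_montage: %d electrodes, contact radius %.1f mm\n",
              length(x$labels), 1000 * x$contact_radius))
  cat(sprintf("  facets/electrode: %s, mean contact area %.1f mm^2, z_l %.3g Ohm m^2\n",
              paste(range(lengths(x$contact_facets)), collapse = "-"),
              1e6 * mean(x$contact_area), x$z_l[1]))
  invisible(x)
}

#' Convert a lumped contact resistance to contact impedance per unit area
#'
#' The complete electrode model parametrises the electrode-skin interface by
#' an impedance per unit contact area, `z_l` (Ohm m^2). A lumped contact
#' resistance `R` measured for an electrode of diameter `d` corresponds to
#' `z_l = R * pi * d^2 / 4`. For a typical 8 mm dense-array EEG electrode
#' with ~40 kOhm contact resistance this gives about 2.01 Ohm m^2.
#'
#' @param resistance lumped contact resistance, Ohm.
#' @param diameter electrode contact diameter, metres.
#' @return contact impedance per unit area, Ohm m^2.
#' @examples
#' contact_impedance_per_area(40e3, 0.008)
#' @export
contact_impedance_per_area <- function(resistance, diameter) {
  if (resistance <= 0 || diameter <= 0) stop("resistance and diameter must be positive")
  resistance * pi * diameter^2 / 4
}

#' Write / read an electrode montage table (TSV)
#'
#' Columns: `label`, `x`, `y`, `z` (centre, metres), `contact_radius_m`,
#' `z_ohm_m2`. Reading returns the table; facet assignment against a mesh is
#' redone with [electrodes_from_table()].
#'
#' @param montage an `electrode_montage`.
#' @param path file path.
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(
    label = montage$labels,
    x = montage$centers[, 1], y = montage$centers[, 2], z = montage$centers[, 3],
    contact_radius_m = montage$contact_radius,
    z_ohm_m2 = montage$z_l
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z", "contact_radius_m", "z_ohm_m2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("montage table missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Build an `electrode_montage` from a montage table and a mesh
#'
#' @param mesh a `tet_mesh`.
#' @param table data frame as returned by [read_montage()].
#' @export
electrodes_from_table <- function(mesh, table) {
  n <- nrow(table)
  centers <- as.matrix(table[, c("x", "y", "z")])
  fc <- triangle_centroids(mesh$nodes, mesh$boundary_facets)
  fa <- triangle_areas(mesh$nodes, mesh$boundary_facets)
  d2 <- outer(rowSums(fc^2), rep(1, n)) +
        outer(rep(1, nrow(fc)), rowSums(centers^2)) -
        2 * fc %*% t(centers)
  nearest <- max.col(-d2, ties.method = "first")
  mind2 <- d2[cbind(seq_len(nrow(fc)), nearest)]
  assigned <- mind2 <= table$contact_radius_m[nearest]^2
  contact <- split(which(assigned), nearest[assigned])
  empty <- setdiff(seq_len(n), as.integer(names(contact)))
  if (length(empty)) {
    stop(sprintf("electrode %s captured no boundary facet", table$label[empty[1]]))
  }
  contact <- contact[order(as.integer(names(contact)))]
  montage <- list(
    labels = table$label,
    centers = centers,
    contact_facets = unname(contact),
    contact_area = unname(vapply(contact, function(ix) sum(fa[ix]), numeric(1))),
    z_l = table$z_ohm_m2,
    contact_radius = table$contact_radius_m[1]
  )
  class(montage) <- "electrode_montage"
  montage
}

#' Area-average a surface potential over each electrode's contact patch
#'
#' A finite-contact electrode measures (approximately) the area average of
#' the scalp potential over its contact patch, not the potential at its
#' nominal centre. When comparing complete-electrode-model solutions with
#' closed-form point-wise solutions, evaluate the closed form at the
#' boundary-facet centroids and average with this function.
#'
#' @param mesh a `tet_mesh`.
#' @param montage an `electrode_montage` on the mesh.
#' @param values potential (or any quantity) at each boundary-facet centroid,
#'   length `nrow(mesh$boundary_facets)`.
#' @return per-electrode area-weighted averages (length L).
#' @export
patch_average_potentials <- function(mesh, montage, values) {
  fa <- triangle_areas(mesh$nodes, mesh$boundary_facets)
  vapply(montage$contact_facets, function(ix) sum(values[ix] * fa[ix]) / sum(fa[ix]),
         numeric(1))
}

#' Default isotropic tissue conductivities (S/m)
#'
#' Literature average values for the head tissues: gray matter 0.33 (used for
#' the whole brain shell), white matter 0.2, CSF 1.79, skull 0.008, scalp
#' 0.35, eyeballs 1.5.
#'
#' @param ... name = value overrides or additions.
#' @return named numeric vector, label -> conductivity in S/m.
#' @examples
#' default_conductivities()
#' default_conductivities(skull = 0.01)
#' @export
default_conductivities <- function(...) {
  sigma <- c(brain = 0.33, gm = 0.33, wm = 0.2, csf = 1.79,
             skull = 0.008, scalp = 0.35, eyes = 1.5)
  over <- c(...)
  if (length(over)) sigma[names(over)] <- over
  sigma
}
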