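# Analytic verification fixtures: a labeled sphere, a straight implanted
# duct, a solid cylinder, and an exactly-spherical concentric-shell mesh.
# These are first-class geometries used by the test suite and by convergence
# studies; they exercise the same meshing and solving paths as the cochlea.

#' Sphere geometry fixture
#'
#' A single-compartment ball, used for mesh-volume convergence checks.
#'
#' @param radius sphere radius (mm).
#' @return an object of class `sphere_geometry`.
#' @export
geometry_sphere <- function(radius = 1) {
  stopifnot(radius > 0)
  structure(
    list(radius = radius,
         fine_box = rbind(lo = rep(-radius, 3L), hi = rep(radius, 3L)),
         domain_radius = radius),
    class = "sphere_geometry"
  )
}

#' Straight implanted-duct geometry fixture
#'
#' A straight cylindrical "unrolled" cochlear duct along the x axis with a
#' coaxial insulating carrier, evenly pitched contact bands, a bone sheath
#' and a grounded far-end cap. Used for voltage-spread monotonicity and
#' mesh-convergence studies where the spiral geometry would only obscure the
#' physics.
#'
#' @param length duct length (mm).
#' @param duct_radius canal radius (mm).
#' @param carrier_radius carrier radius (mm).
#' @param n_contact_pairs number of contact bands.
#' @param pitch contact spacing (mm).
#' @param bone_margin bone sheath thickness (mm).
#' @return an object of class `duct_geometry`.
#' @export
geometry_straight_duct <- function(length = 16, duct_radius = 1,
                                   carrier_radius = 0.3,
                                   n_contact_pairs = 6L, pitch = 2,
                                   bone_margin = 0.8) {
  stopifnot(length > 0, duct_radius > carrier_radius, carrier_radius > 0)
  span <- (n_contact_pairs - 1L) * pitch
  if (span > length - 2)
    stop("geometry-infeasible: contact span exceeds the duct length")
  x0 <- (length - span) / 2
  structure(
    list(
      length = length, duct_radius = duct_radius,
      carrier_radius = carrier_radius,
      n_contact_pairs = as.integer(n_contact_pairs), pitch = pitch,
      bone_margin = bone_margin,
      contact_x = x0 + (seq_len(n_contact_pairs) - 1L) * pitch,
      outer_radius = duct_radius + bone_margin,
      fine_box = rbind(
        lo = c(-bone_margin, -(duct_radius + bone_margin), -(duct_radius + bone_margin)),
        hi = c(length + bone_margin, duct_radius + bone_margin, duct_radius + bone_margin)
      )
    ),
    class = "duct_geometry"
  )
}

#' Solid cylinder geometry fixture
#'
#' A homogeneous cylinder of arbitrary axis direction labeled as a single
#' compartment (default: auditory nerve). Used as the straight-tube fixture
#' for fiber-tracing geodesic checks.
#'
#' @param radius cylinder radius (mm).
#' @param length cylinder length (mm).
#' @param axis direction vector of the cylinder axis.
#' @param origin centre of the basal end cap.
#' @param compartment compartment name for the cylinder elements.
#' @return an object of class `cylinder_geometry`.
#' @export
geometry_cylinder <- function(radius = 0.5, length = 10,
                              axis = c(1, 0, 0), origin = c(0, 0, 0),
                              compartment = "auditory_nerve") {
  stopifnot(radius > 0, length > 0)
  u <- axis / sqrt(sum(axis^2))
  ends <- rbind(origin, origin + length * u)
  lo <- pmin(ends[1L, ], ends[2L, ]) - radius
  hi <- pmax(ends[1L, ], ends[2L, ]) + radius
  structure(
    list(radius = radius, length = length, axis = u, origin = origin,
         compartment = compartment,
         fine_box = rbind(lo = lo, hi = hi)),
    class = "cylinder_geometry"
  )
}

#' @keywords internal
label_points_sphere <- function(geom, pts) {
  as.integer(sqrt(rowSums(pts^2)) <= geom$radius)
}

#' @keywords internal
label_points_duct <- function(geom, pts) {
  n <- nrow(pts)
  lab <- integer(n)
  rr <- sqrt(pts[, 2L]^2 + pts[, 3L]^2)
  x <- pts[, 1L]
  in_block <- x >= -geom$bone_margin & x <= geom$length + geom$bone_margin &
    rr <= geom$outer_radius
  lab[in_block] <- COMPARTMENTS[["bony_labyrinth"]]
  in_canal <- in_block & rr <= geom$duct_radius & x >= 0 & x <= geom$length
  lab[in_canal] <- COMPARTMENTS[["cochlear_canal"]]
  in_carrier <- in_canal & rr <= geom$carrier_radius &
    x >= 1 & x <= geom$length - 1
  lab[in_carrier] <- -1L
  lab
}

#' @keywords internal
label_points_cylinder <- function(geom, pts) {
  d <- sweep(pts, 2L, geom$origin)
  t <- drop(d %*% geom$axis)
  perp2 <- rowSums(d^2) - t^2
  ok <- t >= 0 & t <= geom$length & perp2 <= geom$radius^2
  as.integer(ok) * COMPARTMENTS[[geom$compartment]]
}

# Contacts are bands on the carrier surface; the whole outer sheath surface
# is grounded, so the duct behaves as a leaky cable and the potential decays
# with distance from the stimulating contact in both directions.
#' @keywords internal
classify_facets_duct <- function(geom, centroids, h_local) {
  patch <- rep(NA_character_, nrow(centroids))
  rr <- sqrt(centroids[, 2L]^2 + centroids[, 3L]^2)
  x <- centroids[, 1L]
  on_carrier <- rr <= geom$carrier_radius + 1.1 * h_local &
    x > 0.5 & x < geom$length - 0.5
  # fixed band width so the electrode geometry is identical across
  # refinement levels
  half <- max(0.4, 0.8 * h_local)
  for (k in seq_len(geom$n_contact_pairs)) {
    sel <- on_carrier & abs(x - geom$contact_x[k]) <= half
    patch[sel] <- paste0("contact_", k)
  }
  patch[!on_carrier &
          (rr >= geom$outer_radius - 0.75 * h_local |
           x <= -geom$bone_margin + 0.75 * h_local |
           x >= geom$length + geom$bone_margin - 0.75 * h_local)] <- "ground"
  patch
}
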