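# Parametric synthetic cochlea.
#
# The geometry is an analytic tapered spiral, not an anatomical replica: a
# spiral lamina edge curve of prescribed total arclength, a tapering cochlear
# duct (the two scalae merged into one canal), a central modiolar nerve trunk,
# a spiral nerve ramp connecting the lamina to the trunk, an insulating
# electrode carrier threaded along the duct with 12 merged contact pairs, and
# concentric brain/skull/scalp shells that carry the return current to an
# extracochlear ground patch. With `microstructures = TRUE` (the detailed,
# "ORI"-style variant) the ramp is replaced by discrete tubular channels
# through the modiolar bone -- the porous Rosenthal's-canal microstructure --
# so nerve fibers must thread them; with `FALSE` ("SIM"-style) the whole
# modiolar envelope is solid nerve. Both variants are labeled from the same
# deterministic implicit functions, so they are identical outside the
# modiolar nerve envelope.

COMPARTMENTS <- c(
  bony_labyrinth = 1L, cochlear_canal = 2L, auditory_nerve = 3L,
  brain = 4L, skull = 5L, scalp = 6L
)

#' Cochlea geometry parameters
#'
#' Parameters of the synthetic cochlear geometry. Lengths in mm.
#'
#' @param n_turns number of spiral turns (default 2.5).
#' @param lamina_curve_length total arclength of the outer edge of the osseous
#'   spiral lamina (default 25.003 mm); the spiral is scaled to hit it.
#' @param duct_radius_base,duct_radius_apex radius of the cochlear canal at
#'   base and apex; must taper monotonically.
#' @param modiolus_radius radius of the central nerve trunk.
#' @param microstructures logical; `TRUE` builds the detailed variant with
#'   discrete modiolar channels ("ORI"), `FALSE` the simplified solid nerve
#'   ("SIM").
#' @param n_channels number of Rosenthal's-canal channels when
#'   `microstructures = TRUE`.
#' @param channel_radius radius of each channel (mm).
#' @param head_shell_radii named radii (mm) of the concentric brain, skull and
#'   scalp shells surrounding the cochlear block.
#' @param taper fractional reduction of the lamina spiral radius from base to
#'   apex (dimensionless, in (0, 1)).
#' @param rise axial rise of the spiral relative to its basal radius.
#' @param lamina_sleeve_radius radius of the nerve sleeve that follows the
#'   lamina edge (mm); also the half-thickness of the simplified nerve ramp.
#' @param spoke_drop axial drop from a lamina point to its modiolar entry
#'   point (mm).
#' @param nerve_base_z z-coordinate (mm) of the plane where the truncated
#'   nerve trunk ends.
#' @param bone_margin thickness (mm) of otic bone wrapped around the canal.
#' @return an object of class `cochlea_params`.
#' @export
cochlea_params <- function(n_turns = 2.5,
                           lamina_curve_length = 25.003,
                           duct_radius_base = 0.9,
                           duct_radius_apex = 0.45,
                           modiolus_radius = 0.65,
                           microstructures = TRUE,
                           n_channels = 10L,
                           channel_radius = 0.3,
                           head_shell_radii = c(brain = 9, skull = 11, scalp = 13),
                           taper = 0.72,
                           rise = 1.2,
                           lamina_sleeve_radius = 0.3,
                           spoke_drop = 0.5,
                           nerve_base_z = -2.5,
                           bone_margin = 0.6) {
  stopifnot(is.numeric(lamina_curve_length), length(lamina_curve_length) == 1L)
  if (lamina_curve_length <= 0) stop("lamina_curve_length must be > 0")
  if (n_turns <= 0) stop("n_turns must be > 0")
  if (duct_radius_base <= 0 || duct_radius_apex <= 0)
    stop("duct radii must be > 0")
  if (duct_radius_apex > duct_radius_base)
    stop("duct radii must taper monotonically from base to apex")
  if (modiolus_radius <= 0) stop("modiolus_radius must be > 0")
  if (taper <= 0 || taper >= 1) stop("taper must be in (0, 1)")
  if (microstructures) {
    if (n_channels < 1L) stop("n_channels must be >= 1 when microstructures = TRUE")
    if (channel_radius <= 0) stop("channel_radius must be > 0")
  }
  r <- head_shell_radii
  if (length(r) != 3L || any(diff(unname(r)) <= 0))
    stop("head_shell_radii must be three strictly increasing radii (brain, skull, scalp)")
  structure(
    list(
      n_turns = n_turns, lamina_curve_length = lamina_curve_length,
      duct_radius_base = duct_radius_base, duct_radius_apex = duct_radius_apex,
      modiolus_radius = modiolus_radius, microstructures = isTRUE(microstructures),
      n_channels = as.integer(n_channels), channel_radius = channel_radius,
      head_shell_radii = c(brain = unname(r[1L]), skull = unname(r[2L]),
                           scalp = unname(r[3L])),
      taper = taper, rise = rise,
      lamina_sleeve_radius = lamina_sleeve_radius, spoke_drop = spoke_drop,
      nerve_base_z = nerve_base_z, bone_margin = bone_margin
    ),
    class = "cochlea_params"
  )
}

#' Electrode array parameters
#'
#' Twelve-contact-pair lateral-wall array threaded along the cochlear duct.
#' Each physical contact pair is merged into one electrical patch. Lengths in
#' mm, angles in degrees of insertion depth.
#'
#' @param n_contact_pairs number of contact pairs (default 12).
#' @param contact_radius contact radius (default 0.18 mm).
#' @param pitch centre-to-centre contact spacing along the carrier
#'   (default 2.4 mm).
#' @param insertion_angle_end angular insertion depth of the carrier tip
#'   (default 720 degrees).
#' @param translocation_angle angle at which the carrier crosses from the
#'   scala-tympani side of the duct to the scala-vestibuli side (default 270).
#' @param ground_radius radius (mm) of the extracochlear ground patch on the
#'   outer head surface (default 10).
#' @param carrier_radius radius of the insulating silicone carrier (mm).
#' @param apical_margin distance (mm) from the carrier tip to the most apical
#'   contact centre.
#' @return an object of class `electrode_params`.
#' @export
electrode_params <- function(n_contact_pairs = 12L,
                             contact_radius = 0.18,
                             pitch = 2.4,
                             insertion_angle_end = 720,
                             translocation_angle = 270,
                             ground_radius = 10,
                             carrier_radius = 0.3,
                             apical_margin = 0.8) {
  if (n_contact_pairs < 2L) stop("n_contact_pairs must be >= 2")
  if (pitch <= 2 * contact_radius)
    stop("pitch must exceed twice the contact radius")
  if (insertion_angle_end <= translocation_angle)
    stop("insertion_angle_end must exceed translocation_angle")
  if (ground_radius <= 0 || carrier_radius <= 0)
    stop("radii must be > 0")
  structure(
    list(
      n_contact_pairs = as.integer(n_contact_pairs),
      contact_radius = contact_radius, pitch = pitch,
      insertion_angle_end = insertion_angle_end,
      translocation_angle = translocation_angle,
      ground_radius = ground_radius, carrier_radius = carrier_radius,
      apical_margin = apical_margin
    ),
    class = "electrode_params"
  )
}

# sampling step used for all implicit-geometry point clouds (mm)
.cloud_step <- 0.05

#' Build the labeled synthetic cochlea geometry
#'
#' Constructs the implicit labeled geometry: spiral curves, electrode carrier
#' trajectory with contact centres, the modiolar nerve envelope with or
#' without channel microstructures, and the surrounding head shells. The
#' result carries a deterministic point-labeling function used by
#' [mesh_geometry()] and a boundary-patch classifier; it is purely analytic
#' (no randomness).
#'
#' @param params a [cochlea_params()] object.
#' @param electrode an [electrode_params()] object.
#' @return an object of class `cochlea_geometry`.
#' @export
build_cochlea <- function(params = cochlea_params(),
                          electrode = electrode_params()) {
  stopifnot(inherits(params, "cochlea_params"),
            inherits(electrode, "electrode_params"))
  theta_max <- params$n_turns * 2 * pi
  n_theta <- 2000L
  theta <- seq(0, theta_max, length.out = n_theta)
  frac <- theta / theta_max

  # unit-shape lamina spiral, then uniform scale to the requested arclength
  rho_u <- 1 - params$taper * frac
  z_u <- params$rise * frac
  unit_pts <- cbind(rho_u * cos(theta), rho_u * sin(theta), z_u)
  L1 <- polyline_arclength(unit_pts)
  scale <- params$lamina_curve_length / L1[length(L1)]
  rho <- scale * rho_u
  zz <- scale * z_u
  lamina <- cbind(rho * cos(theta), rho * sin(theta), zz)
  s_lamina <- polyline_arclength(lamina)

  # cochlear duct: tube of tapering radius around a centerline offset
  # radially outward from the lamina edge
  a_duct <- params$duct_radius_base +
    (params$duct_radius_apex - params$duct_radius_base) * frac
  duct_center <- cbind((rho + a_duct) * cos(theta), (rho + a_duct) * sin(theta), zz)

  # carrier centerline: follows the duct to the insertion end, offset below
  # the duct centre before the translocation angle and above it after
  theta_end <- electrode$insertion_angle_end * pi / 180
  theta_tr <- electrode$translocation_angle * pi / 180
  if (theta_end > theta_max)
    stop("geometry-infeasible: insertion angle exceeds the spiral extent")
  in_carrier <- theta <= theta_end
  off_frac <- 0.3 * tanh((theta[in_carrier] - theta_tr) / (10 * pi / 180))
  carrier <- duct_center[in_carrier, , drop = FALSE]
  carrier[, 3L] <- carrier[, 3L] + off_frac * a_duct[in_carrier]
  clearance <- a_duct[in_carrier] - abs(off_frac) * a_duct[in_carrier] -
    electrode$carrier_radius
  if (any(clearance < 0))
    stop("geometry-infeasible: carrier wider than the duct along the insertion")
  s_carrier <- polyline_arclength(carrier)
  s_car_end <- s_carrier[length(s_carrier)]

  # contact centres along the carrier, most apical near the tip
  npair <- electrode$n_contact_pairs
  s_contacts <- s_car_end - electrode$apical_margin -
    (npair - seq_len(npair)) * electrode$pitch
  if (s_contacts[1L] < 0.5)
    stop("geometry-infeasible: contact span exceeds the inserted carrier length")
  contact_centers <- polyline_interp(carrier, s_contacts)
  # lamina-arclength position of each contact (nearest lamina vertex)
  near <- nearest_bruteforce(contact_centers, lamina)
  contact_lamina_s <- s_lamina[near$index]

  # modiolar trunk and nerve ramp
  trunk_r <- params$modiolus_radius
  spoke_in <- cbind(0, 0, pmax(zz - params$spoke_drop, params$nerve_base_z))
  trunk_z_hi <- max(spoke_in[, 3L]) + 0.1
  trunk_z_lo <- params$nerve_base_z

  # point clouds for binned implicit labeling
  lamina_cloud <- resample_polyline(lamina, .cloud_step)
  duct_cloud <- resample_polyline(duct_center, .cloud_step)
  duct_cloud_a <- stats::approx(seq_len(n_theta), a_duct,
                                xout = seq(1, n_theta, length.out = nrow(duct_cloud)))$y
  carrier_cloud <- resample_polyline(carrier, .cloud_step)
  # ramp surface cloud: segments from lamina points to their modiolar entries
  n_ramp_theta <- 500L
  ramp_idx <- round(seq(1L, n_theta, length.out = n_ramp_theta))
  tpar <- seq(0, 1, length.out = 25L)
  ramp_cloud <- do.call(rbind, lapply(tpar, function(t) {
    (1 - t) * lamina[ramp_idx, , drop = FALSE] +
      t * spoke_in[ramp_idx, , drop = FALSE]
  }))
  # channel tubes at evenly spaced angles
  channel_clouds <- NULL
  if (params$microstructures) {
    ch_frac <- (seq_len(params$n_channels) - 0.5) / params$n_channels
    ch_idx <- pmax(1L, pmin(n_theta, round(ch_frac * (n_theta - 1L)) + 1L))
    channel_clouds <- do.call(rbind, lapply(ch_idx, function(i) {
      seg <- rbind(lamina[i, ], spoke_in[i, ])
      resample_polyline(seg, .cloud_step)
    }))
  }

  shells <- params$head_shell_radii
  bone_r <- max(rho + 2 * a_duct) + params$bone_margin
  bone_z <- c(params$nerve_base_z - params$bone_margin,
              max(zz + a_duct) + params$bone_margin)
  if (bone_r >= shells["brain"])
    stop("geometry-infeasible: head shells too small for the cochlear block")

  geom <- structure(
    list(
      params = params, electrode = electrode,
      lamina_curve = lamina, lamina_s = s_lamina,
      duct_center = duct_center, duct_radius = a_duct,
      carrier_curve = carrier, carrier_s = s_carrier,
      contact_centers = contact_centers, contact_s = s_contacts,
      contact_lamina_s = contact_lamina_s,
      trunk_radius = trunk_r, trunk_z = c(trunk_z_lo, trunk_z_hi),
      nerve_base_plane = params$nerve_base_z,
      bone_r = bone_r, bone_z = bone_z,
      ground_anchor = c(unname(shells["scalp"]), 0, 0),
      clouds = list(
        lamina = lamina_cloud, duct = duct_cloud, duct_a = duct_cloud_a,
        carrier = carrier_cloud, ramp = ramp_cloud, channels = channel_clouds
      ),
      fine_box = rbind(
        lo = c(-bone_r, -bone_r, bone_z[1L]),
        hi = c(bone_r, bone_r, bone_z[2L])
      ),
      domain_radius = unname(shells["scalp"])
    ),
    class = "cochlea_geometry"
  )
  geom
}

#' Measured arclength of the lamina edge curve
#' @param geom a `cochlea_geometry`.
#' @return length in mm.
#' @export
lamina_curve_length <- function(geom) {
  stopifnot(inherits(geom, "cochlea_geometry"))
  geom$lamina_s[length(geom$lamina_s)]
}

# Label an n x 3 point matrix with compartment ids. 0 = outside the domain,
# -1 = inside the silicone carrier (excluded from conduction as a void).
#' @keywords internal
label_points_cochlea <- function(geom, pts) {
  p <- geom$params
  shells <- p$head_shell_radii
  n <- nrow(pts)
  lab <- integer(n)
  R <- sqrt(rowSums(pts^2))
  lab[R <= shells["scalp"]] <- COMPARTMENTS[["scalp"]]
  lab[R <= shells["skull"]] <- COMPARTMENTS[["skull"]]
  lab[R <= shells["brain"]] <- COMPARTMENTS[["brain"]]

  rr <- sqrt(pts[, 1L]^2 + pts[, 2L]^2)
  in_bone <- rr <= geom$bone_r & pts[, 3L] >= geom$bone_z[1L] &
    pts[, 3L] <= geom$bone_z[2L]
  lab[in_bone] <- COMPARTMENTS[["bony_labyrinth"]]

  # only points inside the otic block can belong to finer structures
  cand <- which(in_bone)
  if (length(cand)) {
    q <- pts[cand, , drop = FALSE]
    w <- p$lamina_sleeve_radius
    in_trunk <- sqrt(q[, 1L]^2 + q[, 2L]^2) <= geom$trunk_radius &
      q[, 3L] >= geom$trunk_z[1L] & q[, 3L] <= geom$trunk_z[2L]
    d_ramp <- nearest_within(q, geom$clouds$ramp, w)$dist
    envelope <- in_trunk | d_ramp <= w
    if (p$microstructures) {
      d_sleeve <- nearest_within(q, geom$clouds$lamina, w)$dist
      d_chan <- nearest_within(q, geom$clouds$channels,
                               p$channel_radius)$dist
      nerve <- in_trunk | d_sleeve <= w |
        (d_chan <= p$channel_radius & envelope)
    } else {
      nerve <- envelope
    }
    lab[cand[nerve]] <- COMPARTMENTS[["auditory_nerve"]]

    # canal overrides nerve (the sleeve is the half-tube medial to the duct)
    maxa <- max(geom$duct_radius)
    nd <- nearest_within(q, geom$clouds$duct, maxa + 0.01)
    in_canal <- !is.na(nd$index) &
      nd$dist <= geom$clouds$duct_a[ifelse(is.na(nd$index), 1L, nd$index)]
    lab[cand[in_canal]] <- COMPARTMENTS[["cochlear_canal"]]

    dc <- nearest_within(q, geom$clouds$carrier, geom$electrode$carrier_radius)$dist
    lab[cand[dc <= geom$electrode$carrier_radius]] <- -1L
  }
  lab
}

# Classify boundary facets of a meshed cochlea into named patches.
# Facets near the carrier surface become contact bands; outer-scalp facets
# within the ground radius of the ground anchor become the ground patch.
#' @keywords internal
classify_facets_cochlea <- function(geom, centroids, h_fine, h_facet) {
  el <- geom$electrode
  patch <- rep(NA_character_, nrow(centroids))
  h_local <- h_fine

  rcap <- el$carrier_radius + 1.1 * h_local
  nc <- nearest_within(centroids, geom$clouds$carrier, rcap)
  on_carrier <- !is.na(nc$index)
  if (any(on_carrier)) {
    s_cloud <- polyline_arclength(geom$clouds$carrier)
    s_fac <- s_cloud[nc$index[on_carrier]]
    half <- max(el$contact_radius, 0.8 * h_local)
    for (k in seq_len(el$n_contact_pairs)) {
      sel <- abs(s_fac - geom$contact_s[k]) <= half
      patch[which(on_carrier)[sel]] <- paste0("contact_", k)
    }
  }

  R <- sqrt(rowSums(centroids^2))
  outer_surf <- !on_carrier & R >= geom$domain_radius - 1.5 * h_facet
  dg <- sqrt(rowSums((centroids - matrix(geom$ground_anchor,
                                         nrow(centroids), 3, byrow = TRUE))^2))
  patch[outer_surf & dg <= el$ground_radius] <- "ground"
  patch
}
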