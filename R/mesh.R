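# Labeled tetrahedral volume meshing.
#
# Meshes are built on a graded tensor-product hexahedral lattice (uniform
# spacing inside the geometry's fine box, geometrically coarsening outside)
# split into six tetrahedra per hexahedron along a consistent diagonal
# (Freudenthal/Kuhn decomposition, conforming across cells). Each tetrahedron
# is labeled by evaluating the geometry's implicit labeling function at its
# centroid; tetrahedra labeled as outside the domain or inside the insulating
# carrier are removed, so the carrier is a true void in the conduction
# domain. The structured lattice gives O(1) point location for field
# sampling and makes the detailed/simplified labeling toggle act on an
# identical element set.

#' @keywords internal
graded_breaks <- function(fine_lo, fine_hi, h, dom_lo, dom_hi, growth = 1.6) {
  n <- max(1L, ceiling((fine_hi - fine_lo) / h))
  core <- seq(fine_lo, fine_hi, length.out = n + 1L)
  lo <- fine_lo
  low <- numeric(0)
  step <- h
  while (lo > dom_lo + 1e-9) {
    step <- step * growth
    lo <- max(dom_lo, lo - step)
    low <- c(lo, low)
  }
  hi <- fine_hi
  high <- numeric(0)
  step <- h
  while (hi < dom_hi - 1e-9) {
    step <- step * growth
    hi <- min(dom_hi, hi + step)
    high <- c(high, hi)
  }
  c(low, core, high)
}

# 6-tet Kuhn split of a hex; local corner order c000 c100 c010 c110 c001 c101
# c011 c111, main diagonal c000-c111.
.kuhn_tets <- matrix(c(
  1L, 2L, 4L, 8L,
  1L, 2L, 6L, 8L,
  1L, 3L, 4L, 8L,
  1L, 3L, 7L, 8L,
  1L, 5L, 6L, 8L,
  1L, 5L, 7L, 8L
), ncol = 4L, byrow = TRUE)

#' @keywords internal
build_lattice_mesh <- function(bx, by, bz, label_fun, compartments,
                               classify_fun = NULL, h_fine = NULL,
                               prefilter = NULL) {
  nx <- length(bx); ny <- length(by); nz <- length(bz)
  ncx <- nx - 1L; ncy <- ny - 1L; ncz <- nz - 1L
  idx <- function(i, j, k) i + nx * (j - 1L + ny * (k - 1L))

  cells <- expand.grid(i = seq_len(ncx), j = seq_len(ncy), k = seq_len(ncz))
  if (!is.null(prefilter)) {
    centers <- cbind((bx[cells$i] + bx[cells$i + 1L]) / 2,
                     (by[cells$j] + by[cells$j + 1L]) / 2,
                     (bz[cells$k] + bz[cells$k + 1L]) / 2)
    cells <- cells[prefilter(centers), , drop = FALSE]
  }
  ncell <- nrow(cells)
  if (ncell == 0L) stop("mesh error: no cells inside the domain")
  corner <- cbind(
    idx(cells$i,      cells$j,      cells$k),
    idx(cells$i + 1L, cells$j,      cells$k),
    idx(cells$i,      cells$j + 1L, cells$k),
    idx(cells$i + 1L, cells$j + 1L, cells$k),
    idx(cells$i,      cells$j,      cells$k + 1L),
    idx(cells$i + 1L, cells$j,      cells$k + 1L),
    idx(cells$i,      cells$j + 1L, cells$k + 1L),
    idx(cells$i + 1L, cells$j + 1L, cells$k + 1L)
  )
  tets <- do.call(rbind, lapply(seq_len(6L), function(t) {
    corner[, .kuhn_tets[t, ], drop = FALSE]
  }))
  hexid <- rep(cells$i + ncx * (cells$j - 1L + ncy * (cells$k - 1L)), 6L)
  kuhn <- rep(seq_len(6L), each = ncell)

  # global node coordinates (built lazily per used node)
  node_xyz <- function(ids) {
    ids0 <- ids - 1L
    i <- ids0 %% nx
    j <- (ids0 %/% nx) %% ny
    k <- ids0 %/% (nx * ny)
    cbind(bx[i + 1L], by[j + 1L], bz[k + 1L])
  }

  centroids <- (node_xyz(tets[, 1L]) + node_xyz(tets[, 2L]) +
                node_xyz(tets[, 3L]) + node_xyz(tets[, 4L])) / 4
  lab <- label_fun(centroids)
  keep <- lab > 0L
  tets <- tets[keep, , drop = FALSE]
  lab <- lab[keep]
  hexid <- hexid[keep]
  kuhn <- kuhn[keep]
  if (nrow(tets) == 0L) stop("mesh error: no elements labeled inside the domain")

  used <- sort(unique(as.vector(tets)))
  remap <- integer(nx * ny * nz)
  remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4L)
  nodes <- node_xyz(used)

  mesh <- new_volume_mesh(nodes, tets, lab, compartments,
                          grid = list(bx = bx, by = by, bz = bz,
                                      hex_of_tet = hexid, kuhn_of_tet = kuhn,
                                      dims = c(ncx, ncy, ncz)),
                          h = h_fine)
  if (!is.null(classify_fun)) mesh <- assign_patches(mesh, classify_fun)
  mesh
}

#' @keywords internal
new_volume_mesh <- function(nodes, tets, label, compartments,
                            grid = NULL, h = NULL) {
  vol <- tet_volumes_signed(nodes, tets)
  flip <- vol < 0
  if (any(flip)) tets[flip, c(3L, 4L)] <- tets[flip, c(4L, 3L)]
  if (any(abs(vol) < .Machine$double.eps))
    stop("mesh error: degenerate (zero-volume) tetrahedra")
  structure(
    list(nodes = nodes, tets = tets, label = as.integer(label),
         compartments = compartments, patches = list(), patch_nodes = list(),
         grid = grid, h = h, cache = new.env(parent = emptyenv())),
    class = "volume_mesh"
  )
}

#' @keywords internal
tet_volumes_signed <- function(nodes, tets) {
  a <- nodes[tets[, 2L], , drop = FALSE] - nodes[tets[, 1L], , drop = FALSE]
  b <- nodes[tets[, 3L], , drop = FALSE] - nodes[tets[, 1L], , drop = FALSE]
  d <- nodes[tets[, 4L], , drop = FALSE] - nodes[tets[, 1L], , drop = FALSE]
  (a[, 1L] * (b[, 2L] * d[, 3L] - b[, 3L] * d[, 2L]) +
   a[, 2L] * (b[, 3L] * d[, 1L] - b[, 1L] * d[, 3L]) +
   a[, 3L] * (b[, 1L] * d[, 2L] - b[, 2L] * d[, 1L])) / 6
}

#' Total mesh volume, optionally of one compartment
#'
#' @param mesh a `volume_mesh`.
#' @param compartment optional compartment name.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh, compartment = NULL) {
  v <- abs(tet_volumes_signed(mesh$nodes, mesh$tets))
  if (!is.null(compartment)) {
    id <- compartment_id(mesh, compartment)
    v <- v[mesh$label == id]
  }
  sum(v)
}

#' @keywords internal
compartment_id <- function(mesh, compartment) {
  if (is.numeric(compartment)) return(as.integer(compartment))
  if (!compartment %in% names(mesh$compartments))
    stop("unknown compartment: ", compartment)
  mesh$compartments[[compartment]]
}

# boundary facets: faces belonging to exactly one tetrahedron
#' @keywords internal
boundary_facets <- function(mesh) {
  if (!is.null(mesh$cache$boundary)) return(mesh$cache$boundary)
  tt <- mesh$tets
  faces <- rbind(tt[, c(1L, 2L, 3L)], tt[, c(1L, 2L, 4L)],
                 tt[, c(1L, 3L, 4L)], tt[, c(2L, 3L, 4L)])
  a <- pmin(faces[, 1L], faces[, 2L], faces[, 3L])
  c3 <- pmax(faces[, 1L], faces[, 2L], faces[, 3L])
  b <- faces[, 1L] + faces[, 2L] + faces[, 3L] - a - c3
  n <- nrow(mesh$nodes)
  key <- a + as.numeric(n) * (b + as.numeric(n) * c3)
  ord <- order(key)
  ks <- key[ord]
  first <- !duplicated(ks)
  cnt <- tabulate(cumsum(first), sum(first))
  once <- which(first)[cnt == 1L]
  bd <- faces[ord[once], , drop = FALSE]
  mesh$cache$boundary <- bd
  bd
}

#' @keywords internal
assign_patches <- function(mesh, classify_fun) {
  bd <- boundary_facets(mesh)
  cen <- (mesh$nodes[bd[, 1L], , drop = FALSE] +
          mesh$nodes[bd[, 2L], , drop = FALSE] +
          mesh$nodes[bd[, 3L], , drop = FALSE]) / 3
  e1 <- sqrt(rowSums((mesh$nodes[bd[, 2L], , drop = FALSE] -
                      mesh$nodes[bd[, 1L], , drop = FALSE])^2))
  e2 <- sqrt(rowSums((mesh$nodes[bd[, 3L], , drop = FALSE] -
                      mesh$nodes[bd[, 2L], , drop = FALSE])^2))
  h_facet <- pmax(e1, e2)
  pn <- classify_fun(cen, h_facet)
  ok <- !is.na(pn)
  mesh$patches <- lapply(split(which(ok), pn[ok]), function(rows) {
    bd[rows, , drop = FALSE]
  })
  mesh$patch_nodes <- lapply(mesh$patches, function(f) sort(unique(as.vector(f))))
  empty <- vapply(mesh$patch_nodes, length, 1L) == 0L
  if (any(empty)) stop("mesh error: empty boundary patch ",
                       paste(names(which(empty)), collapse = ", "))
  mesh
}

#' Mesh a labeled geometry into a tetrahedral volume mesh
#'
#' @param geom a geometry object (`cochlea_geometry`, `sphere_geometry`,
#'   `duct_geometry` or `cylinder_geometry`).
#' @param target_edge_length lattice spacing (mm) inside the fine region.
#' @param growth geometric grading factor outside the fine region.
#' @param ... passed to methods.
#' @return a `volume_mesh` with per-element compartment labels and named
#'   boundary patches where the geometry defines them.
#' @export
mesh_geometry <- function(geom, target_edge_length, ...) {
  if (target_edge_length <= 0) stop("target_edge_length must be > 0")
  UseMethod("mesh_geometry")
}

#' @rdname mesh_geometry
#' @export
mesh_geometry.cochlea_geometry <- function(geom, target_edge_length = 0.3,
                                           growth = 1.6, ...) {
  h <- target_edge_length
  if (geom$params$microstructures && h > geom$params$channel_radius)
    h <- geom$params$channel_radius  # resolve channels by >= 2 elements/diameter
  R <- geom$domain_radius
  fb <- geom$fine_box
  bx <- graded_breaks(fb["lo", 1L], fb["hi", 1L], h, -R, R, growth)
  by <- graded_breaks(fb["lo", 2L], fb["hi", 2L], h, -R, R, growth)
  bz <- graded_breaks(fb["lo", 3L], fb["hi", 3L], h, -R, R, growth)
  pre <- function(centers) sqrt(rowSums(centers^2)) <= R * 1.05
  build_lattice_mesh(
    bx, by, bz,
    label_fun = function(p) label_points_cochlea(geom, p),
    compartments = COMPARTMENTS,
    classify_fun = function(cen, hf) classify_facets_cochlea(geom, cen, h, hf),
    h_fine = h, prefilter = pre
  )
}

#' @rdname mesh_geometry
#' @export
mesh_geometry.sphere_geometry <- function(geom, target_edge_length, ...) {
  h <- target_edge_length
  r <- geom$radius
  b <- graded_breaks(-r - h / 2, r + h / 2, h, -r - h / 2, r + h / 2)
  build_lattice_mesh(
    b, b, b,
    label_fun = function(p) label_points_sphere(geom, p),
    compartments = c(medium = 1L),
    h_fine = h
  )
}

#' @rdname mesh_geometry
#' @export
mesh_geometry.duct_geometry <- function(geom, target_edge_length, ...) {
  h <- target_edge_length
  fb <- geom$fine_box
  bx <- graded_breaks(fb["lo", 1L], fb["hi", 1L], h, fb["lo", 1L], fb["hi", 1L])
  by <- graded_breaks(fb["lo", 2L], fb["hi", 2L], h, fb["lo", 2L], fb["hi", 2L])
  bz <- graded_breaks(fb["lo", 3L], fb["hi", 3L], h, fb["lo", 3L], fb["hi", 3L])
  build_lattice_mesh(
    bx, by, bz,
    label_fun = function(p) label_points_duct(geom, p),
    compartments = COMPARTMENTS,
    classify_fun = function(cen, hf) classify_facets_duct(geom, cen, h),
    h_fine = h
  )
}

#' @rdname mesh_geometry
#' @export
mesh_geometry.cylinder_geometry <- function(geom, target_edge_length, ...) {
  h <- target_edge_length
  fb <- geom$fine_box
  bx <- graded_breaks(fb["lo", 1L], fb["hi", 1L], h, fb["lo", 1L], fb["hi", 1L])
  by <- graded_breaks(fb["lo", 2L], fb["hi", 2L], h, fb["lo", 2L], fb["hi", 2L])
  bz <- graded_breaks(fb["lo", 3L], fb["hi", 3L], h, fb["lo", 3L], fb["hi", 3L])
  build_lattice_mesh(
    bx, by, bz,
    label_fun = function(p) label_points_cylinder(geom, p),
    compartments = COMPARTMENTS,
    h_fine = h
  )
}

#' Series of successively refined meshes of one geometry
#'
#' Meshes the same geometry at geometrically decreasing lattice spacings,
#' for discretization-convergence studies.
#'
#' @param geom a geometry object.
#' @param levels number of refinement levels (>= 2).
#' @param base_edge_length spacing of the coarsest mesh (mm).
#' @param ratio spacing reduction per level.
#' @return list of `volume_mesh`, element counts strictly increasing.
#' @export
refinement_series <- function(geom, levels, base_edge_length = 0.3,
                              ratio = 1.4) {
  if (levels < 2L) stop("levels must be >= 2")
  hs <- base_edge_length / ratio^(seq_len(levels) - 1L)
  meshes <- lapply(hs, function(h) mesh_geometry(geom, h))
  counts <- vapply(meshes, function(m) nrow(m$tets), 1L)
  if (any(diff(counts) <= 0L))
    stop("mesh error: refinement did not increase element count")
  meshes
}

#' Concentric-sphere shell mesh with exactly spherical boundaries
#'
#' Builds a tetrahedral mesh of the domain between two concentric spheres by
#' mapping a cube lattice radially ("spider-web" construction), so that both
#' the inner (source) and outer (ground) boundaries are exactly spherical.
#' Used as the analytic point-source verification fixture: with current I
#' injected at the inner sphere and the outer sphere grounded, the exact
#' potential is V(r) = I/(4 pi sigma) (1/r - 1/R).
#'
#' @param r_inner inner (source) radius (mm).
#' @param r_outer outer (ground) radius (mm).
#' @param n cells per half-axis of the generating cube lattice.
#' @return a `volume_mesh` with one compartment `medium` and patches
#'   `source` and `ground`.
#' @export
mesh_concentric_spheres <- function(r_inner = 0.5, r_outer = 5, n = 12L) {
  stopifnot(r_inner > 0, r_outer > r_inner, n >= 4L)
  k0 <- max(1L, round(n * r_inner / r_outer))
  coords <- seq(-n, n)  # integer lattice
  grid <- as.matrix(expand.grid(i = coords, j = coords, k = coords))
  mlev <- pmax(abs(grid[, 1L]), abs(grid[, 2L]), abs(grid[, 3L]))
  nid <- function(i, j, k) {
    (i + n) + (2L * n + 1L) * ((j + n) + (2L * n + 1L) * (k + n)) + 1L
  }
  ci <- seq(-n, n - 1L)
  cells <- expand.grid(i = ci, j = ci, k = ci)
  # drop cells fully inside the inner cube [-k0, k0]^3
  inner <- cells$i >= -k0 & cells$i + 1L <= k0 &
    cells$j >= -k0 & cells$j + 1L <= k0 &
    cells$k >= -k0 & cells$k + 1L <= k0
  cells <- cells[!inner, , drop = FALSE]
  corner <- cbind(
    nid(cells$i,      cells$j,      cells$k),
    nid(cells$i + 1L, cells$j,      cells$k),
    nid(cells$i,      cells$j + 1L, cells$k),
    nid(cells$i + 1L, cells$j + 1L, cells$k),
    nid(cells$i,      cells$j,      cells$k + 1L),
    nid(cells$i + 1L, cells$j,      cells$k + 1L),
    nid(cells$i,      cells$j + 1L, cells$k + 1L),
    nid(cells$i + 1L, cells$j + 1L, cells$k + 1L)
  )
  tets <- do.call(rbind, lapply(seq_len(6L), function(t) {
    corner[, .kuhn_tets[t, ], drop = FALSE]
  }))
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(grid))
  remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4L)
  g <- grid[used, , drop = FALSE]
  m <- mlev[used]
  # radial map: cube shell level m -> sphere radius r(m)
  r <- r_inner + (r_outer - r_inner) * (m - k0) / (n - k0)
  len <- sqrt(rowSums(g^2))
  len[len == 0] <- 1
  nodes <- g / len * r
  mesh <- new_volume_mesh(nodes, tets, rep(1L, nrow(tets)),
                          c(medium = 1L), h = (r_outer - r_inner) / (n - k0))
  # patches from lattice levels of the generating cube
  bd <- boundary_facets(mesh)
  lev <- m[bd[, 1L]]
  lev2 <- m[bd[, 2L]]; lev3 <- m[bd[, 3L]]
  src <- lev == k0 & lev2 == k0 & lev3 == k0
  gnd <- lev == n & lev2 == n & lev3 == n
  mesh$patches <- list(source = bd[src, , drop = FALSE],
                       ground = bd[gnd, , drop = FALSE])
  mesh$patch_nodes <- lapply(mesh$patches, function(f) sort(unique(as.vector(f))))
  mesh
}

#' Edge graph of one compartment
#'
#' Unique mesh edges whose elements belong to the given compartment, with
#' Euclidean lengths; the graph Dijkstra fiber tracing runs on.
#'
#' @param mesh a `volume_mesh`.
#' @param compartment compartment name or id; `NULL` for the whole mesh.
#' @return list with `from`, `to` (node ids), `length` (mm) and `nodes`
#'   (ids of nodes incident to the compartment).
#' @export
compartment_graph <- function(mesh, compartment = NULL) {
  key <- paste0("graph_", compartment %||% "all")
  if (!is.null(mesh$cache[[key]])) return(mesh$cache[[key]])
  tt <- mesh$tets
  if (!is.null(compartment)) {
    id <- compartment_id(mesh, compartment)
    tt <- tt[mesh$label == id, , drop = FALSE]
    if (nrow(tt) == 0L) stop("compartment has no elements: ", compartment)
  }
  pairs <- rbind(tt[, c(1L, 2L)], tt[, c(1L, 3L)], tt[, c(1L, 4L)],
                 tt[, c(2L, 3L)], tt[, c(2L, 4L)], tt[, c(3L, 4L)])
  a <- pmin(pairs[, 1L], pairs[, 2L])
  b <- pmax(pairs[, 1L], pairs[, 2L])
  keyv <- a + as.numeric(nrow(mesh$nodes)) * b
  kp <- !duplicated(keyv)
  a <- a[kp]; b <- b[kp]
  len <- sqrt(rowSums((mesh$nodes[a, , drop = FALSE] -
                       mesh$nodes[b, , drop = FALSE])^2))
  g <- list(from = a, to = b, length = len,
            nodes = sort(unique(as.vector(tt))))
  mesh$cache[[key]] <- g
  g
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Locate points in the mesh; returns tet index (NA when not found) and
# barycentric coordinates. Lattice meshes use a closed-form O(1) lookup:
# within a Kuhn-split box the containing tetrahedron is determined by the
# ordering of the fractional coordinates, and the barycentric coordinates
# are their successive differences.
#' @keywords internal
locate_points <- function(mesh, pts, tol = 1e-9) {
  npt <- nrow(pts)
  tet_of <- rep(NA_integer_, npt)
  bary <- matrix(NA_real_, npt, 4L)
  if (!is.null(mesh$grid)) {
    g <- mesh$grid
    if (is.null(mesh$cache$tetkey)) {
      key <- (as.numeric(g$hex_of_tet) - 1) * 6 + g$kuhn_of_tet
      ord <- order(key)
      mesh$cache$tetkey <- list(sorted = key[ord], ord = ord)
    }
    tk <- mesh$cache$tetkey
    ix <- findInterval(pts[, 1L], g$bx, all.inside = TRUE)
    iy <- findInterval(pts[, 2L], g$by, all.inside = TRUE)
    iz <- findInterval(pts[, 3L], g$bz, all.inside = TRUE)
    fx <- (pts[, 1L] - g$bx[ix]) / (g$bx[ix + 1L] - g$bx[ix])
    fy <- (pts[, 2L] - g$by[iy]) / (g$by[iy + 1L] - g$by[iy])
    fz <- (pts[, 3L] - g$bz[iz]) / (g$bz[iz + 1L] - g$bz[iz])
    inside <- fx >= -tol & fx <= 1 + tol & fy >= -tol & fy <= 1 + tol &
      fz >= -tol & fz <= 1 + tol
    fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
    fz <- pmin(pmax(fz, 0), 1)
    # tet index within the box by fractional-coordinate ordering, matching
    # the row order of .kuhn_tets
    k <- ifelse(fx >= fy & fy >= fz, 1L,
         ifelse(fx >= fz & fz >= fy, 2L,
         ifelse(fy >= fx & fx >= fz, 3L,
         ifelse(fy >= fz & fz >= fx, 4L,
         ifelse(fz >= fx & fx >= fy, 5L, 6L)))))
    hexid <- ix + g$dims[1L] * (iy - 1L + g$dims[2L] * (iz - 1L))
    key <- (as.numeric(hexid) - 1) * 6 + k
    pos <- findInterval(key, tk$sorted)
    hit <- inside & pos >= 1L & tk$sorted[pmax(pos, 1L)] == key
    t_idx <- tk$ord[pos[hit]]
    tet_of[hit] <- t_idx
    # barycentric coordinates: sorted fractions' successive differences
    a <- pmax(fx, fy, fz)
    c3 <- pmin(fx, fy, fz)
    b <- fx + fy + fz - a - c3
    bary[hit, ] <- cbind(1 - a, a - b, b - c3, c3)[hit, , drop = FALSE]
  } else {
    cen <- mesh$cache$centroids
    if (is.null(cen)) {
      cen <- (mesh$nodes[mesh$tets[, 1L], ] + mesh$nodes[mesh$tets[, 2L], ] +
              mesh$nodes[mesh$tets[, 3L], ] + mesh$nodes[mesh$tets[, 4L], ]) / 4
      mesh$cache$centroids <- cen
    }
    for (q in seq_len(npt)) {
      d2 <- rowSums(sweep(cen, 2L, pts[q, ])^2)
      for (t in order(d2)[seq_len(min(60L, length(d2)))]) {
        lam <- tet_barycentric(mesh, t, pts[q, ])
        if (all(lam >= -tol)) {
          tet_of[q] <- t
          bary[q, ] <- lam
          break
        }
      }
    }
  }
  list(tet = tet_of, bary = bary)
}

#' @keywords internal
tet_barycentric <- function(mesh, t, p) {
  v <- mesh$tets[t, ]
  p1 <- mesh$nodes[v[1L], ]
  M <- cbind(mesh$nodes[v[2L], ] - p1, mesh$nodes[v[3L], ] - p1,
             mesh$nodes[v[4L], ] - p1)
  det <- M[1L, 1L] * (M[2L, 2L] * M[3L, 3L] - M[2L, 3L] * M[3L, 2L]) -
         M[1L, 2L] * (M[2L, 1L] * M[3L, 3L] - M[2L, 3L] * M[3L, 1L]) +
         M[1L, 3L] * (M[2L, 1L] * M[3L, 2L] - M[2L, 2L] * M[3L, 1L])
  if (abs(det) < .Machine$double.xmin) return(rep(-1, 4L))
  r <- p - p1
  # Cramer's rule
  l2 <- (r[1L] * (M[2L, 2L] * M[3L, 3L] - M[2L, 3L] * M[3L, 2L]) -
         M[1L, 2L] * (r[2L] * M[3L, 3L] - M[2L, 3L] * r[3L]) +
         M[1L, 3L] * (r[2L] * M[3L, 2L] - M[2L, 2L] * r[3L])) / det
  l3 <- (M[1L, 1L] * (r[2L] * M[3L, 3L] - M[2L, 3L] * r[3L]) -
         r[1L] * (M[2L, 1L] * M[3L, 3L] - M[2L, 3L] * M[3L, 1L]) +
         M[1L, 3L] * (M[2L, 1L] * r[3L] - r[2L] * M[3L, 1L])) / det
  l4 <- (M[1L, 1L] * (M[2L, 2L] * r[3L] - r[2L] * M[3L, 2L]) -
         M[1L, 2L] * (M[2L, 1L] * r[3L] - r[2L] * M[3L, 1L]) +
         r[1L] * (M[2L, 1L] * M[3L, 2L] - M[2L, 2L] * M[3L, 1L])) / det
  c(1 - l2 - l3 - l4, l2, l3, l4)
}

#' @exportS3Method base::print
print.volume_mesh <- function(x, ...) {
  cat("<volume_mesh>", nrow(x$nodes), "nodes,", nrow(x$tets), "tets\n")
  tab <- table(x$label)
  nm <- names(x$compartments)[match(as.integer(names(tab)), x$compartments)]
  cat("  compartments:",
      paste0(nm, " (", as.integer(tab), ")", collapse = ", "), "\n")
  if (length(x$patches))
    cat("  patches:", paste(names(x$patches), collapse = ", "), "\n")
  invisible(x)
}
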