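# Auditory-nerve-fiber reconstruction.
#
# Fibers are traced as shortest paths over the edge graph of the
# auditory-nerve compartment: seed points on the lamina edge curve and on the
# truncated nerve-trunk base are snapped to the closest nerve mesh nodes, a
# deterministic Dijkstra search returns the minimal Euclidean-length edge
# path, and an optional refinement pass remeshes a tubular subvolume around
# the coarse path at finer resolution and re-runs the search to smooth the
# trajectory. Because paths can only use nerve edges, every fiber vertex is
# guaranteed to lie inside the auditory nerve -- the property spline-based
# reconstructions cannot ensure in a porous modiolus.

#' Seed point pairs for fiber tracing
#'
#' Places `n` seed points evenly spaced by arclength (endpoints included) on
#' the lamina edge curve, and builds the matching end points by projecting
#' that curve onto the nerve-trunk base plane, uniformly shrinking it about
#' the trunk axis until its maximal radial extent is 90% of the trunk radius,
#' and rotating it by `rotation` degrees about the axis (the spiral "wrap"
#' that gives basal fibers a tangential course). Pairs are matched by
#' arclength rank.
#'
#' @param geom a `cochlea_geometry`.
#' @param n number of seed pairs (>= 2).
#' @param rotation rotation of the projected end curve, degrees.
#' @return list with matrices `start` and `end` (n x 3 each).
#' @export
make_seed_pairs <- function(geom, n = 400L, rotation = 45) {
  stopifnot(inherits(geom, "cochlea_geometry"))
  if (n < 2L) stop("n must be >= 2")
  L <- geom$lamina_s[length(geom$lamina_s)]
  s_seed <- seq(0, L, length.out = n)
  start <- polyline_interp(geom$lamina_curve, s_seed)

  proj <- start
  proj[, 3L] <- geom$nerve_base_plane
  rad <- sqrt(proj[, 1L]^2 + proj[, 2L]^2)
  if (max(rad) < .Machine$double.eps)
    stop("geometry error: degenerate projection of the lamina curve")
  shrink <- 0.9 * geom$trunk_radius / max(rad)
  th <- rotation * pi / 180
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
  endp <- cbind(proj[, 1L] * shrink, proj[, 2L] * shrink, proj[, 3L]) %*% rot
  list(start = start, end = endp, lamina_s = s_seed)
}

#' Snap points to the closest mesh nodes of one compartment
#'
#' Exact nearest-node queries with a deterministic lowest-node-id tie-break.
#'
#' @param points n x 3 coordinate matrix.
#' @param mesh a `volume_mesh`.
#' @param compartment compartment name (default auditory nerve).
#' @return integer vector of mesh node ids.
#' @export
snap_to_mesh <- function(points, mesh, compartment = "auditory_nerve") {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  g <- compartment_graph(mesh, compartment)
  if (length(g$nodes) == 0L) stop("compartment is empty: ", compartment)
  nb <- nearest_bruteforce(points, mesh$nodes[g$nodes, , drop = FALSE])
  g$nodes[nb$index]
}

#' @keywords internal
graph_csr <- function(mesh, compartment) {
  key <- paste0("csr_", compartment %||% "all")
  if (!is.null(mesh$cache[[key]])) return(mesh$cache[[key]])
  g <- compartment_graph(mesh, compartment)
  n <- nrow(mesh$nodes)
  from <- c(g$from, g$to)
  to <- c(g$to, g$from)
  w <- c(g$length, g$length)
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]; w <- w[ord]
  deg <- tabulate(from, n)
  csr <- list(ptr = c(1L, 1L + cumsum(deg)), idx = to, w = w, n = n,
              members = g$nodes)
  mesh$cache[[key]] <- csr
  csr
}

#' Shortest path between two mesh nodes within a compartment
#'
#' Dijkstra search over mesh edges whose elements belong to the compartment,
#' with Euclidean edge lengths and deterministic tie-breaking.
#'
#' @param mesh a `volume_mesh`.
#' @param src,dst mesh node ids.
#' @param compartment compartment name constraining the path.
#' @return a `fiber_path`: ordered coordinates, source node ids, cumulative
#'   arclength `s` (mm).
#' @export
shortest_path <- function(mesh, src, dst, compartment = "auditory_nerve") {
  csr <- graph_csr(mesh, compartment)
  if (!(src %in% csr$members))
    stop("unreachable error: source node ", src, " not in ", compartment)
  if (!(dst %in% csr$members))
    stop("unreachable error: target node ", dst, " not in ", compartment)
  res <- .dijkstra_cpp(csr$ptr, csr$idx, csr$w, csr$n,
                       as.integer(src), as.integer(dst))
  if (!isTRUE(res$found))
    stop("unreachable error: no ", compartment, " path between nodes ",
         src, " and ", dst)
  ids <- res$path
  pts <- mesh$nodes[ids, , drop = FALSE]
  new_fiber_path(pts, node_ids = ids, compartment = compartment)
}

#' @keywords internal
new_fiber_path <- function(pts, node_ids = NULL, compartment = "auditory_nerve",
                           refined = FALSE) {
  s <- polyline_arclength(pts)
  if (length(s) == 1L) s <- 0
  structure(
    list(points = pts, node_ids = node_ids, s = s,
         compartment = compartment, refined = refined,
         soma_center_arclength = NA_real_, soma_diameter_um = NA_real_,
         region = NULL),
    class = "fiber_path"
  )
}

#' Fiber path total arclength (mm)
#' @param path a `fiber_path`.
#' @export
fiber_length <- function(path) path$s[length(path$s)]

#' Refine a fiber by remeshing a tubular subvolume
#'
#' Extracts the part of the compartment within `tube_radius` of the coarse
#' path, remeshes it with a fine lattice oriented along the path's endpoint
#' chord (so the refined edge graph contains edges parallel to the dominant
#' fiber direction and the lattice metrication error shrinks), and re-runs
#' the shortest-path search between the snapped original endpoints.
#'
#' @param mesh the parent `volume_mesh`.
#' @param path a coarse `fiber_path` from [shortest_path()].
#' @param tube_radius subvolume radius around the coarse path (mm); default
#'   3x the parent lattice spacing.
#' @param fine_edge_length lattice spacing of the refined subvolume (mm);
#'   default a quarter of the parent spacing.
#' @return a refined `fiber_path` (`refined = TRUE`); endpoints lie within
#'   one fine edge length of the originals and every vertex within
#'   `tube_radius` of the input path.
#' @export
refine_fiber <- function(mesh, path, tube_radius = NULL,
                         fine_edge_length = NULL) {
  h0 <- mesh$h %||% stop("parent mesh has no lattice spacing")
  tube_radius <- tube_radius %||% (3 * h0)
  fine_edge_length <- fine_edge_length %||% (h0 / 4)
  if (fine_edge_length >= h0)
    stop("fine_edge_length must be smaller than the parent mesh edge scale")
  pts <- path$points
  if (nrow(pts) < 2L) return(path)
  chord <- pts[nrow(pts), ] - pts[1L, ]
  if (sqrt(sum(chord^2)) < fine_edge_length) return(path)
  Fm <- orthonormal_frame(chord)             # rows u, v, w
  local <- sweep(pts, 2L, pts[1L, ]) %*% t(Fm)
  dense <- resample_polyline(pts, fine_edge_length)

  h <- fine_edge_length
  lo <- apply(local, 2L, min) - tube_radius
  hi <- apply(local, 2L, max) + tube_radius
  bx <- seq(lo[1L], hi[1L] + h, by = h)
  by <- seq(lo[2L], hi[2L] + h, by = h)
  bz <- seq(lo[3L], hi[3L] + h, by = h)

  comp_id <- compartment_id(mesh, path$compartment)
  margin <- tube_radius - 0.9 * h  # keeps refined vertices inside the tube
  label_fun <- function(centers_local) {
    world <- centers_local %*% Fm + matrix(pts[1L, ], nrow(centers_local), 3L,
                                           byrow = TRUE)
    d <- nearest_within(world, dense, max(margin, h))$dist
    ok <- d <= margin
    if (any(ok)) {
      loc <- locate_points(mesh, world[ok, , drop = FALSE])
      inside <- !is.na(loc$tet) & mesh$label[ifelse(is.na(loc$tet), 1L, loc$tet)] == comp_id
      ok[ok] <- inside
    }
    as.integer(ok)
  }
  pre <- function(centers_local) {
    world <- centers_local %*% Fm + matrix(pts[1L, ], nrow(centers_local), 3L,
                                           byrow = TRUE)
    is.finite(nearest_within(world, dense, tube_radius + h)$dist)
  }
  sub <- tryCatch(
    build_lattice_mesh(bx, by, bz, label_fun, c(tube = 1L), h_fine = h,
                       prefilter = pre),
    error = function(e) stop("unreachable error: refinement tube too thin; ",
                             "try a larger tube_radius")
  )
  # map subvolume nodes to world coordinates (rigid motion, lengths kept)
  sub$nodes <- sub$nodes %*% Fm + matrix(pts[1L, ], nrow(sub$nodes), 3L,
                                         byrow = TRUE)
  ends <- nearest_bruteforce(pts[c(1L, nrow(pts)), , drop = FALSE], sub$nodes)
  if (any(ends$dist > sqrt(3) * h))
    stop("unreachable error: refinement tube too thin; try a larger tube_radius")
  fine <- tryCatch(
    shortest_path(sub, ends$index[1L], ends$index[2L], compartment = "tube"),
    error = function(e) stop("unreachable error: refined tube disconnected; ",
                             "try a larger tube_radius")
  )
  out <- new_fiber_path(fine$points, node_ids = NULL,
                        compartment = path$compartment, refined = TRUE)
  out
}

#' Annotate the soma position on a fiber
#'
#' Marks the spiral-ganglion soma at a given arclength from the synaptic
#' (lamina) end of the fiber and classifies each vertex as peripheral axon,
#' soma, or central axon.
#'
#' @param path a `fiber_path`.
#' @param peripheral_length arclength of the peripheral axon (mm, default
#'   1.5).
#' @param soma_diameter soma diameter in micrometres (default 20).
#' @return the annotated `fiber_path`.
#' @export
place_soma <- function(path, peripheral_length = 1.5, soma_diameter = 20) {
  total <- fiber_length(path)
  if (peripheral_length < 0) stop("peripheral_length must be >= 0")
  if (total < peripheral_length)
    stop("fiber (", format(total, digits = 4),
         " mm) is shorter than the requested peripheral length")
  if (peripheral_length == 0)
    warning("soma placed at the synaptic ending (peripheral_length = 0)")
  half_mm <- soma_diameter / 2000  # um -> mm
  path$soma_center_arclength <- peripheral_length
  path$soma_diameter_um <- soma_diameter
  reg <- rep("central", length(path$s))
  reg[path$s < peripheral_length - half_mm] <- "peripheral"
  reg[path$s >= peripheral_length - half_mm &
      path$s <= peripheral_length + half_mm] <- "soma"
  path$region <- reg
  path
}

#' Trace the full set of auditory nerve fibers
#'
#' Runs the complete reconstruction: seed pairs, snapping, per-pair shortest
#' paths, optional tubular refinement, and soma placement.
#'
#' @param geom a `cochlea_geometry`.
#' @param mesh its `volume_mesh`.
#' @param n number of fibers (default 400).
#' @param rotation end-curve rotation in degrees (default 45).
#' @param refine logical; run the subvolume refinement pass per fiber.
#' @param peripheral_length,soma_diameter forwarded to [place_soma()].
#' @param tube_radius,fine_edge_length forwarded to [refine_fiber()].
#' @return list of `fiber_path` (basal to apical order) with attribute
#'   `lamina_s` giving each fiber's seed position along the lamina curve.
#' @export
trace_fibers <- function(geom, mesh, n = 400L, rotation = 45,
                         refine = FALSE, peripheral_length = 1.5,
                         soma_diameter = 20, tube_radius = NULL,
                         fine_edge_length = NULL) {
  seeds <- make_seed_pairs(geom, n, rotation)
  src <- snap_to_mesh(seeds$start, mesh)
  dst <- snap_to_mesh(seeds$end, mesh)
  fibers <- vector("list", n)
  for (i in seq_len(n)) {
    fp <- shortest_path(mesh, src[i], dst[i])
    if (refine) fp <- refine_fiber(mesh, fp, tube_radius, fine_edge_length)
    fibers[[i]] <- place_soma(fp, peripheral_length, soma_diameter)
  }
  attr(fibers, "lamina_s") <- seeds$lamina_s
  fibers
}

#' @exportS3Method base::print
print.fiber_path <- function(x, ...) {
  cat("<fiber_path>", nrow(x$points), "vertices,",
      format(fiber_length(x), digits = 4), "mm",
      if (x$refined) "(refined)" else "", "\n")
  invisible(x)
}
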