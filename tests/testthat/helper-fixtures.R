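# Shared fixtures, built once per test run and cached. The default study
# (both geometry variants at the default 0.3 mm lattice, one 1 mA stimulus
# each, 400 fibers) is the most expensive piece and is reused by several
# test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

get_study <- function() {
  memo("study", function() current_spread_study())
}

get_sphere_fixture <- function() {
  memo("sphere", function() {
    sigma <- conductivity_map()
    lapply(c(coarse = 10L, fine = 16L), function(n) {
      mesh <- mesh_concentric_spheres(r_inner = 0.5, r_outer = 5, n = n)
      field <- solve_field(mesh, sigma, stimulus_spec("source", 1e-3))
      list(mesh = mesh, field = field, n = n)
    })
  })
}

get_duct_fixture <- function() {
  memo("duct", function() {
    geom <- geometry_straight_duct(length = 16, n_contact_pairs = 6, pitch = 2)
    mesh <- mesh_geometry(geom, 0.2)
    spread <- voltage_spread(mesh, conductivity_map(), amplitude = 50e-6)
    list(geom = geom, mesh = mesh, spread = spread)
  })
}

get_tube_fixture <- function() {
  memo("tube", function() {
    axis <- c(1, 0.45, 0.3)
    geom <- geometry_cylinder(radius = 0.6, length = 10, axis = axis)
    mesh <- mesh_geometry(geom, 0.4)
    u <- axis / sqrt(sum(axis^2))
    ends <- rbind(0.4 * u, (10 - 0.4) * u)
    ids <- snap_to_mesh(ends, mesh)
    coarse <- shortest_path(mesh, ids[1L], ids[2L])
    refined <- refine_fiber(mesh, coarse, tube_radius = 1.2,
                            fine_edge_length = 0.1)
    list(mesh = mesh, ids = ids, coarse = coarse, refined = refined)
  })
}

# Hand-built tiny meshes for exhaustive shortest-path oracles. The node
# chain guarantees connectivity; extra random tets add shortcuts.
toy_mesh <- function(n_nodes = 10L, seed = 1L, extra = 3L) {
  set.seed(seed)
  repeat {
    nodes <- matrix(stats::runif(n_nodes * 3L, 0, 10), ncol = 3L)
    tets <- cbind(1:(n_nodes - 3L), 2:(n_nodes - 2L),
                  3:(n_nodes - 1L), 4:n_nodes)
    for (k in seq_len(extra)) {
      tets <- rbind(tets, sort(sample.int(n_nodes, 4L)))
    }
    vols <- abs(cochleafield:::tet_volumes_signed(nodes, tets))
    if (all(vols > 1e-6)) break
  }
  cochleafield:::new_volume_mesh(
    nodes, tets, rep(3L, nrow(tets)),
    c(bony_labyrinth = 1L, auditory_nerve = 3L)
  )
}

# Exhaustive enumeration of simple paths (oracle for Dijkstra).
brute_force_path_length <- function(mesh, src, dst,
                                    compartment = "auditory_nerve") {
  g <- compartment_graph(mesh, compartment)
  n <- nrow(mesh$nodes)
  adj <- vector("list", n)
  for (e in seq_along(g$from)) {
    a <- g$from[e]; b <- g$to[e]; w <- g$length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  best <- Inf
  visited <- logical(n)
  dfs <- function(u, acc) {
    if (acc >= best) return()
    if (u == dst) {
      best <<- acc
      return()
    }
    visited[u] <<- TRUE
    nb <- adj[[u]]
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1L]
        if (!visited[v]) dfs(v, acc + nb[r, 2L])
      }
    }
    visited[u] <<- FALSE
  }
  dfs(src, 0)
  best
}

total_variation <- function(x) sum(abs(diff(x)))
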