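test_that("sphere mesh volume converges to the analytic volume", {
  errs <- sapply(c(0.25, 0.15, 0.1), function(h) {
    m <- mesh_geometry(geometry_sphere(1), h)
    abs(mesh_volume(m) - 4 * pi / 3) / (4 * pi / 3)
  })
  expect_lt(errs[3L], 0.01)
  # staircase volume error is not strictly monotone step to step, but the
  # finest mesh must beat the coarsest
  expect_lt(errs[3L], errs[1L])
})

test_that("halving the edge length strictly increases the element count", {
  m1 <- mesh_geometry(geometry_sphere(1), 0.3)
  m2 <- mesh_geometry(geometry_sphere(1), 0.15)
  expect_gt(nrow(m2$tets), nrow(m1$tets))
})

test_that("every tetrahedron carries exactly one valid compartment label", {
  st <- get_study()
  m <- st$mesh$ori
  expect_length(m$label, nrow(m$tets))
  expect_true(all(m$label %in% m$compartments))
})

test_that("refinement series demands >= 2 levels and increases resolution", {
  expect_error(refinement_series(geometry_sphere(1), levels = 1,
                                 base_edge_length = 0.3), ">= 2")
  ms <- refinement_series(geometry_sphere(1), levels = 3,
                          base_edge_length = 0.3)
  counts <- sapply(ms, function(m) nrow(m$tets))
  expect_true(all(diff(counts) > 0))
  # the finest mesh has at most the volume error of the coarsest
  errs <- sapply(ms, function(m) abs(mesh_volume(m) - 4 * pi / 3))
  expect_lte(errs[3L], errs[1L])
})

test_that("microstructure toggle changes only nerve/bone labels inside the modiolus", {
  st <- get_study()
  m_ori <- st$mesh$ori
  m_sim <- st$mesh$sim
  expect_identical(m_ori$tets, m_sim$tets)
  nerve <- m_ori$compartments[["auditory_nerve"]]
  bone <- m_ori$compartments[["bony_labyrinth"]]
  d <- which(m_ori$label != m_sim$label)
  expect_gt(length(d), 0L)
  # elements can only swap between nerve and modiolar bone, never anything else
  expect_true(all(m_sim$label[d] == nerve & m_ori$label[d] == bone))
  # the detailed nerve is a subset of the simplified (solid) nerve
  expect_true(all(which(m_ori$label == nerve) %in% which(m_sim$label == nerve)))
  # swapped elements sit inside the modiolar envelope, not out in the shells
  cen <- (m_ori$nodes[m_ori$tets[d, 1L], , drop = FALSE] +
          m_ori$nodes[m_ori$tets[d, 2L], , drop = FALSE] +
          m_ori$nodes[m_ori$tets[d, 3L], , drop = FALSE] +
          m_ori$nodes[m_ori$tets[d, 4L], , drop = FALSE]) / 4
  expect_true(all(sqrt(cen[, 1L]^2 + cen[, 2L]^2) < st$geometry$ori$bone_r))
})

test_that("contact patches are complete, disjoint and pitch-spaced", {
  st <- get_study()
  m <- st$mesh$ori
  g <- st$geometry$ori
  cn <- grep("^contact_", names(m$patches), value = TRUE)
  expect_length(cn, g$electrode$n_contact_pairs)
  expect_true("ground" %in% names(m$patches))
  # no node belongs to two electrode patches
  all_nodes <- unlist(m$patch_nodes[cn])
  expect_false(any(duplicated(all_nodes)))
  # centre-to-centre spacing of patch centroids measured along the carrier
  # centerline: pitch +/- 5%
  cen <- t(sapply(cn[order(as.integer(sub("contact_", "", cn)))], function(p) {
    f <- m$patches[[p]]
    colMeans((m$nodes[f[, 1L], , drop = FALSE] +
              m$nodes[f[, 2L], , drop = FALSE] +
              m$nodes[f[, 3L], , drop = FALSE]) / 3)
  }))
  s_cloud <- cochleafield:::polyline_arclength(g$clouds$carrier)
  idx <- cochleafield:::nearest_bruteforce(cen, g$clouds$carrier)$index
  gaps <- diff(s_cloud[idx])
  expect_true(all(abs(gaps - g$electrode$pitch) / g$electrode$pitch < 0.05))
})

test_that("meshing a geometry with no interior elements fails loudly", {
  g <- geometry_sphere(1)
  g$radius <- 1e-9
  expect_error(mesh_geometry(g, 0.5), "mesh error")
})
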