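test_that("homogeneous sphere solve matches the point-source closed form", {
  fx <- get_sphere_fixture()
  sigma <- 1
  I <- 1e-3
  errs <- sapply(fx, function(lev) {
    mesh <- lev$mesh
    r <- sqrt(rowSums(mesh$nodes^2))
    h_r <- mesh$h
    sel <- r >= 0.5 + 3 * h_r & r <= 5 - 3 * h_r
    # exact concentric-shell solution (1/r - 1/R), radii in m
    exact <- I / (4 * pi * sigma) * (1 / (r[sel] * 1e-3) - 1 / 5e-3)
    max(abs(lev$field$nodal_values[sel] - exact) / exact)
  })
  expect_lt(errs[["coarse"]], 0.05)
  expect_lt(errs[["fine"]], errs[["coarse"]])
})

test_that("zero current gives an identically zero field", {
  fx <- get_duct_fixture()
  f0 <- solve_field(fx$mesh, conductivity_map(),
                    stimulus_spec(active_pair = 3, current = 0))
  expect_equal(max(abs(f0$nodal_values)), 0)
})

test_that("the field is linear in current and inverse in conductivity", {
  fx <- get_duct_fixture()
  f1 <- solve_field(fx$mesh, conductivity_map(),
                    stimulus_spec(active_pair = 2, current = 1e-3))
  f2 <- solve_field(fx$mesh, conductivity_map(),
                    stimulus_spec(active_pair = 2, current = 2e-3))
  expect_equal(f2$nodal_values, 2 * f1$nodal_values, tolerance = 1e-12)
  sig2 <- conductivity_map()
  sig2[] <- 2 * unclass(conductivity_map())
  f3 <- solve_field(fx$mesh, sig2, stimulus_spec(active_pair = 2,
                                                 current = 1e-3))
  expect_equal(f3$nodal_values, f1$nodal_values / 2, tolerance = 1e-9)
})

test_that("net contact currents satisfy the stimulation constraints", {
  st <- get_study()
  f <- st$field$ori
  I <- f$stimulus$current
  active <- paste0("contact_", f$stimulus$active_pair)
  expect_lt(abs(contact_net_current(f, active) - I), 1e-3 * I)
  expect_lt(abs(contact_net_current(f, "ground") + I), 1e-3 * I)
  floating <- setdiff(grep("^contact_", names(f$mesh$patches), value = TRUE),
                      active)
  for (p in floating) {
    expect_lt(abs(contact_net_current(f, p)), 1e-3 * I)
  }
  # global conservation over all patches
  tot <- sum(sapply(names(f$mesh$patches), contact_net_current, field = f))
  expect_lt(abs(tot), 1e-3 * I)
  expect_error(contact_net_current(f, "nonexistent"), "no such patch")
})

test_that("extrema of the potential sit on electrode boundaries", {
  fx <- get_duct_fixture()
  f <- solve_field(fx$mesh, conductivity_map(),
                   stimulus_spec(active_pair = 3, current = 1e-3))
  patch_nodes <- unlist(fx$mesh$patch_nodes)
  interior <- setdiff(seq_len(nrow(fx$mesh$nodes)), patch_nodes)
  tol <- 1e-9 * diff(range(f$nodal_values))
  expect_lte(max(f$nodal_values[interior]),
             max(f$nodal_values[patch_nodes]) + tol)
  expect_gte(min(f$nodal_values[interior]),
             min(f$nodal_values[patch_nodes]) - tol)
})

test_that("field sampling reproduces nodal and centroid values exactly", {
  fx <- get_duct_fixture()
  f <- solve_field(fx$mesh, conductivity_map(),
                   stimulus_spec(active_pair = 3, current = 1e-3))
  m <- fx$mesh
  set.seed(42)
  ids <- sample.int(nrow(m$nodes), 100L)
  expect_equal(sample_potential(f, m$nodes[ids, ]), f$nodal_values[ids],
               tolerance = 1e-12)
  tid <- sample.int(nrow(m$tets), 100L)
  cen <- (m$nodes[m$tets[tid, 1L], ] + m$nodes[m$tets[tid, 2L], ] +
          m$nodes[m$tets[tid, 3L], ] + m$nodes[m$tets[tid, 4L], ]) / 4
  vv <- f$nodal_values
  expect_equal(sample_potential(f, cen),
               (vv[m$tets[tid, 1L]] + vv[m$tets[tid, 2L]] +
                vv[m$tets[tid, 3L]] + vv[m$tets[tid, 4L]]) / 4,
               tolerance = 1e-12)
  expect_error(sample_potential(f, rbind(c(500, 500, 500))),
               "out-of-domain.*1")
})

test_that("voltage spread matrix is reciprocal and decays with separation", {
  fx <- get_duct_fixture()
  M <- fx$spread
  expect_true(all(is.na(diag(unclass(M)))))
  expect_equal(attr(M, "amplitude_A"), 50e-6)
  asym <- max(abs(M - t(M)) / abs(M), na.rm = TRUE)
  expect_lt(asym, 0.01)
  # monotone decay with contact separation on each side of the source
  n <- ncol(M)
  for (i in seq_len(n)) {
    v <- unclass(M)[i, ]
    right <- if (i < n) v[(i + 1L):n] else numeric(0)
    left <- if (i > 1L) v[(i - 1L):1L] else numeric(0)
    expect_true(length(right) < 2 || all(diff(right[!is.na(right)]) < 0))
    expect_true(length(left) < 2 || all(diff(left[!is.na(left)]) < 0))
  }
})

test_that("sampled potentials converge under mesh refinement", {
  # carrier fat enough to be resolved at the coarsest level, so successive
  # levels discretize the same electrode geometry
  geom <- geometry_straight_duct(length = 12, duct_radius = 2,
                                 carrier_radius = 0.6, n_contact_pairs = 4,
                                 pitch = 2.4, bone_margin = 1)
  hs <- c(0.4, 0.28, 0.2)
  probes <- cbind(seq(2, 10, by = 0.5), 1.2, 0)
  vals <- lapply(hs, function(h) {
    m <- mesh_geometry(geom, h)
    f <- solve_field(m, conductivity_map(),
                     stimulus_spec(active_pair = 2, current = 1e-3))
    sample_potential(f, probes)
  })
  d12 <- max(abs(vals[[2L]] - vals[[1L]]) / abs(vals[[2L]]))
  d23 <- max(abs(vals[[3L]] - vals[[2L]]) / abs(vals[[3L]]))
  expect_lt(d23, d12)
})

test_that("a mesh without a ground patch is rejected", {
  m <- mesh_geometry(geometry_sphere(1), 0.3)  # no patches at all
  expect_error(solve_field(m, conductivity_map(), stimulus_spec("source")),
               "active pair patch")
  m$patches$source <- cochleafield:::boundary_facets(m)[1:10, ]
  m$patch_nodes$source <- sort(unique(as.vector(m$patches$source)))
  expect_error(solve_field(m, conductivity_map(), stimulus_spec("source")),
               "boundary-condition")
})
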