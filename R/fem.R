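# Quasi-static volume-conduction solver.
#
# Solves div(-sigma grad V) = 0 on the labeled tetrahedral mesh with linear
# elements. Electrode contacts are handled as equipotential constraints: all
# nodes of a contact patch are condensed into a single unknown, and the
# right-hand side of that unknown carries the prescribed total injected
# current (the weak form of a total-normal-current condition). The active
# pair carries the stimulus current, every inactive pair carries zero net
# current (a floating contact), and the ground patch is a homogeneous
# Dirichlet condition. The condensed system is symmetric positive definite
# and is solved with a sparse Cholesky factorization, which is reused across
# stimuli sharing the same mesh and conductivities.

#' Compartment conductivities (S/m)
#'
#' Named conductivity per compartment. Defaults follow the standard values
#' used in head and cochlea volume-conduction models; the silicone carrier is
#' excluded from the conduction domain as a void rather than carrying a zero
#' conductivity, which is physically identical for a perfect insulator and
#' keeps the system non-singular.
#'
#' @param ... name = value overrides of the defaults.
#' @return an object of class `conductivity_map` (named numeric, S/m).
#' @export
conductivity_map <- function(...) {
  sigma <- c(
    scalp = 0.33, skull = 0.013, brain = 0.2,
    bony_labyrinth = 0.013, cochlear_canal = 1.43,
    auditory_nerve = 0.3333, medium = 1
  )
  over <- list(...)
  for (nm in names(over)) sigma[[nm]] <- over[[nm]]
  if (any(sigma <= 0)) stop("conductivities must be > 0 for every conducting compartment")
  structure(sigma, class = "conductivity_map")
}

#' Monopolar stimulus specification
#'
#' @param active_pair index of the stimulating contact pair (1 = most basal).
#' @param current injected current in ampere (default 1 mA).
#' @param reference name of the grounded reference patch.
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(active_pair = 1L, current = 1e-3,
                          reference = "ground") {
  if (!is.character(active_pair)) active_pair <- as.integer(active_pair)
  structure(list(active_pair = active_pair,
                 current = current, reference = reference),
            class = "stimulus_spec")
}

#' @keywords internal
assemble_stiffness <- function(mesh, sigma) {
  nm <- names(mesh$compartments)
  missing <- setdiff(nm[mesh$compartments %in% unique(mesh$label)], names(sigma))
  if (length(missing))
    stop("conductivity map lacks entries for: ", paste(missing, collapse = ", "))
  sig_of_label <- numeric(max(mesh$compartments))
  for (n2 in nm) sig_of_label[mesh$compartments[[n2]]] <- sigma[[n2]]
  sig_e <- sig_of_label[mesh$label]

  nd <- mesh$nodes
  tt <- mesh$tets
  p1 <- nd[tt[, 1L], , drop = FALSE]
  a <- nd[tt[, 2L], , drop = FALSE] - p1
  b <- nd[tt[, 3L], , drop = FALSE] - p1
  d <- nd[tt[, 4L], , drop = FALSE] - p1
  cross <- function(u, v) cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
                                u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
                                u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  bxd <- cross(b, d)
  detJ <- rowSums(a * bxd)  # 6 * signed volume
  g2 <- bxd / detJ
  g3 <- cross(d, a) / detJ
  g4 <- cross(a, b) / detJ
  g1 <- -(g2 + g3 + g4)
  # mesh lengths are mm, sigma is S/m; the stiffness integral has net
  # dimension sigma * length, hence the 1e-3 mm -> m factor
  vol <- abs(detJ) / 6 * 1e-3
  grads <- list(g1, g2, g3, g4)

  m <- nrow(tt)
  ii <- integer(16L * m); jj <- integer(16L * m); xx <- numeric(16L * m)
  pos <- 0L
  for (i in 1:4) {
    for (j in 1:4) {
      rng <- pos + seq_len(m)
      ii[rng] <- tt[, i]
      jj[rng] <- tt[, j]
      xx[rng] <- sig_e * vol * rowSums(grads[[i]] * grads[[j]])
      pos <- pos + m
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nrow(nd), nrow(nd)))
}

# dof map: 0 for grounded nodes, a shared dof per electrode patch, own dof
# otherwise. Returns list(map, n_dof, patch_dof named).
#' @keywords internal
build_dof_map <- function(mesh, reference) {
  n <- nrow(mesh$nodes)
  if (!reference %in% names(mesh$patches))
    stop("boundary-condition error: no '", reference,
         "' patch on the mesh; the system would be singular")
  pn <- mesh$patch_nodes
  epatches <- setdiff(names(pn), reference)
  owner <- integer(n)  # 0 free, -1 ground, k for patch k
  for (k in seq_along(epatches)) {
    nodes <- pn[[epatches[k]]]
    if (any(owner[nodes] > 0L))
      stop("boundary patches overlap at shared nodes")
    owner[nodes] <- k
  }
  owner[pn[[reference]]] <- -1L
  map <- integer(n)
  free <- owner == 0L
  map[free] <- seq_len(sum(free))
  nf <- sum(free)
  for (k in seq_along(epatches)) map[owner == k] <- nf + k
  patch_dof <- stats::setNames(nf + seq_along(epatches), epatches)
  list(map = map, n_dof = nf + length(epatches), patch_dof = patch_dof)
}

#' @keywords internal
fem_context <- function(mesh, sigma, reference = "ground") {
  key <- paste0("fem_", paste(signif(unclass(sigma), 8), collapse = "_"),
                "_", reference)
  ctx <- mesh$cache[[key]]
  if (!is.null(ctx)) return(ctx)
  K <- assemble_stiffness(mesh, sigma)
  dm <- build_dof_map(mesh, reference)
  Tk <- as(K, "TsparseMatrix")
  di <- dm$map[Tk@i + 1L]
  dj <- dm$map[Tk@j + 1L]
  keep <- di > 0L & dj > 0L
  Kred <- Matrix::sparseMatrix(i = di[keep], j = dj[keep], x = Tk@x[keep],
                               dims = c(dm$n_dof, dm$n_dof))
  chol <- Matrix::Cholesky(Matrix::forceSymmetric(Kred), LDL = FALSE)
  ctx <- list(K = K, dof = dm, chol = chol)
  mesh$cache[[key]] <- ctx
  ctx
}

#' Solve the volume-conduction problem for one stimulus
#'
#' @param mesh a `volume_mesh` with electrode patches and a ground patch.
#' @param sigma a [conductivity_map()].
#' @param stim a [stimulus_spec()].
#' @return an object of class `potential_field` holding nodal potentials (V),
#'   the stimulus, and solver metadata.
#' @export
solve_field <- function(mesh, sigma = conductivity_map(),
                        stim = stimulus_spec()) {
  stopifnot(inherits(mesh, "volume_mesh"))
  active <- if (is.character(stim$active_pair)) stim$active_pair else
    paste0("contact_", stim$active_pair)
  if (!active %in% names(mesh$patches))
    stop("active pair patch not found: ", active)
  ctx <- fem_context(mesh, sigma, stim$reference)
  b <- numeric(ctx$dof$n_dof)
  b[ctx$dof$patch_dof[[active]]] <- stim$current
  x <- as.numeric(Matrix::solve(ctx$chol, b))
  v <- numeric(nrow(mesh$nodes))
  pos <- ctx$dof$map > 0L
  v[pos] <- x[ctx$dof$map[pos]]
  structure(
    list(mesh = mesh, nodal_values = v, stimulus = stim, sigma = sigma,
         patch_values = stats::setNames(x[ctx$dof$patch_dof],
                                        names(ctx$dof$patch_dof)),
         context_key = NULL),
    class = "potential_field"
  )
}

#' Net current through a boundary patch
#'
#' Discrete boundary flux of -sigma grad V through a named patch, evaluated
#' as the stiffness residual summed over the patch nodes (the consistent FEM
#' flux). Positive values are currents injected into the domain.
#'
#' @param field a `potential_field`.
#' @param patch patch name.
#' @return current in ampere.
#' @export
contact_net_current <- function(field, patch) {
  mesh <- field$mesh
  if (!patch %in% names(mesh$patches)) stop("no such patch: ", patch)
  ctx <- fem_context(mesh, field$sigma, field$stimulus$reference)
  r <- as.numeric(ctx$K %*% field$nodal_values)
  sum(r[mesh$patch_nodes[[patch]]])
}

#' Sample the potential field at arbitrary points
#'
#' Element-wise linear interpolation. Points that fall marginally outside the
#' conducting domain (within one tenth of the local edge length of a mesh
#' node) are snapped to the nearest node; points further outside raise an
#' error listing their indices.
#'
#' @param field a `potential_field`.
#' @param points n x 3 matrix of query coordinates (mm).
#' @return numeric vector of potentials (V), in input order.
#' @export
sample_potential <- function(field, points) {
  mesh <- field$mesh
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  loc <- locate_points(mesh, points)
  v <- rep(NA_real_, nrow(points))
  ok <- !is.na(loc$tet)
  if (any(ok)) {
    tt <- mesh$tets[loc$tet[ok], , drop = FALSE]
    vv <- field$nodal_values
    v[ok] <- rowSums(loc$bary[ok, , drop = FALSE] *
                     cbind(vv[tt[, 1L]], vv[tt[, 2L]], vv[tt[, 3L]], vv[tt[, 4L]]))
  }
  if (any(!ok)) {
    eps <- 0.1 * (mesh$h %||% 1)
    nb <- nearest_bruteforce(points[!ok, , drop = FALSE], mesh$nodes)
    snap <- nb$dist <= eps
    v[which(!ok)[snap]] <- field$nodal_values[nb$index[snap]]
    if (any(!snap))
      stop("out-of-domain error: points outside the conducting domain: ",
           paste(which(!ok)[!snap], collapse = ", "))
  }
  v
}

#' Simulated voltage-spread matrix
#'
#' Solves one monopolar stimulus per contact and records the potential of
#' every other (floating) contact, emulating an all-against-all intracochlear
#' voltage-spread measurement. Entries on the diagonal (the stimulating
#' contact itself) are `NA`. One Cholesky factorization is shared by all
#' stimuli.
#'
#' @param mesh a `volume_mesh` with contact patches.
#' @param sigma a [conductivity_map()].
#' @param contacts contact pair indices (default: all `contact_*` patches).
#' @param amplitude injected current in ampere (default 50 uA, the telemetry
#'   protocol amplitude).
#' @return matrix (stimulating x measuring) of class `voltage_spread`, volts,
#'   with attribute `amplitude_A`.
#' @export
voltage_spread <- function(mesh, sigma = conductivity_map(), contacts = NULL,
                           amplitude = 50e-6) {
  all_idx <- sort(as.integer(sub("contact_", "",
                                 grep("^contact_", names(mesh$patches),
                                      value = TRUE))))
  contacts <- contacts %||% all_idx
  if (length(contacts) < 2L) stop("need at least 2 contacts")
  nmv <- paste0("contact_", contacts)
  M <- matrix(NA_real_, length(contacts), length(contacts),
              dimnames = list(stim = contacts, meas = contacts))
  for (ii in seq_along(contacts)) {
    f <- solve_field(mesh, sigma,
                     stimulus_spec(active_pair = contacts[ii],
                                   current = amplitude))
    M[ii, ] <- f$patch_values[nmv]
    M[ii, ii] <- NA_real_
  }
  structure(M, amplitude_A = amplitude, class = c("voltage_spread", "matrix"))
}

#' @exportS3Method base::print
print.potential_field <- function(x, ...) {
  cat("<potential_field> pair", x$stimulus$active_pair,
      "current", format(x$stimulus$current), "A;",
      "V in [", format(min(x$nodal_values), digits = 4), ",",
      format(max(x$nodal_values), digits = 4), "] V\n")
  invisible(x)
}
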