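#' @keywords internal
"_PACKAGE"

#' @useDynLib cochleafield, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Run the full detailed-versus-simplified current-spread study
#'
#' Convenience driver: builds the detailed (microstructured) and simplified
#' (solid-nerve) geometry variants, meshes both on the same lattice, solves
#' one monopolar stimulus in each, traces fibers through the detailed nerve,
#' samples both fields along the same fiber coordinates, and computes
#' activation profiles, basal/apical decay fits and the model-comparison
#' metrics.
#'
#' @param params a [cochlea_params()]; its `microstructures` flag is
#'   overridden per variant.
#' @param electrode an [electrode_params()].
#' @param target_edge_length lattice spacing (mm).
#' @param active_pair stimulating contact pair.
#' @param current stimulus current (A).
#' @param n_fibers number of fibers to trace.
#' @param rotation end-curve rotation (degrees).
#' @param refine run the per-fiber tubular refinement pass.
#' @param cc cable constants for the activation analysis.
#' @param sigma conductivity map.
#' @param progress print stage messages.
#' @return list with the geometries, meshes, fields, fibers, profiles
#'   (`ori`, `sim`), `comparison`, `decay_basal`, `decay_apical` and the
#'   seed lamina arclengths.
#' @export
current_spread_study <- function(params = cochlea_params(),
                                 electrode = electrode_params(),
                                 target_edge_length = 0.3,
                                 active_pair = 3L, current = 1e-3,
                                 n_fibers = 400L, rotation = 45,
                                 refine = FALSE,
                                 cc = cable_constants(),
                                 sigma = conductivity_map(),
                                 progress = FALSE) {
  say <- function(...) if (progress) message(...)
  p_ori <- params; p_ori$microstructures <- TRUE
  p_sim <- params; p_sim$microstructures <- FALSE
  say("building geometries")
  g_ori <- build_cochlea(p_ori, electrode)
  g_sim <- build_cochlea(p_sim, electrode)
  say("meshing")
  m_ori <- mesh_geometry(g_ori, target_edge_length)
  m_sim <- mesh_geometry(g_sim, target_edge_length)
  say("solving")
  stim <- stimulus_spec(active_pair = active_pair, current = current)
  f_ori <- solve_field(m_ori, sigma, stim)
  f_sim <- solve_field(m_sim, sigma, stim)
  say("tracing fibers")
  fibers <- trace_fibers(g_ori, m_ori, n = n_fibers, rotation = rotation,
                         refine = refine)
  lamina_s <- attr(fibers, "lamina_s")
  say("profiling")
  lambda <- length_constant(cc)
  prof_ori <- lapply(fibers, activation_profile, field = f_ori, cc = cc,
                     lambda = lambda)
  prof_sim <- lapply(fibers, activation_profile, field = f_sim, cc = cc,
                     lambda = lambda)
  cmp <- compare_models(prof_ori, prof_sim)
  tip_v <- vapply(prof_ori, function(p) p$V[1L], 1)
  es <- g_ori$contact_lamina_s[active_pair]
  decay_b <- decay_rate(lamina_s, tip_v, es, "basal")
  decay_a <- decay_rate(lamina_s, tip_v, es, "apical")
  list(
    geometry = list(ori = g_ori, sim = g_sim),
    mesh = list(ori = m_ori, sim = m_sim),
    field = list(ori = f_ori, sim = f_sim),
    fibers = fibers, lamina_s = lamina_s, tip_potentials = tip_v,
    profiles = list(ori = prof_ori, sim = prof_sim),
    comparison = cmp,
    decay_basal = decay_b, decay_apical = decay_a,
    stimulus = stim
  )
}
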