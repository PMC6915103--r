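# Activating-function analysis along reconstructed fibers.
#
# The extracellular potential sampled along a fiber is low-pass filtered with
# the steady-state cable kernel (a unit-area two-sided exponential with the
# myelinated-axon length constant), then differentiated with the uneven-
# spacing finite differences used for polyline-sampled data, and scaled into
# the activating function f = d/(4 rho_i c) * d2V/dx2 whose positive peaks
# mark candidate spike-initiation (depolarization) sites.

#' Passive cable constants of a myelinated spiral-ganglion axon
#'
#' @param rho_m_layer transmembrane resistivity per myelin layer
#'   (kOhm cm^2, default 1).
#' @param n_layers number of myelin layers (default 80).
#' @param rho_i intracellular (axoplasmic) resistivity (kOhm cm, default
#'   0.05).
#' @param a axon radius in micrometres (default 1).
#' @param d fiber diameter in micrometres (default `2 * a`).
#' @param c membrane capacity per unit length (F/cm); default derived from a
#'   1 uF/cm^2 specific membrane capacity divided by the myelin layer count.
#' @return an object of class `cable_constants`.
#' @export
cable_constants <- function(rho_m_layer = 1, n_layers = 80, rho_i = 0.05,
                            a = 1, d = 2 * a, c = NULL) {
  vals <- c(rho_m_layer = rho_m_layer, n_layers = n_layers, rho_i = rho_i,
            a = a, d = d)
  if (any(vals <= 0)) stop("all cable constants must be strictly positive")
  if (is.null(c)) {
    d_cm <- d * 1e-4
    c <- pi * d_cm * 1e-6 / n_layers  # F/cm of myelinated membrane
  }
  if (c <= 0) stop("membrane capacity must be strictly positive")
  structure(list(rho_m_layer = rho_m_layer, n_layers = n_layers,
                 rho_i = rho_i, a = a, d = d, c = c),
            class = "cable_constants")
}

#' Length constant of the myelinated axon
#'
#' lambda = sqrt(rho_m a / (2 rho_i)) with rho_m = n_layers x per-layer
#' resistivity. With the defaults (80 x 1 kOhm cm^2, 0.05 kOhm cm, a = 1 um)
#' lambda is about 2.83 mm.
#'
#' @param cc a [cable_constants()] object.
#' @return length constant in mm.
#' @export
length_constant <- function(cc = cable_constants()) {
  stopifnot(inherits(cc, "cable_constants"))
  rho_m <- cc$rho_m_layer * cc$n_layers     # kOhm cm^2
  a_cm <- cc$a * 1e-4
  lambda_cm <- sqrt(rho_m * a_cm / (2 * cc$rho_i))
  10 * lambda_cm                            # cm -> mm
}

#' Spatial low-pass filter with the cable length constant
#'
#' Discrete convolution along arclength with the unit-area two-sided
#' exponential kernel g(x) = exp(-|x|/lambda) / (2 lambda) (the steady-state
#' cable Green's function), using trapezoidal quadrature on the native,
#' possibly uneven spacing. The kernel is renormalized per sample so the DC
#' gain is exactly one, which also handles the fiber endpoints.
#'
#' @param v potential samples (V).
#' @param s strictly increasing arclength coordinates (mm).
#' @param lambda length constant (mm).
#' @return filtered samples, same length as `v`.
#' @export
lowpass_filter <- function(v, s, lambda = length_constant()) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (length(s) != length(v)) stop("s and v must have equal length")
  if (length(s) < 2L) return(v)
  if (any(diff(s) <= 0)) stop("s must be strictly increasing")
  n <- length(s)
  wtrap <- numeric(n)
  ds <- diff(s)
  wtrap[1L] <- ds[1L] / 2
  wtrap[n] <- ds[n - 1L] / 2
  if (n > 2L) wtrap[2:(n - 1L)] <- (ds[-1L] + ds[-(n - 1L)]) / 2
  G <- exp(-abs(outer(s, s, "-")) / lambda)
  num <- G %*% (wtrap * v)
  den <- G %*% wtrap
  as.numeric(num / den)
}

#' First spatial derivative (forward difference on uneven spacing)
#'
#' `V'_k = (V_{k+1} - V_k) / |r_{k,k+1}|`; the last node is undefined and
#' returned as `NA`.
#'
#' @param v potential samples.
#' @param s arclength coordinates (mm); for polyline-sampled fibers these
#'   are the cumulative chord lengths, so `diff(s)` is the inter-node
#'   distance.
#' @return derivative per node (V/mm), `NA` at the last node.
#' @export
first_derivative <- function(v, s) {
  if (length(v) < 2L) stop("need at least 2 nodes")
  if (length(s) != length(v)) stop("s and v must have equal length")
  n <- length(v)
  out <- rep(NA_real_, n)
  out[-n] <- diff(v) / diff(s)
  out
}

#' Second spatial derivative (uneven-spacing finite difference)
#'
#' `V''_k = ((V_{k+1}-V_k)/|r_{k,k+1}| - (V_k-V_{k-1})/|r_{k-1,k}|) /
#' (|r_{k-1,k+1}|/2)` at interior nodes; both endpoints are undefined and
#' returned as `NA` (never zero-filled).
#'
#' @param v potential samples.
#' @param s arclength coordinates (mm).
#' @param points optional n x 3 vertex coordinates; when given,
#'   `|r_{k-1,k+1}|` is the direct chord between nodes k-1 and k+1 rather
#'   than the arclength difference.
#' @return derivative per node (V/mm^2), `NA` at both endpoints.
#' @export
second_derivative <- function(v, s, points = NULL) {
  n <- length(v)
  if (n < 3L) stop("need at least 3 nodes")
  if (length(s) != n) stop("s and v must have equal length")
  fwd <- diff(v) / diff(s)                   # at k..k+1
  if (is.null(points)) {
    r13 <- s[3:n] - s[1:(n - 2L)]
  } else {
    r13 <- sqrt(rowSums((points[3:n, , drop = FALSE] -
                         points[1:(n - 2L), , drop = FALSE])^2))
  }
  out <- rep(NA_real_, n)
  out[2:(n - 1L)] <- (fwd[-1L] - fwd[-(n - 1L)]) / (r13 / 2)
  out
}

#' Activating function
#'
#' `f = d / (4 rho_i c) * d2V/dx2`. With the cable constants fixed along a
#' homogeneous axon, f is proportional to the second spatial derivative, so
#' its argmax coincides with the argmax of V''.
#'
#' @param v2 second-derivative samples (V/mm^2; `NA` kept as `NA`).
#' @param cc a [cable_constants()] object.
#' @return activating-function values, same length as `v2`.
#' @export
activating_function <- function(v2, cc = cable_constants()) {
  stopifnot(inherits(cc, "cable_constants"))
  d_cm <- cc$d * 1e-4
  rho_i_ohm <- cc$rho_i * 1e3                # kOhm cm -> Ohm cm
  scale <- d_cm / (4 * rho_i_ohm * cc$c)
  scale * v2
}

#' Activation profile along one fiber
#'
#' Samples the potential field at the fiber vertices and computes the
#' filtered potential, first and second derivatives, and activating
#' function.
#'
#' @param fiber a `fiber_path` (soma-annotated paths keep their region
#'   labels).
#' @param field a `potential_field`, or a numeric vector of potentials
#'   already sampled at the fiber vertices.
#' @param cc a [cable_constants()] object.
#' @param lambda filter length constant (mm); defaults to
#'   `length_constant(cc)`.
#' @return a data frame of class `activation_profile` with columns `s`, `V`,
#'   `V_filt`, `dV`, `d2V`, `f` and `region`.
#' @export
activation_profile <- function(fiber, field, cc = cable_constants(),
                               lambda = NULL) {
  stopifnot(inherits(fiber, "fiber_path"))
  lambda <- lambda %||% length_constant(cc)
  v <- if (is.numeric(field)) field else sample_potential(field, fiber$points)
  if (length(v) != length(fiber$s)) stop("mismatched sampling")
  vf <- lowpass_filter(v, fiber$s, lambda)
  dv <- first_derivative(vf, fiber$s)
  d2v <- second_derivative(vf, fiber$s, points = fiber$points)
  out <- data.frame(
    s = fiber$s, V = v, V_filt = vf, dV = dv, d2V = d2v,
    f = activating_function(d2v, cc),
    region = fiber$region %||% rep(NA_character_, length(v)),
    stringsAsFactors = FALSE
  )
  attr(out, "soma_center_arclength") <- fiber$soma_center_arclength
  attr(out, "lambda_mm") <- lambda
  class(out) <- c("activation_profile", "data.frame")
  out
}

#' Potential decay rate along the spiral lamina
#'
#' Least-squares fit of the normalized potential in dB,
#' `20 log10(|V| / max|V|)`, against lamina arclength on one side of the
#' stimulating electrode, skipping a near-field gap. The rate is reported as
#' a positive dB/mm of decline away from the electrode.
#'
#' @param s lamina arclength of each sample (mm).
#' @param v potential at each sample (V).
#' @param electrode_s lamina arclength of the stimulating contact (mm).
#' @param direction `"basal"` (toward decreasing s) or `"apical"`.
#' @param gap near-field exclusion around the electrode (mm, default 1).
#' @param window optional arclength interval (length 2) further restricting
#'   the fit.
#' @return an object of class `decay_fit` with fields `direction`,
#'   `rate_db_per_mm`, `r_squared`, `window` and `n`.
#' @export
decay_rate <- function(s, v, electrode_s,
                       direction = c("basal", "apical"), gap = 1,
                       window = NULL) {
  direction <- match.arg(direction)
  if (length(s) != length(v)) stop("s and v must have equal length")
  sel <- if (direction == "basal") s <= electrode_s - gap else
    s >= electrode_s + gap
  if (!is.null(window)) sel <- sel & s >= window[1L] & s <= window[2L]
  if (sum(sel) < 5L)
    stop("need at least 5 samples on the ", direction, " side of the electrode")
  if (any(abs(v[sel]) <= 0)) stop("window contains non-positive |V|")
  db <- 20 * log10(abs(v[sel]) / max(abs(v)))
  x <- if (direction == "basal") electrode_s - s[sel] else s[sel] - electrode_s
  fit <- stats::lm(db ~ x)
  ss_tot <- sum((db - mean(db))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(direction = direction,
         rate_db_per_mm = -unname(stats::coef(fit)[2L]),
         r_squared = r2,
         window = range(s[sel]), n = sum(sel)),
    class = "decay_fit"
  )
}

#' @exportS3Method base::print
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %s: %.4f dB/mm (R^2 = %.3f, n = %d, window %.2f-%.2f mm)\n",
              x$direction, x$rate_db_per_mm, x$r_squared, x$n,
              x$window[1L], x$window[2L]))
  invisible(x)
}

#' Compare detailed (ORI-style) and simplified (SIM-style) model profiles
#'
#' For matched fibers sampled at identical coordinates, computes the
#' relative difference of potential RD = (V_ori - V_sim) / max|V_ori| in
#' percent, the ratios of first- and second-derivative extrema
#' (detailed/simplified), the arclength segments where the second
#' derivatives have opposite sign, and the convergence arclength beyond
#' which their relative difference stays below `rd_tol` percent.
#'
#' @param ori,sim `activation_profile` objects or lists of them (matched by
#'   position).
#' @param rd_tol convergence tolerance for the second derivative, percent.
#' @param sign_floor fraction of the peak |V''| below which values are
#'   treated as numerically zero for the sign-flip search (default 0, exact
#'   signs).
#' @return an object of class `model_comparison`: per-fiber list with
#'   `max_abs_rd_percent`, `ratio_dV`, `ratio_d2V`, `sign_flip_segments`
#'   (two-column matrix of arclength intervals), `convergence_s`; plus
#'   aggregate maxima.
#' @export
compare_models <- function(ori, sim, rd_tol = 5, sign_floor = 0) {
  if (inherits(ori, "activation_profile")) ori <- list(ori)
  if (inherits(sim, "activation_profile")) sim <- list(sim)
  if (length(ori) != length(sim)) stop("mismatched sampling: fiber counts differ")
  per <- vector("list", length(ori))
  for (i in seq_along(ori)) {
    a <- ori[[i]]; b <- sim[[i]]
    if (nrow(a) != nrow(b) || max(abs(a$s - b$s)) > 1e-9)
      stop("mismatched sampling: fiber ", i,
           " is not sampled at identical coordinates")
    denom <- max(abs(a$V))
    rd <- (a$V - b$V) / denom * 100
    ext <- function(x) max(abs(range(x, na.rm = TRUE)))
    ratio_dv <- ext(a$dV) / ext(b$dV)
    ratio_d2v <- ext(a$d2V) / ext(b$d2V)
    ok <- !is.na(a$d2V) & !is.na(b$d2V)
    floor_val <- sign_floor * ext(a$d2V)
    flip <- ok & (a$d2V * b$d2V < 0) &
      abs(a$d2V) > floor_val & abs(b$d2V) > floor_val
    segs <- run_segments(a$s, flip)
    rd2 <- abs(a$d2V - b$d2V) / ext(a$d2V) * 100
    conv <- convergence_arclength(a$s, rd2, rd_tol)
    per[[i]] <- list(max_abs_rd_percent = max(abs(rd)),
                     ratio_dV = ratio_dv, ratio_d2V = ratio_d2v,
                     sign_flip_segments = segs, convergence_s = conv)
  }
  structure(
    list(per_fiber = per,
         max_abs_rd_percent = max(vapply(per, `[[`, 1, "max_abs_rd_percent")),
         max_ratio_dV = max(vapply(per, `[[`, 1, "ratio_dV")),
         max_ratio_d2V = max(vapply(per, `[[`, 1, "ratio_d2V")),
         n_sign_flip_segments = sum(vapply(per, function(p)
           nrow(p$sign_flip_segments), 1L))),
    class = "model_comparison"
  )
}

#' @keywords internal
run_segments <- function(s, flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (!length(on)) return(matrix(numeric(0), 0L, 2L,
                                 dimnames = list(NULL, c("s_start", "s_end"))))
  cbind(s_start = s[starts[on]], s_end = s[ends[on]])
}

#' @keywords internal
convergence_arclength <- function(s, rd2, rd_tol) {
  ok <- !is.na(rd2)
  bad <- which(ok & rd2 >= rd_tol)
  if (!length(bad)) return(s[which(ok)[1L]])
  last_bad <- max(bad)
  after <- which(ok & seq_along(s) > last_bad)
  if (!length(after)) return(NA_real_)
  s[after[1L]]
}

#' @exportS3Method base::print
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %d fibers: max |RD(V)| %.2f%%, dV' ratio up to %.2f, dV'' ratio up to %.2f, %d sign-flip segments\n",
              length(x$per_fiber), x$max_abs_rd_percent, x$max_ratio_dV,
              x$max_ratio_d2V, x$n_sign_flip_segments))
  invisible(x)
}
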