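# Polyline and point-cloud helpers shared by the geometry, meshing and
# fiber-tracing code. All coordinates are in mm.

#' Cumulative arclength of a polyline
#'
#' @param pts numeric matrix (n x 3) of ordered vertices.
#' @return numeric vector of length n; `[1] == 0`.
#' @keywords internal
polyline_arclength <- function(pts) {
  if (!is.matrix(pts) || ncol(pts) != 3L) stop("pts must be an n x 3 matrix")
  n <- nrow(pts)
  if (n < 2L) return(0)
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  c(0, cumsum(seg))
}

#' Interpolate points on a polyline at given arclengths
#' @keywords internal
polyline_interp <- function(pts, s_query) {
  s <- polyline_arclength(pts)
  s_query <- pmin(pmax(s_query, 0), s[length(s)])
  idx <- findInterval(s_query, s, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(pts) - 1L)
  ds <- s[idx + 1L] - s[idx]
  t <- ifelse(ds > 0, (s_query - s[idx]) / ds, 0)
  pts[idx, , drop = FALSE] * (1 - t) + pts[idx + 1L, , drop = FALSE] * t
}

#' Resample a polyline at roughly even spacing
#' @keywords internal
resample_polyline <- function(pts, spacing) {
  L <- polyline_arclength(pts)
  total <- L[length(L)]
  n <- max(2L, ceiling(total / spacing) + 1L)
  polyline_interp(pts, seq(0, total, length.out = n))
}

# Grid-binned nearest-neighbour query against a point cloud. Returns, for each
# query point, the index of the nearest cloud point and its distance, but only
# when that distance is <= max_dist (Inf / NA otherwise). Bin size equals
# max_dist so a 27-neighbourhood always covers the search radius.
#' @keywords internal
nearest_within <- function(query, cloud, max_dist) {
  nq <- nrow(query)
  res_d <- rep(Inf, nq)
  res_i <- rep(NA_integer_, nq)
  if (nq == 0L || nrow(cloud) == 0L) return(list(dist = res_d, index = res_i))
  h <- max_dist
  qb <- floor(query / h)
  cb <- floor(cloud / h)
  ckey <- paste(cb[, 1L], cb[, 2L], cb[, 3L])
  cenv <- new.env(hash = TRUE, parent = emptyenv())
  csplit <- split(seq_len(nrow(cloud)), ckey)
  for (k in names(csplit)) assign(k, csplit[[k]], envir = cenv)
  qkey <- paste(qb[, 1L], qb[, 2L], qb[, 3L])
  qsplit <- split(seq_len(nq), qkey)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (k in names(qsplit)) {
    qi <- qsplit[[k]]
    b <- qb[qi[1L], ]
    cand <- integer(0)
    for (r in seq_len(nrow(offs))) {
      nk <- paste(b[1L] + offs[r, 1L], b[2L] + offs[r, 2L], b[3L] + offs[r, 3L])
      v <- get0(nk, envir = cenv, inherits = FALSE)
      if (!is.null(v)) cand <- c(cand, v)
    }
    if (length(cand) == 0L) next
    qp <- query[qi, , drop = FALSE]
    cp <- cloud[cand, , drop = FALSE]
    d2 <- outer(rowSums(qp^2), rowSums(cp^2), "+") - 2 * tcrossprod(qp, cp)
    j <- max.col(-d2, ties.method = "first")
    dmin <- sqrt(pmax(d2[cbind(seq_along(qi), j)], 0))
    ok <- dmin <= max_dist
    res_d[qi[ok]] <- dmin[ok]
    res_i[qi[ok]] <- cand[j[ok]]
  }
  list(dist = res_d, index = res_i)
}

# Exact nearest neighbour (brute force, chunked); deterministic lowest-index
# tie-break. Used for seed snapping where exactness matters.
#' @keywords internal
nearest_bruteforce <- function(query, cloud) {
  nq <- nrow(query)
  idx <- integer(nq)
  dist <- numeric(nq)
  chunk <- max(1L, floor(2e7 / max(1L, nrow(cloud))))
  cs2 <- rowSums(cloud^2)
  for (start in seq(1L, nq, by = chunk)) {
    sel <- start:min(nq, start + chunk - 1L)
    qp <- query[sel, , drop = FALSE]
    d2 <- outer(rowSums(qp^2), cs2, "+") - 2 * tcrossprod(qp, cloud)
    for (r in seq_along(sel)) {
      dr <- d2[r, ]
      m <- min(dr)
      idx[sel[r]] <- which(dr == m)[1L]  # lowest index on exact ties
      dist[sel[r]] <- sqrt(max(m, 0))
    }
  }
  list(index = idx, dist = dist)
}

#' Build an orthonormal frame whose first axis is the given direction
#' @keywords internal
orthonormal_frame <- function(u) {
  u <- u / sqrt(sum(u^2))
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(
    u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L]
  )
  rbind(u, v, w)
}
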