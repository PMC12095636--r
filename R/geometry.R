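#' @name trap-network-geometry
#' @title Spatial support of the trap network
#'
#' @description
#' The spatial units of the suppression model are Voronoi cells around trap
#' locations, clipped to the site boundary. Cells sharing a border segment
#' of positive length are neighbors; the resulting contiguity graph defines
#' the intrinsic conditional autoregressive (ICAR) precision, whose
#' generalized inverse under the sum-to-zero constraint gives the BYM2
#' scaling factor. All geometry is planar (meters in a local projection);
#' the sites are small enough (tens of hectares) that geodesic effects are
#' negligible.
NULL

#' Shoelace area of a polygon
#'
#' @param poly two-column matrix of vertices (open ring).
#' @return non-negative area.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Point-in-polygon test (ray casting; boundary points count as inside)
#'
#' @param pts two-column matrix of query points.
#' @param poly two-column matrix of polygon vertices (open ring).
#' @return logical vector.
#' @export
point_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  jx <- px[c(n, seq_len(n - 1))]; jy <- py[c(n, seq_len(n - 1))]
  apply(pts, 1, function(p) {
    crosses <- ((py > p[2]) != (jy > p[2])) &
      (p[1] < (jx - px) * (p[2] - py) / (jy - py) + px)
    sum(crosses) %% 2 == 1
  })
}

# TRUE if no two non-adjacent edges intersect
is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1 else i + 1, ])
  for (i in seq_len(n - 1)) for (k in seq((i + 1), n)) {
    if (k == i || k == i + 1 || (i == 1 && k == n)) next
    if (.segments_cross(seg(i), seg(k))) return(FALSE)
  }
  TRUE
}

.segments_cross <- function(s1, s2) {
  d1 <- s1[2, ] - s1[1, ]; d2 <- s2[2, ] - s2[1, ]
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) return(FALSE)
  t <- ((s2[1, 1] - s1[1, 1]) * d2[2] - (s2[1, 2] - s1[1, 2]) * d2[1]) / den
  u <- ((s2[1, 1] - s1[1, 1]) * d1[2] - (s2[1, 2] - s1[1, 2]) * d1[1]) / den
  t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
}

# clip polygon (open ring) to half-plane {x : a.x <= c} (Sutherland-Hodgman)
clip_halfplane <- function(poly, a, c, tol = 1e-9) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  f <- as.numeric(poly %*% a) - c
  keep <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (f[i] <= tol) keep[[length(keep) + 1]] <- poly[i, ]
    if ((f[i] < -tol && f[j] > tol) || (f[i] > tol && f[j] < -tol)) {
      t <- f[i] / (f[i] - f[j])
      keep[[length(keep) + 1]] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (!length(keep)) return(matrix(numeric(0), 0, 2))
  out <- do.call(rbind, keep)
  # drop consecutive duplicates (incl. wrap-around)
  n <- nrow(out)
  if (n > 1) {
    d <- sqrt(rowSums((out - out[c(2:n, 1), , drop = FALSE])^2))
    scale <- max(abs(out)) + 1
    out <- out[d > 1e-12 * scale, , drop = FALSE]
  }
  out
}

#' Voronoi tessellation of trap locations clipped to a site boundary
#'
#' Each trap's cell is the set of boundary points nearer to it than to any
#' other trap, computed by successive half-plane clipping of the boundary
#' polygon against the perpendicular bisectors. The cells partition the
#' boundary.
#'
#' @param traps two-column matrix (or data frame with columns `x`, `y`) of
#'   trap coordinates, all strictly inside `boundary`, no duplicates.
#' @param boundary two-column matrix of boundary polygon vertices (open ring).
#' @return list of two-column matrices, one clipped cell per trap, in trap
#'   order.
#' @export
voronoi_cells <- function(traps, boundary) {
  traps <- .as_xy(traps)
  boundary <- as.matrix(boundary)
  J <- nrow(traps)
  if (J < 1) stop("at least one trap is required")
  dmat <- as.matrix(stats::dist(traps))
  scale <- max(dmat, 1e-12)
  if (J > 1 && min(dmat[upper.tri(dmat)]) < 1e-9 * scale)
    stop("duplicate trap locations")
  inside <- point_in_polygon(traps, boundary)
  if (!all(inside))
    stop("traps outside the site boundary: ", paste(which(!inside), collapse = ", "))
  lapply(seq_len(J), function(j) {
    cell <- boundary
    for (k in seq_len(J)) {
      if (k == j) next
      a <- traps[k, ] - traps[j, ]
      c <- sum(a * (traps[j, ] + traps[k, ])) / 2
      cell <- clip_halfplane(cell, a, c)
      if (nrow(cell) < 3) stop("degenerate cell for trap ", j)
    }
    cell
  })
}

#' Contiguity graph from Voronoi cells
#'
#' Two cells are neighbors iff they share a border segment of positive
#' length; cells meeting only at a point are not neighbors. Each cell edge
#' is attributed to the perpendicular bisector it lies on (midpoint
#' equidistant from the two nearest traps).
#'
#' @param cells list of cell polygons from [voronoi_cells()].
#' @param traps trap coordinates matching `cells`.
#' @return symmetric binary adjacency matrix (J x J, zero diagonal).
#' @export
adjacency_from_cells <- function(cells, traps) {
  traps <- .as_xy(traps)
  J <- nrow(traps)
  stopifnot(length(cells) == J)
  scale <- max(apply(traps, 2, function(z) diff(range(z))), 1e-12)
  tol <- 1e-6 * scale
  A <- matrix(0L, J, J)
  for (j in seq_len(J)) {
    cell <- cells[[j]]
    n <- nrow(cell)
    for (e in seq_len(n)) {
      p1 <- cell[e, ]; p2 <- cell[if (e == n) 1 else e + 1, ]
      if (sqrt(sum((p1 - p2)^2)) <= tol) next  # zero-length: point contact only
      mid <- (p1 + p2) / 2
      d <- sqrt(rowSums((traps - matrix(mid, J, 2, byrow = TRUE))^2))
      near <- which(d <= d[j] + tol)
      k <- setdiff(near, j)
      if (length(k) == 1 && abs(d[k] - d[j]) <= tol) A[j, k] <- A[k, j] <- 1L
    }
  }
  dimnames(A) <- list(rownames(traps), rownames(traps))
  A
}

#' ICAR precision matrix of a contiguity graph
#'
#' The graph Laplacian: degree on the diagonal, -1 for neighbors. Rows sum
#' to zero; for a connected graph the null space is the constant vector.
#' Degree-zero nodes are flagged with a warning (the intrinsic field is
#' undefined for them; they receive only the unstructured BYM2 component).
#'
#' @param adjacency symmetric binary adjacency matrix.
#' @return sparse symmetric precision matrix (`Matrix::dgCMatrix`).
#' @export
icar_precision <- function(adjacency) {
  A <- as.matrix(adjacency)
  if (!isSymmetric(unname(A))) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency must have no self-loops")
  deg <- rowSums(A)
  if (nrow(A) > 1 && any(deg == 0))
    warning("isolated node(s) in contiguity graph: ",
            paste(which(deg == 0), collapse = ", "))
  Matrix::Matrix(diag(deg, nrow(A)) - A, sparse = TRUE)
}

#' BYM2 scaling factor of an ICAR precision
#'
#' The geometric mean of the marginal variances of the intrinsic field
#' under the sum-to-zero constraint, i.e. of the diagonal of the
#' constrained generalized inverse of Q. Dividing the field by the square
#' root of this factor standardizes it so its marginal variances have
#' geometric mean one, making the BYM2 standard deviation interpretable on
#' a common scale. For a disconnected graph the factor is computed per
#' connected component (with a warning); isolated nodes get NA.
#'
#' @param Q ICAR precision matrix from [icar_precision()].
#' @return scalar scaling factor for a connected graph; otherwise a
#'   per-node vector.
#' @export
bym2_scaling_factor <- function(Q) {
  Q <- as.matrix(Q)
  comps <- graph_components(Q)
  ncomp <- length(unique(comps))
  marg <- rep(NA_real_, nrow(Q))
  for (cid in unique(comps)) {
    idx <- which(comps == cid)
    if (length(idx) == 1) next  # isolated: intrinsic field undefined
    Sigma <- MASS::ginv(Q[idx, idx, drop = FALSE])
    marg[idx] <- diag(Sigma)
  }
  if (ncomp == 1) return(exp(mean(log(marg))))
  warning("disconnected contiguity graph: per-component BYM2 scaling")
  out <- rep(NA_real_, nrow(Q))
  for (cid in unique(comps)) {
    idx <- which(comps == cid)
    if (length(idx) > 1) out[idx] <- exp(mean(log(marg[idx])))
  }
  out
}

# connected component labels from a precision/adjacency structure
graph_components <- function(Q) {
  A <- as.matrix(Q) != 0
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::components(g)$membership
}

#' Build the full spatial support of a trap network
#'
#' Tessellates the site, derives the contiguity graph, the ICAR precision,
#' its BYM2 scaling, and the eigenbasis of the precision restricted to the
#' (per-component) sum-to-zero subspace used by both the simulator and the
#' posterior sampler.
#'
#' @param traps data frame with columns `trap_id`, `x`, `y` (or a matrix of
#'   coordinates).
#' @param boundary optional boundary polygon; if `NULL`, the convex hull of
#'   the traps buffered by the median nearest-neighbor distance is used.
#' @return an object of class `"trap_network"`.
#' @export
build_trap_network <- function(traps, boundary = NULL) {
  if (is.matrix(traps)) traps <- data.frame(trap_id = as.character(seq_len(nrow(traps))),
                                            x = traps[, 1], y = traps[, 2])
  stopifnot(all(c("trap_id", "x", "y") %in% names(traps)))
  xy <- cbind(traps$x, traps$y)
  if (is.null(boundary)) boundary <- default_boundary(xy)
  cells <- voronoi_cells(xy, boundary)
  A <- adjacency_from_cells(cells, xy)
  Q <- suppressWarnings(icar_precision(A))
  scaling <- suppressWarnings(bym2_scaling_factor(Q))
  eig <- .icar_eigen(as.matrix(Q), scaling)
  structure(list(
    traps = data.frame(trap_id = as.character(traps$trap_id), x = traps$x, y = traps$y,
                       stringsAsFactors = FALSE),
    boundary = boundary, cells = cells, adjacency = A, Q = Q,
    scaling_factor = scaling, basis = eig
  ), class = "trap_network")
}

# eigenbasis of Q on the sum-to-zero subspace; zprec[i] is the prior
# precision of the i-th coefficient of the *scaled* field w* = U z,
# i.e. zprec = s_comp * lambda so that Var(w*) has geometric mean 1.
.icar_eigen <- function(Q, scaling) {
  J <- nrow(Q)
  eig <- eigen(Q, symmetric = TRUE)
  tol <- 1e-8 * max(abs(eig$values), 1)
  pos <- eig$values > tol
  U <- eig$vectors[, pos, drop = FALSE]
  lambda <- eig$values[pos]
  if (length(scaling) == 1) {
    zprec <- scaling * lambda
  } else {
    comps <- graph_components(Q)
    svec <- scaling
    zprec <- vapply(seq_along(lambda), function(i) {
      nodes <- which(abs(U[, i]) > 1e-9)
      s <- svec[comps[nodes[1]]]
      if (is.na(s)) s <- 1
      s * lambda[i]
    }, numeric(1))
  }
  list(U = U, lambda = lambda, zprec = zprec)
}

# convex hull of traps buffered by the median nearest-neighbor distance
default_boundary <- function(xy) {
  xy <- .as_xy(xy)
  if (nrow(xy) == 1) {
    r <- 1
  } else {
    d <- as.matrix(stats::dist(xy)); diag(d) <- Inf
    r <- stats::median(apply(d, 1, min))
  }
  ang <- seq(0, 2 * pi, length.out = 33)[-33]
  pts <- do.call(rbind, lapply(seq_len(nrow(xy)), function(i)
    cbind(xy[i, 1] + r * cos(ang), xy[i, 2] + r * sin(ang))))
  pts[grDevices::chull(pts), , drop = FALSE]
}

.as_xy <- function(p) {
  if (is.data.frame(p)) p <- cbind(p$x, p$y)
  matrix(as.numeric(p), ncol = 2)
}

#' @export
print.trap_network <- function(x, ...) {
  J <- nrow(x$traps)
  cat(sprintf("trap network: %d traps, %d contiguity edges, site area %.2f ha\n",
              J, sum(x$adjacency) / 2, polygon_area(x$boundary) / 1e4))
  if (length(x$scaling_factor) == 1)
    cat(sprintf("ICAR scaling factor: %.4f\n", x$scaling_factor))
  else cat("ICAR scaling: per-component (disconnected graph)\n")
  invisible(x)
}

#' Export cells (or any polygon set) with values as GeoJSON
#'
#' Writes a GeoJSON FeatureCollection, one Polygon feature per cell, each
#' carrying the supplied properties.
#'
#' @param cells list of two-column matrices (open rings).
#' @param values numeric vector (or data frame of per-cell properties), one
#'   entry/row per cell.
#' @param path output path.
#' @param value_name property name used when `values` is a plain vector.
#' @return `path`, invisibly.
#' @export
write_choropleth <- function(cells, values, path, value_name = "value") {
  props <- if (is.data.frame(values)) values else
    stats::setNames(data.frame(values), value_name)
  if (length(cells) != nrow(props))
    stop("length mismatch: ", length(cells), " cells vs ", nrow(props), " values")
  features <- lapply(seq_along(cells), function(i) {
    ring <- rbind(cells[[i]], cells[[i]][1, , drop = FALSE])  # close ring
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(r) as.numeric(ring[r, ])))),
         properties = as.list(props[i, , drop = FALSE]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a GeoJSON choropleth
#'
#' Reads a FeatureCollection written by [write_choropleth()].
#'
#' @param path GeoJSON path.
#' @return list with `cells` (list of open-ring matrices) and `properties`
#'   (data frame).
#' @export
read_choropleth <- function(path) {
  fc <- jsonlite::read_json(path)
  stopifnot(identical(fc$type, "FeatureCollection"))
  cells <- lapply(fc$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(p)
      c(p[[1]], p[[2]])))
    ring[-nrow(ring), , drop = FALSE]  # reopen ring
  })
  props <- do.call(rbind, lapply(fc$features, function(f)
    as.data.frame(lapply(f$properties, function(v) if (is.null(v)) NA else v))))
  list(cells = cells, properties = props)
}

#' Export a contiguity graph as an edge list
#'
#' @param adjacency symmetric adjacency matrix.
#' @param path output path for a two-column whitespace-separated edge list.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(adjacency, path) {
  A <- as.matrix(adjacency)
  idx <- which(A != 0 & upper.tri(A), arr.ind = TRUE)
  utils::write.table(idx, path, row.names = FALSE, col.names = c("from", "to"),
                     quote = FALSE)
  invisible(path)
}
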