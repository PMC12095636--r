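test_that("a single trap's cell is the whole boundary", {
  cells <- voronoi_cells(matrix(c(0.4, 0.6), 1), unit_square)
  expect_equal(polygon_area(cells[[1]]), 1, tolerance = 1e-12)
})

test_that("two traps symmetric about the center split a unit square in half", {
  cells <- voronoi_cells(rbind(c(0.25, 0.5), c(0.75, 0.5)), unit_square)
  expect_equal(vapply(cells, polygon_area, numeric(1)), c(0.5, 0.5),
               tolerance = 1e-12)
})

test_that("random tessellations partition the boundary and contain their seeds", {
  for (seed in 1:5) {
    set.seed(seed)
    pts <- cbind(runif(5, 0.05, 0.95), runif(5, 0.05, 0.95))
    cells <- voronoi_cells(pts, unit_square)
    areas <- vapply(cells, polygon_area, numeric(1))
    expect_equal(sum(areas), 1, tolerance = 1e-6)
    for (j in 1:5)
      expect_true(point_in_polygon(pts[j, , drop = FALSE], cells[[j]]))
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(voronoi_cells(rbind(c(0.5, 0.5), c(0.5, 0.5)), unit_square),
               "duplicate")
  expect_error(voronoi_cells(rbind(c(0.5, 0.5), c(1.5, 0.5)), unit_square),
               "outside")
})

test_that("tessellation is permutation-equivariant", {
  # rings may start at a different vertex; compare canonical rotations
  canon <- function(ring) {
    i <- order(round(ring[, 1], 9), round(ring[, 2], 9))[1]
    n <- nrow(ring)
    ring[((seq_len(n) + i - 2) %% n) + 1, , drop = FALSE]
  }
  set.seed(3)
  pts <- cbind(runif(6, 0.1, 0.9), runif(6, 0.1, 0.9))
  perm <- c(4, 1, 6, 2, 5, 3)
  cells <- voronoi_cells(pts, unit_square)
  cells_p <- voronoi_cells(pts[perm, ], unit_square)
  for (k in seq_along(perm)) {
    a <- canon(cells_p[[k]]); b <- canon(cells[[perm[k]]])
    same <- isTRUE(all.equal(a, b, tolerance = 1e-9)) ||
      isTRUE(all.equal(canon(a[nrow(a):1, ]), b, tolerance = 1e-9))
    expect_true(same)
  }
})

test_that("adjacency requires a shared border of positive length", {
  # two half-squares share one edge
  pts2 <- rbind(c(0.25, 0.5), c(0.75, 0.5))
  A2 <- adjacency_from_cells(voronoi_cells(pts2, unit_square), pts2)
  expect_equal(A2, matrix(c(0L, 1L, 1L, 0L), 2), ignore_attr = TRUE)
  # three collinear traps form a path graph
  pts3 <- rbind(c(0.2, 0.5), c(0.5, 0.5), c(0.8, 0.5))
  A3 <- adjacency_from_cells(voronoi_cells(pts3, unit_square), pts3)
  expect_equal(A3, matrix(c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L), 3),
               ignore_attr = TRUE)
  # 2x2 symmetric grid: 4-cycle, diagonal cells meet only at the center point
  pts4 <- rbind(c(0.25, 0.25), c(0.75, 0.25), c(0.25, 0.75), c(0.75, 0.75))
  A4 <- adjacency_from_cells(voronoi_cells(pts4, unit_square), pts4)
  expect_equal(sum(A4), 8L)            # 4 undirected edges
  expect_equal(A4[1, 4], 0L)           # diagonals not adjacent
  expect_equal(A4[2, 3], 0L)
})

test_that("adjacency from a convex site is connected", {
  for (seed in 1:3) {
    set.seed(seed)
    pts <- cbind(runif(8, 0.05, 0.95), runif(8, 0.05, 0.95))
    A <- adjacency_from_cells(voronoi_cells(pts, unit_square), pts)
    comp <- boostsit:::graph_components(A + diag(0, 8))
    expect_equal(length(unique(comp)), 1)
  }
})

test_that("the ICAR precision is the graph Laplacian", {
  Ap <- matrix(0, 3, 3); Ap[1, 2] <- Ap[2, 1] <- Ap[2, 3] <- Ap[3, 2] <- 1
  expect_equal(as.matrix(icar_precision(Ap)),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)),
               ignore_attr = TRUE)
  Ak <- matrix(1, 3, 3); diag(Ak) <- 0
  Qk <- as.matrix(icar_precision(Ak))
  expect_equal(diag(Qk), rep(2, 3))
  expect_equal(Qk[upper.tri(Qk)], rep(-1, 3))
  expect_error(icar_precision(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("Q satisfies the pairwise-difference identity and annihilates constants", {
  set.seed(9)
  pts <- cbind(runif(7, 0.05, 0.95), runif(7, 0.05, 0.95))
  A <- adjacency_from_cells(voronoi_cells(pts, unit_square), pts)
  Q <- as.matrix(icar_precision(A))
  expect_equal(rowSums(Q), rep(0, 7))
  expect_equal(as.numeric(Q %*% rep(2.5, 7)), rep(0, 7))
  for (r in 1:5) {
    x <- rnorm(7)
    edges <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
    expect_equal(as.numeric(t(x) %*% Q %*% x),
                 sum((x[edges[, 1]] - x[edges[, 2]])^2))
  }
})

test_that("the BYM2 scaling factor matches a dense pseudo-inverse oracle", {
  # path graph of 3
  Ap <- matrix(0, 3, 3); Ap[1, 2] <- Ap[2, 1] <- Ap[2, 3] <- Ap[3, 2] <- 1
  Q <- icar_precision(Ap)
  s <- bym2_scaling_factor(Q)
  oracle <- exp(mean(log(diag(MASS::ginv(as.matrix(Q))))))
  expect_equal(s, oracle, tolerance = 1e-10)
  # complete graphs: all marginal variances equal, so scaling gives exactly 1
  for (J in c(3, 5, 6)) {
    Ak <- matrix(1, J, J); diag(Ak) <- 0
    Qk <- icar_precision(Ak)
    sk <- bym2_scaling_factor(Qk)
    expect_equal(diag(MASS::ginv(as.matrix(Qk))) / sk, rep(1, J),
                 tolerance = 1e-8)
  }
})

test_that("after scaling, marginal variances have geometric mean one", {
  set.seed(12)
  pts <- cbind(runif(6, 0.05, 0.95), runif(6, 0.05, 0.95))
  net <- build_trap_network(data.frame(trap_id = letters[1:6],
                                       x = pts[, 1], y = pts[, 2]),
                            unit_square)
  Sigma <- MASS::ginv(as.matrix(net$Q)) / net$scaling_factor
  expect_equal(exp(mean(log(diag(Sigma)))), 1, tolerance = 1e-10)
})

test_that("a disconnected graph is scaled per component with a warning", {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 1; A[3, 4] <- A[4, 3] <- 1
  Q <- suppressWarnings(icar_precision(A))
  expect_warning(s <- bym2_scaling_factor(Q), "disconnected")
  expect_length(s, 4)
  expect_equal(s[1], s[2])
  expect_equal(s[3], s[4])
})

test_that("choropleth export round-trips values to 6 decimals", {
  net <- two_trap_network()
  path <- withr::local_tempfile(fileext = ".geojson")
  vals <- c(0.1234567, 0.9876543)
  write_choropleth(net$cells, vals, path)
  back <- read_choropleth(path)
  expect_length(back$cells, 2)
  expect_equal(back$properties$value, vals, tolerance = 1e-7)
  expect_equal(back$cells[[1]], net$cells[[1]], ignore_attr = TRUE)
  # length mismatch and empty collections
  expect_error(write_choropleth(net$cells, c(1, 2, 3), path), "mismatch")
  write_choropleth(list(), numeric(0), path)
  expect_length(read_choropleth(path)$cells, 0)
})
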