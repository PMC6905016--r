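# Small meshes built in code for the unit tests.

# structured triangulation of [0, Lx] x [0, Ly] with nx x ny quads
square_mesh <- function(nx = 8L, ny = nx, Lx = 1, Ly = 1) {
  xs <- seq(0, Lx, length.out = nx + 1L)
  ys <- seq(0, Ly, length.out = ny + 1L)
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  nodes <- cbind(rep(xs, times = ny + 1L), rep(ys, each = nx + 1L))
  tris <- vector("list", nx * ny)
  k <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    a <- id(i, j); b <- id(i + 1L, j); c <- id(i + 1L, j + 1L); d <- id(i, j + 1L)
    k <- k + 1L
    tris[[k]] <- if ((i + j) %% 2L == 0L) rbind(c(a, b, c), c(a, c, d))
                 else rbind(c(a, b, d), c(b, c, d))
  }
  wall_mesh(nodes, do.call(rbind, tris))
}

# single unit right triangle (legs 1), the reference element
unit_triangle_mesh <- function() {
  wall_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)), rbind(c(1L, 2L, 3L)))
}

# mesh-free stand-in carrying only a triangle count (for selection logic)
dummy_mesh <- function(m) {
  structure(list(triangles = matrix(1L, m, 3L)), class = "wall_mesh")
}

# nodes of a square mesh lying on the boundary
square_boundary_nodes <- function(mesh) {
  sort(unique(as.vector(mesh$boundary_edges)))
}

# order-2 Gauss (edge-midpoint) quadrature on a triangle: exact for
# quadratics; independent oracle for element mass/stiffness entries
quad2_integrate <- function(xy, f) {
  mids <- (xy[c(1, 2, 3), ] + xy[c(2, 3, 1), ]) / 2
  A <- abs((xy[2, 1] - xy[1, 1]) * (xy[3, 2] - xy[1, 2]) -
           (xy[3, 1] - xy[1, 1]) * (xy[2, 2] - xy[1, 2])) / 2
  A / 3 * sum(apply(mids, 1L, function(p) f(p[1], p[2])))
}

# P1 hat-function factory on a triangle
hat_fun <- function(xy, i) {
  M <- cbind(1, xy)
  coef <- solve(M, as.numeric(seq_len(3) == i))
  function(x, y) coef[1] + coef[2] * x + coef[3] * y
}
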