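test_that("P1 mass matrix matches the closed form and partitions unity", {
  tm <- unit_triangle_mesh()
  M <- as.matrix(assemble_mass(tm))
  A <- 0.5
  expect_equal(M, A / 12 * matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3),
               tolerance = 1e-14)
  expect_equal(as.matrix(assemble_mass(tm, 0)), matrix(0, 3, 3))

  m <- generate_wall_mesh(2, 3, pi / 3, 0.2)
  expect_equal(sum(assemble_mass(m, 2.5)), 2.5 * mesh_area(m), tolerance = 1e-12)
})

test_that("element mass and stiffness agree with order-2 Gauss quadrature", {
  set.seed(4)
  xy <- matrix(runif(6, -1, 2), 3, 2)
  m1 <- wall_mesh(xy, rbind(1:3))
  M <- as.matrix(assemble_mass(m1))
  K <- as.matrix(assemble_diffusion(m1, 1.7))
  for (i in 1:3) for (j in 1:3) {
    fi <- hat_fun(m1$nodes, i); fj <- hat_fun(m1$nodes, j)
    expect_equal(M[i, j],
                 quad2_integrate(m1$nodes, function(x, y) fi(x, y) * fj(x, y)),
                 tolerance = 1e-12)
  }
  # gradients are constant: stiffness entry = 1.7 * A * grad_i . grad_j
  g <- function(i) {
    co <- solve(cbind(1, m1$nodes), as.numeric(seq_len(3) == i))
    co[2:3]
  }
  A <- m1$element_areas
  for (i in 1:3) for (j in 1:3)
    expect_equal(K[i, j], 1.7 * A * sum(g(i) * g(j)), tolerance = 1e-12)
})

test_that("stiffness annihilates constants and reproduces Dirichlet energy", {
  tm <- unit_triangle_mesh()
  K <- as.matrix(assemble_diffusion(tm))
  expect_equal(K, 0.5 * matrix(c(2, -1, -1, -1, 1, 0, -1, 0, 1), 3),
               tolerance = 1e-14)
  m <- square_mesh(6)
  K <- assemble_diffusion(m, 3.0)
  expect_lt(max(abs(K %*% rep(1, nrow(m$nodes)))), 1e-12)
  u <- m$nodes[, 1]  # u = x, unit gradient
  expect_equal(as.numeric(t(u) %*% K %*% u), 3.0 * mesh_area(m),
               tolerance = 1e-12)
  expect_equal(sum(abs(assemble_diffusion(m, 0))), 0)
  expect_error(assemble_diffusion(m, matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("advection operator vanishes for zero velocity and conserves mass", {
  m <- square_mesh(3)
  v0 <- matrix(0, nrow(m$triangles), 2)
  expect_equal(sum(abs(assemble_advection_supg(m, v0, 1e-3))), 0)

  v <- cbind(rep(1, nrow(m$triangles)), rep(0.5, nrow(m$triangles)))
  G <- assemble_advection_supg(m, v, 1e-3)
  # interior rows of the pure-advection part sum to zero (divergence-free v)
  interior <- setdiff(seq_len(nrow(m$nodes)), square_boundary_nodes(m))
  rs <- rowSums(as.matrix(G))
  expect_lt(max(abs(rs[interior])), 1e-12)
  # column sums vanish everywhere: total mass is conserved by transport
  expect_lt(max(abs(colSums(as.matrix(G)))), 1e-12)
  expect_error(assemble_advection_supg(m, v * Inf, 1e-3), "finite")
})

test_that("SUPG keeps the steady advection-diffusion profile monotone at Pe = 10", {
  nx <- 20L
  m <- square_mesh(nx, 2L, Lx = 1, Ly = 0.1)
  h <- 1 / nx
  D <- 1e-3
  vmag <- 10 * 2 * D / h  # element Peclet ~ 10 along the flow
  v <- cbind(rep(vmag, nrow(m$triangles)), 0)
  A <- assemble_diffusion(m, D) + assemble_advection_supg(m, v, D)
  x <- m$nodes[, 1]
  left <- which(x < 1e-12); right <- which(x > 1 - 1e-12)
  bc <- apply_dirichlet(A, numeric(nrow(m$nodes)),
                        c(left, right), c(rep(0, length(left)), rep(1, length(right))))
  u <- solve_linear_system(bc$op, bc$rhs)
  for (yv in unique(round(m$nodes[, 2], 9))) {
    row <- which(abs(m$nodes[, 2] - yv) < 1e-9)
    prof <- u[row][order(x[row])]
    # monotone along the flow up to a sub-percent crosswind wiggle
    expect_true(all(diff(prof) > -5e-3))
  }
  # compares against the exact exponential-layer solution at the nodes
  pe <- vmag / D
  exact <- (exp(pe * x) - 1) / (exp(pe) - 1)
  expect_lt(max(abs(u - exact)[x > 1 - 3.5 * h]), 0.35)  # layer resolved to O(1)
  expect_lt(max(abs(u[x < 0.5])), 0.05)                  # upstream plateau flat
})

test_that("elasticity operator annihilates translations and passes the patch test", {
  m <- square_mesh(5)
  n <- nrow(m$nodes)
  for (form in c("grad_div", "full_stress")) {
    K <- assemble_vector_elasticity(m, 204.7, 23.3, form = form)
    expect_lt(max(abs(K %*% c(rep(1, n), rep(0, n)))), 1e-10)
    expect_lt(max(abs(K %*% c(rep(0, n), rep(1, n)))), 1e-10)
    expect_lt(max(abs(K - t(K))), 1e-10)

    # linear displacement imposed on the boundary is reproduced exactly
    ux <- 0.3 * m$nodes[, 1] + 0.1 * m$nodes[, 2]
    uy <- -0.2 * m$nodes[, 1] + 0.4 * m$nodes[, 2]
    bn <- square_boundary_nodes(m)
    bdofs <- c(bn, bn + n)
    bc <- apply_dirichlet(K, numeric(2 * n), bdofs, c(ux[bn], uy[bn]))
    u <- solve_linear_system(bc$op, bc$rhs)
    expect_equal(u, c(ux, uy), tolerance = 1e-9)
  }
  expect_error(assemble_vector_elasticity(m, 1, -1), "non-physical")
})

test_that("manufactured displacement solution converges at second order", {
  lam <- 2; mu <- 1
  err <- sapply(c(8L, 16L), function(nn) {
    m <- square_mesh(nn)
    n <- nrow(m$nodes)
    K <- assemble_vector_elasticity(m, lam, mu)
    # U = (sin(pi x) sin(pi y), 0):
    # f_x = -(lam+mu) dx(div U) - mu lap U_x, f_y = -(lam+mu) dy(div U)
    fx <- function(x, y) (lam + mu) * pi^2 * sin(pi * x) * sin(pi * y) +
      mu * 2 * pi^2 * sin(pi * x) * sin(pi * y)
    fy <- function(x, y) -(lam + mu) * pi^2 * cos(pi * x) * cos(pi * y)
    fem <- fem_precompute(m)
    cx <- (m$nodes[fem$tri[, 1], ] + m$nodes[fem$tri[, 2], ] +
           m$nodes[fem$tri[, 3], ]) / 3
    load <- numeric(2 * n)
    for (k in 1:3) {
      idx <- fem$tri[, k]
      load[seq_len(n)] <- load[seq_len(n)] +
        unname(tapply(fx(cx[, 1], cx[, 2]) * fem$areas / 3, idx, sum)[as.character(seq_len(n))]) |>
        (\(v) ifelse(is.na(v), 0, v))()
      load[n + seq_len(n)] <- load[n + seq_len(n)] +
        unname(tapply(fy(cx[, 1], cx[, 2]) * fem$areas / 3, idx, sum)[as.character(seq_len(n))]) |>
        (\(v) ifelse(is.na(v), 0, v))()
    }
    bn <- square_boundary_nodes(m)
    bc <- apply_dirichlet(K, load, c(bn, bn + n), 0)
    u <- solve_linear_system(bc$op, bc$rhs)
    uex <- c(sin(pi * m$nodes[, 1]) * sin(pi * m$nodes[, 2]), numeric(n))
    M <- assemble_mass(m)
    e <- u - uex
    sqrt(sum(e[seq_len(n)] * (M %*% e[seq_len(n)])) +
         sum(e[n + seq_len(n)] * (M %*% e[n + seq_len(n)])))
  })
  rate <- log2(err[1] / err[2])
  expect_gt(rate, 1.5)
  expect_lt(rate, 2.8)
})

test_that("Dirichlet elimination is exact and leaves unconstrained systems alone", {
  m <- square_mesh(4)
  n <- nrow(m$nodes)
  K <- assemble_diffusion(m, 1) + assemble_mass(m, 1)
  b <- runif(n)
  bc <- apply_dirichlet(K, b, integer(0))
  expect_identical(bc$op, K)

  all_bc <- apply_dirichlet(K, b, seq_len(n), 0)
  expect_equal(solve_linear_system(all_bc$op, all_bc$rhs), rep(0, n))

  some <- c(1L, 5L)
  bc2 <- apply_dirichlet(K, b, some, c(2, 3))
  u <- solve_linear_system(bc2$op, bc2$rhs)
  expect_equal(u[some], c(2, 3), tolerance = 1e-14)
  expect_lt(max(abs(bc2$op - t(bc2$op))), 1e-14)

  expect_error(apply_dirichlet(K, b, c(1L, 1L), c(0, 1)), "conflicting")
})

test_that("the 1D Poisson analogue with unit source matches x(L-x)/2", {
  # thin strip, u = 0 at both ends, zero-flux top/bottom: effectively 1D
  nx <- 16L
  m <- square_mesh(nx, 1L, Lx = 1, Ly = 1 / nx)
  n <- nrow(m$nodes)
  K <- assemble_diffusion(m, 1)
  fem <- fem_precompute(m)
  load <- poroedema:::elem_load(fem, rep(1, nrow(m$triangles)))
  x <- m$nodes[, 1]
  ends <- which(x < 1e-12 | x > 1 - 1e-12)
  bc <- apply_dirichlet(K, load, ends, 0)
  u <- solve_linear_system(bc$op, bc$rhs)
  # the 2D triangulated strip is not the pure 1D operator, so nodal values
  # carry a small cross-coupling error rather than being exact
  expect_equal(u, x * (1 - x) / 2, tolerance = 2e-3)
  expect_lt(max(abs(u - x * (1 - x) / 2)), 5e-4)
})

test_that("sparse solves are exact on small systems and flag singular ones", {
  A <- Matrix::Matrix(c(2, 1, 1, 2), 2, sparse = TRUE)
  expect_equal(solve_linear_system(A, c(3, 3)), c(1, 1), tolerance = 1e-12)
  I2 <- Matrix::Diagonal(2)
  expect_equal(solve_linear_system(I2, c(4, 7)), c(4, 7))
  m <- square_mesh(3)
  K <- assemble_diffusion(m, 1)  # singular without boundary conditions
  expect_error(solve_linear_system(K, runif(nrow(m$nodes))), "singular|converge")
})

test_that("a backward-Euler decay step is nodally exact on any mesh", {
  m <- generate_wall_mesh(2, 3, pi / 4, 0.2)
  M <- assemble_mass(m)
  a <- 0.7; dt <- 0.05
  u0 <- runif(nrow(m$nodes))
  A <- (1 / dt) * M + a * M
  u1 <- solve_linear_system(A, as.vector(M %*% u0) / dt)
  expect_equal(u1, u0 / (1 + a * dt), tolerance = 1e-12)
})

test_that("assembly is permutation-equivariant", {
  m <- generate_wall_mesh(2, 3, pi / 4, 0.25)
  n <- nrow(m$nodes)
  set.seed(2)
  perm <- sample(n)
  inv <- order(perm)
  m2 <- wall_mesh(m$nodes[perm, ], matrix(inv[m$triangles], ncol = 3))
  K1 <- as.matrix(assemble_diffusion(m, 1))
  K2 <- as.matrix(assemble_diffusion(m2, 1))
  expect_equal(K2, K1[perm, perm][seq_len(n), seq_len(n)] * 0 + K1[perm, perm],
               tolerance = 1e-12)
})
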