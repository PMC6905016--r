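ip <- immune_params()

test_that("pathogen reaction terms evaluate pointwise", {
  r <- pathogen_reactions(0.2, 0, ip)
  expect_equal(r$q_b, 0.03)   # 0.15 * 0.2
  expect_equal(r$r_b, 0)
  r2 <- pathogen_reactions(0.2, 0.55, ip)
  expect_equal(r2$r_b, 0.198) # 1.8 * 0.55 * 0.2
  r3 <- pathogen_reactions(c(0, 0.5), c(1, 1), ip)
  expect_equal(r3$q_b[1], 0)
  expect_equal(r3$r_b[1], 0)
})

test_that("leukocyte reaction terms saturate and decay as closed forms say", {
  expect_equal(leukocyte_reactions(0.3, ip$C_n_max, ip)$q_n, 0)
  r <- leukocyte_reactions(0, 0.1, ip)
  expect_equal(r$q_n, 0)
  expect_equal(r$r_n, 0.02)   # mu_n * C_l = 0.2 * 0.1
  expect_equal(leukocyte_reactions(0.2, 0, ip)$q_n, 0.011)  # 0.1*0.2*0.55
})

test_that("a uniform pathogen field follows the backward-Euler growth closed form", {
  m <- fem_attach(generate_wall_mesh(2, 3, pi / 4, 0.2))
  n <- nrow(m$nodes)
  dt <- 0.01
  st <- immune_state(rep(0.3, n), rep(0, n))
  C1 <- step_pathogen(st, m, ip, dt)
  expect_equal(C1, rep(0.3 / (1 - dt * ip$c_p / ip$phi_f), n), tolerance = 1e-10)
  # zero field stays zero
  st0 <- immune_state(rep(0, n), rep(0.2, n))
  expect_equal(step_pathogen(st0, m, ip, dt), rep(0, n), tolerance = 1e-12)
})

test_that("a uniform leukocyte field follows the backward-Euler decay closed form", {
  m <- fem_attach(generate_wall_mesh(2, 3, pi / 4, 0.2))
  n <- nrow(m$nodes)
  dt <- 0.02
  st <- immune_state(rep(0, n), rep(0.4, n))
  C1 <- step_leukocyte(st, m, ip, dt, rep(0, n))
  expect_equal(C1, rep(0.4 / (1 + dt * ip$mu_n / ip$phi_f), n), tolerance = 1e-10)
})

test_that("total mass is conserved with reactions and sources off", {
  m <- fem_attach(generate_wall_mesh(2, 3, pi / 3, 0.15))
  n <- nrow(m$nodes)
  p0 <- immune_params(c_p = 0, lambda_nb = 0, gamma_n = 0, mu_n = 0,
                      lambda_bn = 0, chi_nb = 0)
  # nodal (lumped) quadrature of int phi_f C, the mass functional the
  # zero-flux semi-discretization conserves exactly
  w <- Matrix::rowSums(assemble_mass(m))
  set.seed(7)
  C_p <- runif(n); C_l <- runif(n)
  m0p <- p0$phi_f * sum(w * C_p)
  m0l <- p0$phi_f * sum(w * C_l)
  for (k in 1:100) {
    st <- immune_state(C_p, C_l)
    C_p <- step_pathogen(st, m, p0, 0.05)
    C_l <- step_leukocyte(st, m, p0, 0.05, C_p)
  }
  expect_lt(abs(p0$phi_f * sum(w * C_p) - m0p) / m0p, 1e-10)
  expect_lt(abs(p0$phi_f * sum(w * C_l) - m0l) / m0l, 1e-10)
})

test_that("leukocytes drift up the pathogen gradient (chemotaxis)", {
  m <- fem_attach(square_mesh(10))
  n <- nrow(m$nodes)
  peak <- c(0.7, 0.7)
  C_p <- exp(-20 * ((m$nodes[, 1] - peak[1])^2 + (m$nodes[, 2] - peak[2])^2))
  pm <- immune_params(D_n = 1e-4, chi_nb = 0.02, gamma_n = 0, mu_n = 0,
                      lambda_bn = 0, c_p = 0, lambda_nb = 0)
  C_l <- rep(1, n)
  M <- assemble_mass(m)
  centroid <- function(w) {
    ww <- as.vector(M %*% w)
    c(sum(ww * m$nodes[, 1]), sum(ww * m$nodes[, 2])) / sum(ww)
  }
  d0 <- sqrt(sum((centroid(C_l) - peak)^2))
  for (k in 1:10)
    C_l <- step_leukocyte(immune_state(C_p, C_l), m, pm, 0.05, C_p)
  d1 <- sqrt(sum((centroid(C_l) - peak)^2))
  expect_lt(d1, d0)
})

test_that("leukocytes only appear after the pathogen does, and stay positive", {
  m <- fem_attach(generate_wall_mesh(2, 3, pi / 2, 0.12))
  n <- nrow(m$nodes)
  C_p <- numeric(n)
  C_p[mark_infection_region(m, "epicardium", 0.4, 0.6)] <- 0.2
  C_l <- numeric(n)
  expect_equal(max(C_l), 0)
  maxes <- numeric(5)
  for (k in 1:5) {
    st <- immune_state(C_p, C_l)
    C_p <- step_pathogen(st, m, ip, 0.01)
    C_l <- step_leukocyte(st, m, ip, 0.01, C_p)
    maxes[k] <- max(C_l)
    expect_gt(min(C_p), -1e-8)
    expect_gt(min(C_l), -1e-8)
  }
  expect_true(all(diff(c(0, maxes)) > 0))
})

test_that("integrated concentrations are mesh-converged to a few percent", {
  run_int <- function(h, dt) {
    m <- fem_attach(generate_wall_mesh(2, 2.5, pi / 4, h))
    n <- nrow(m$nodes)
    # smooth, mesh-independent initial pocket near the epicardium
    r <- sqrt(rowSums(m$nodes^2)); th <- atan2(m$nodes[, 2], m$nodes[, 1])
    C_p <- 0.2 * exp(-((r - 2.5) / 0.15)^2 - ((th - pi / 8) / 0.15)^2)
    C_l <- numeric(n)
    for (k in seq_len(round(1 / dt))) {
      st <- immune_state(C_p, C_l)
      C_p <- step_pathogen(st, m, ip, dt)
      C_l <- step_leukocyte(st, m, ip, dt, C_p)
    }
    M <- assemble_mass(m)
    c(sum(M %*% C_p), sum(M %*% C_l))
  }
  coarse <- run_int(0.10, 0.02)
  fine <- run_int(0.05, 0.01)
  expect_lt(abs(coarse[1] - fine[1]) / fine[1], 0.05)
  expect_lt(abs(coarse[2] - fine[2]) / fine[2], 0.05)
})
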