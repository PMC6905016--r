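# Independent 1D radial finite-difference oracle for the radially symmetric
# annulus scenario (no chemotaxis, no lymph elements): conservative
# second-order FD in r with zero-flux ends, and the same backward-Euler
# semi-implicit staggering as the package solvers.  Used to cross-check the
# 2D finite-element fields.

radial_oracle <- function(r_i, r_o, n_r, dt, t_end, ip, fp, ep, cp0_outer) {
  r <- seq(r_i, r_o, length.out = n_r)
  h <- r[2] - r[1]
  rf <- (r[-1] + r[-n_r]) / 2  # face radii
  # conservative radial diffusion (1/r) d/dr (r d/dr): face fluxes divided
  # by the control-volume measure r_j h (half cells at the Neumann ends)
  vol <- r * h
  vol[c(1, n_r)] <- vol[c(1, n_r)] / 2
  L <- matrix(0, n_r, n_r)
  for (j in seq_len(n_r)) {
    if (j > 1) {
      L[j, j - 1] <- L[j, j - 1] + rf[j - 1] / (h * vol[j])
      L[j, j] <- L[j, j] - rf[j - 1] / (h * vol[j])
    }
    if (j < n_r) {
      L[j, j + 1] <- L[j, j + 1] + rf[j] / (h * vol[j])
      L[j, j] <- L[j, j] - rf[j] / (h * vol[j])
    }
  }
  C_p <- numeric(n_r); C_p[n_r] <- cp0_outer
  C_l <- numeric(n_r)
  P <- rep(fp$P_0, n_r)
  I <- diag(n_r)
  nsteps <- round(t_end / dt)
  for (k in seq_len(nsteps)) {
    A <- (ip$phi_f / dt - ip$c_p + ip$lambda_nb * pmax(C_l, 0)) * I - ip$D_b * L
    C_p_new <- solve(A, ip$phi_f / dt * C_p)
    cp <- pmax(C_p_new, 0)
    A <- (ip$phi_f / dt + ip$mu_n + (ip$lambda_bn + ip$gamma_n) * cp) * I -
      ip$D_n * L
    C_l <- solve(A, ip$phi_f / dt * C_l + ip$gamma_n * cp * ip$C_n_max)
    C_p <- C_p_new
    cf <- hydraulic_permeability(cp, fp) * fp$S_over_V
    sg <- reflection_coefficient(cp, fp)
    A <- (ep$storage / dt + cf) * I - fp$mobility * L
    P <- solve(A, ep$storage / dt * P + cf * (fp$P_c - sg * (fp$pi_c - fp$pi_i)))
  }
  list(r = r, C_p = C_p, C_l = C_l, P = P)
}
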