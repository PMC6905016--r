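# Quasi-static displacement of the solid skeleton driven by the interstitial
# pressure gradient, and the derived dilatation, phase fractions and phase
# stresses.  The displacement problem is elliptic (no time derivative): it is
# solved once per time step after the pressure update, with homogeneous
# Dirichlet data on the whole boundary.

#' Solve the quasi-static displacement problem
#'
#' Solves `(lambda_s + mu_s) grad(div U) + mu_s lap U = grad P` with `U = 0`
#' on the whole boundary; in weak form the pressure enters as the load
#' `(P, div W)`.  Also derives the dilatation and phase fractions via
#' [porosity_update()].
#'
#' @param P nodal pressure field, mmHg.
#' @param mesh a `wall_mesh`.
#' @param params [elastic_params()] in internal units (mmHg moduli).
#' @param cache optional cache from [displacement_cache()]; reuse it when
#'   stepping repeatedly, the stiffness factorization is constant.
#' @return object of class `displacement_state`: `U` (n x 2, cm), `e`
#'   (element dilatation), `phi_s`, `phi_f` (element fractions), `t`.
#' @export
solve_displacement <- function(P, mesh, params, cache = NULL) {
  if (any(!is.finite(P))) stop("pressure field must be finite")
  if (is.null(cache)) cache <- displacement_cache(mesh, params)
  fem <- cache$fem
  p_e <- elem_mean(fem, P)
  # load (P, div W): dof (i, comp) receives A_e * mean(P) * dphi_i/dx_comp
  f <- numeric(2L * fem$n_nodes)
  vals_x <- fem$G1 * (p_e * fem$areas)
  vals_y <- fem$G2 * (p_e * fem$areas)
  for (k in 1:3) {
    sx <- rowsum(vals_x[, k], fem$tri[, k])
    sy <- rowsum(vals_y[, k], fem$tri[, k])
    ix <- as.integer(rownames(sx))
    f[ix] <- f[ix] + sx[, 1L]
    f[ix + fem$n_nodes] <- f[ix + fem$n_nodes] + sy[, 1L]
  }
  f[cache$bdofs] <- 0
  u <- fem_solve_spd(cache$fac, f)
  U <- cbind(u[seq_len(fem$n_nodes)], u[fem$n_nodes + seq_len(fem$n_nodes)])
  por <- porosity_update(U, mesh, params)
  structure(list(U = U, e = por$e, phi_s = por$phi_s, phi_f = por$phi_f),
            class = "displacement_state")
}

#' Build the reusable elasticity cache
#'
#' Assembles the elasticity operator, applies the homogeneous Dirichlet
#' boundary condition on every boundary node and factorizes once.
#'
#' @inheritParams solve_displacement
#' @return list with the Cholesky factor, boundary dof indices and FEM data.
#' @export
displacement_cache <- function(mesh, params) {
  fem <- fem_cache(mesh)
  K <- assemble_vector_elasticity(mesh, params$lambda_s, params$mu_s,
                                  form = params$form)
  bnodes <- sort(unique(as.vector(mesh$boundary_edges)))
  bdofs <- c(bnodes, bnodes + fem$n_nodes)
  K <- apply_dirichlet(K, numeric(2L * fem$n_nodes), bdofs, 0)$op
  list(fac = fem_factor_spd(K), bdofs = bdofs, fem = fem, bnodes = bnodes)
}

#' Dilatation and phase fractions from a displacement field
#'
#' Element-wise dilatation `e = div U` from the P1 gradients, and the
#' linearized solid mass balance `phi_s = phi_s0 (1 - e)` (clamped to (0,1)),
#' `phi_f = 1 - phi_s`.  The relative solid-phase decrease
#' `(phi_s0 - phi_s)/phi_s0` equals `e`, the quantity thresholded at 10% to
#' delineate edema.
#'
#' @param U n x 2 nodal displacement (cm).
#' @param mesh a `wall_mesh`.
#' @param params [elastic_params()] (uses `phi_s0`).
#' @return list with element-wise `e`, `phi_s`, `phi_f` and the number of
#'   clamped elements `n_clamped`.
#' @export
porosity_update <- function(U, mesh, params) {
  fem <- fem_cache(mesh)
  ux <- matrix(U[fem$tri, 1L], ncol = 3L)
  uy <- matrix(U[fem$tri, 2L], ncol = 3L)
  e <- rowSums(fem$G1 * ux) + rowSums(fem$G2 * uy)
  eps <- 1e-9
  phi_s_raw <- params$phi_s0 * (1 - e)
  phi_s <- pmin(pmax(phi_s_raw, eps), 1 - eps)
  list(e = e, phi_s = phi_s, phi_f = 1 - phi_s,
       n_clamped = sum(phi_s_raw != phi_s))
}

#' Phase stress tensors
#'
#' Solid skeleton stress `sigma_s = lambda_s tr(eps) I + 2 mu_s eps(U)` and
#' fluid stress `sigma_f = -P I`, element-wise.
#'
#' @param U n x 2 nodal displacement.
#' @param P nodal pressure.
#' @param mesh a `wall_mesh`.
#' @param params [elastic_params()] in internal units.
#' @return list: `sigma_s` m x 3 matrix (xx, yy, xy components) and
#'   `sigma_f` length-m vector (the diagonal value `-P`).
#' @export
stress_tensors <- function(U, P, mesh, params) {
  fem <- fem_cache(mesh)
  ux <- matrix(U[fem$tri, 1L], ncol = 3L)
  uy <- matrix(U[fem$tri, 2L], ncol = 3L)
  exx <- rowSums(fem$G1 * ux)
  eyy <- rowSums(fem$G2 * uy)
  exy <- 0.5 * (rowSums(fem$G2 * ux) + rowSums(fem$G1 * uy))
  tr <- exx + eyy
  sigma_s <- cbind(xx = params$lambda_s * tr + 2 * params$mu_s * exx,
                   yy = params$lambda_s * tr + 2 * params$mu_s * eyy,
                   xy = 2 * params$mu_s * exy)
  list(sigma_s = sigma_s, sigma_f = -elem_mean(fem, P))
}
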