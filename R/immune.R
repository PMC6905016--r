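# Pathogen / leukocyte dynamics: reaction-diffusion for the pathogen and
# reaction-diffusion-chemotaxis for leukocytes, both with zero-(total-)flux
# boundaries.  Time discretization is backward Euler with the reaction terms
# semi-implicit: terms linear in the unknown are implicit, the cross-species
# factor is lagged, and the leukocyte step sees the freshly updated pathogen
# field (one-way causal staggering within a step).  Time-derivative and
# reaction terms use lumped (nodal) mass so each step is an M-matrix and the
# discrete maximum principle holds where the transport term permits it.

#' Create an immune state
#' @param C_p nodal pathogen concentration (10^10 cell/cm^3).
#' @param C_l nodal leukocyte concentration (10^7 cell/cm^3).
#' @param t time in hours.
#' @return object of class `immune_state`.
#' @export
immune_state <- function(C_p, C_l, t = 0) {
  stopifnot(length(C_p) == length(C_l))
  structure(list(C_p = C_p, C_l = C_l, t = t), class = "immune_state")
}

#' Pathogen reaction terms
#'
#' Pointwise reproduction `q_b = c_p C_p` and phagocytosis by leukocytes
#' `r_b = lambda_nb C_l C_p`.
#'
#' @param C_p,C_l concentration fields (any shape, evaluated pointwise).
#' @param params an [immune_params()] object.
#' @return list with fields `q_b` and `r_b`.
#' @export
pathogen_reactions <- function(C_p, C_l, params) {
  list(q_b = params$c_p * C_p, r_b = params$lambda_nb * C_l * C_p)
}

#' Leukocyte reaction terms
#'
#' Extravasation from the bloodstream, saturating at the blood concentration
#' (`q_n = gamma_n C_p (C_n_max - C_l)`), and death by post-phagocytosis
#' apoptosis plus natural decay (`r_n = lambda_bn C_l C_p + mu_n C_l`).
#'
#' @inheritParams pathogen_reactions
#' @return list with fields `q_n` and `r_n`.
#' @export
leukocyte_reactions <- function(C_p, C_l, params) {
  list(q_n = params$gamma_n * C_p * (params$C_n_max - C_l),
       r_n = params$lambda_bn * C_l * C_p + params$mu_n * C_l)
}

# mean of a nodal field over each element
elem_mean <- function(fem, nodal) {
  (nodal[fem$tri[, 1L]] + nodal[fem$tri[, 2L]] + nodal[fem$tri[, 3L]]) / 3
}

# element-wise gradient of a nodal P1 field, m x 2
elem_grad <- function(fem, nodal) {
  u <- matrix(nodal[fem$tri], ncol = 3L)
  cbind(rowSums(fem$G1 * u), rowSums(fem$G2 * u))
}

# load vector of an element-wise source density: int coeff phi_i
elem_load <- function(fem, coeff) {
  vals <- coeff * fem$areas / 3
  v <- numeric(fem$n_nodes)
  for (k in 1:3) {
    s <- rowsum(vals, fem$tri[, k])
    v[as.integer(rownames(s))] <- v[as.integer(rownames(s))] + s[, 1L]
  }
  v
}

#' One backward-Euler step of the pathogen field
#'
#' Advances `phi_f dC_p/dt = div(D_b grad C_p) + c_p C_p -
#' lambda_nb C_l C_p` with a natural zero-flux boundary.  Reproduction and
#' the phagocytosis term are implicit in `C_p`, with `C_l` lagged at the
#' previous time level.
#'
#' @param state an [immune_state()].
#' @param mesh a `wall_mesh` (use [fem_attach()] for repeated stepping).
#' @param params an [immune_params()] object.
#' @param dt time step, h.
#' @return the new nodal `C_p` field.
#' @export
step_pathogen <- function(state, mesh, params, dt) {
  if (!(dt > 0)) stop("dt must be positive")
  fem <- fem_cache(mesh)
  w <- lumped_mass_weights(fem)
  K <- assemble_diffusion(mesh, params$D_b)
  cl <- pmax(state$C_l, 0)  # lagged field, clip SUPG undershoot
  # lumped time/reaction terms keep the system an M-matrix (positivity)
  diag_c <- w * (params$phi_f / dt - params$c_p + params$lambda_nb * cl)
  A <- K + Diagonal(x = diag_c)
  rhs <- (params$phi_f / dt) * w * state$C_p
  solve_linear_system(A, rhs, "pathogen step")
}

#' One backward-Euler step of the leukocyte field
#'
#' Advances the leukocyte balance with diffusion, chemotactic advection at
#' the element-wise velocity `chi_nb grad C_p` (SUPG-stabilized), saturating
#' extravasation and death terms.  `C_p` is taken at the new time level
#' (pathogen stepped first); terms linear in `C_l` are implicit.
#'
#' @inheritParams step_pathogen
#' @param C_p_new nodal pathogen field at the new time level.
#' @return the new nodal `C_l` field.
#' @export
step_leukocyte <- function(state, mesh, params, dt, C_p_new) {
  if (!(dt > 0)) stop("dt must be positive")
  fem <- fem_cache(mesh)
  w <- lumped_mass_weights(fem)
  K <- assemble_diffusion(mesh, params$D_n)
  vel <- params$chi_nb * elem_grad(fem, C_p_new)
  G <- assemble_advection_supg(mesh, vel, params$D_n)
  cp <- pmax(C_p_new, 0)  # clip solver undershoot
  sink <- params$lambda_bn * cp + params$mu_n + params$gamma_n * cp
  A <- K + G + Diagonal(x = w * (params$phi_f / dt + sink))
  rhs <- (params$phi_f / dt) * w * state$C_l +
    w * params$gamma_n * cp * params$C_n_max
  solve_linear_system(A, rhs, "leukocyte step")
}
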