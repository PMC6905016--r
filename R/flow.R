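# Interstitial fluid pressure: parabolic balance with Starling capillary
# filtration on capillary elements and Hill-type lymphatic drainage on lymph
# elements, both modulated by the local pathogen load through the hydraulic
# permeability L_p(C_p) and the reflection coefficient sigma(C_p).

#' Infection-modulated capillary-wall hydraulic permeability
#'
#' `L_p = L_p0 (1 + c_bp C_p)`: the pathogen opens the microvascular wall,
#' increasing filtration.  Non-decreasing in `C_p`.
#'
#' @param C_p pathogen concentration field (pointwise).
#' @param params [flow_params()] in internal units (see [convert_units()]).
#' @return hydraulic permeability, cm/(h mmHg).
#' @export
hydraulic_permeability <- function(C_p, params) {
  params$L_p0 * (1 + params$c_bp * C_p)
}

#' Infection-modulated oncotic reflection coefficient
#'
#' `sigma = sigma_0 / (1 + c_br C_p)`: inflammation makes the wall leaky to
#' plasma proteins, eroding the oncotic pressure difference.  Range
#' `(0, sigma_0]`, non-increasing in `C_p`.
#'
#' @inheritParams hydraulic_permeability
#' @return dimensionless reflection coefficient.
#' @export
reflection_coefficient <- function(C_p, params) {
  params$sigma_0 / (1 + params$c_br * C_p)
}

#' Starling capillary filtration source
#'
#' `q_c = L_p(C_p) (S/V) (P_c - P - sigma(C_p) (pi_c - pi_i))`, a volumetric
#' filtration rate (1/h).  When a mesh and region map are supplied the
#' source is evaluated per element from element-mean fields and zeroed on
#' lymph elements (unless `capillary_everywhere` is set); otherwise it is
#' evaluated pointwise on the given fields.
#'
#' @param P interstitial pressure field, mmHg.
#' @param C_p pathogen concentration field.
#' @param params [flow_params()] in internal units.
#' @param mesh optional `wall_mesh` (switches to element-wise evaluation).
#' @param regions optional `region_map` giving the lymph/capillary partition.
#' @return filtration rate field, 1/h.
#' @export
capillary_source <- function(P, C_p, params, mesh = NULL, regions = NULL) {
  if (!is.null(mesh)) {
    fem <- fem_cache(mesh)
    P <- elem_mean(fem, P)
    C_p <- elem_mean(fem, C_p)
  }
  lp <- hydraulic_permeability(C_p, params)
  sg <- reflection_coefficient(C_p, params)
  q <- lp * params$S_over_V * (params$P_c - P - sg * (params$pi_c - params$pi_i))
  if (!is.null(regions) && !params$capillary_everywhere)
    q[regions$lymph_elements] <- 0
  q
}

#' Hill-type lymphatic drainage flux
#'
#' `q_l = -q_0 (1 + V_max dP^n / (K_m^n + dP^n))` with `dP = max(P - P_0, 0)`
#' (the Hill term is clamped for pressures below the normal interstitial
#' pressure, where an odd exponent would otherwise reverse the drainage).
#' Monotone non-increasing in `P` and bounded in
#' `[-q_0 (1 + V_max), -q_0]`.  When a region map is supplied the flux is
#' evaluated per element and zeroed off the lymph elements.  The returned
#' value is a wall flux in `q_0`'s unit (cm/h internally); `step_pressure`
#' converts it to a volumetric rate with the lymph surface-density factor.
#'
#' @param P interstitial pressure field, mmHg.
#' @param params [flow_params()] in internal units.
#' @param mesh,regions optional; as in [capillary_source()].
#' @return drainage flux field (negative on drained elements).
#' @export
lymph_drainage <- function(P, params, mesh = NULL, regions = NULL) {
  if (!is.null(mesh)) P <- elem_mean(fem_cache(mesh), P)
  dp <- pmax(P - params$P_0, 0)
  hill <- ifelse(dp > 0,
                 params$V_max * dp^params$n_hill /
                   (params$K_m^params$n_hill + dp^params$n_hill),
                 0)
  q <- -params$q_0 * (1 + hill)
  if (!is.null(regions)) {
    mask <- numeric(length(q))
    mask[regions$lymph_elements] <- 1
    q <- q * mask
  }
  q
}

# per-element lymph surface density factor (1/cm): user value or 1/sqrt(A_e)
lymph_density_of <- function(fem, params) {
  if (is.null(params$lymph_density)) 1 / sqrt(fem$areas)
  else rep_len(params$lymph_density, length(fem$areas))
}

#' One backward-Euler step of the interstitial pressure
#'
#' Advances `S dP/dt = div(k grad P) + q_c + q_l` with the storage
#' coefficient `S = 3/(3 lambda_s + 2 mu_s)` (1/mmHg), zero-flux boundary,
#' the Starling source implicit in its linear-in-P part, and the lymph Hill
#' term lagged at the previous pressure.  Capillary filtration acts as a
#' pressure source, lymphatic drainage as a sink.
#'
#' @param P nodal pressure at the current time level, mmHg.
#' @param C_p nodal pathogen field at the current time level.
#' @param mesh a `wall_mesh` (use [fem_attach()] for repeated stepping).
#' @param regions a `region_map`.
#' @param flow [flow_params()] in internal units.
#' @param elastic [elastic_params()] in internal units (provides the storage
#'   coefficient).
#' @param dt time step, h.
#' @return the new nodal pressure field.
#' @export
step_pressure <- function(P, C_p, mesh, regions, flow, elastic, dt) {
  if (!(dt > 0)) stop("dt must be positive")
  fem <- fem_cache(mesh)
  S <- elastic$storage
  w <- lumped_mass_weights(fem)
  K <- assemble_diffusion(mesh, flow$mobility)

  cp_e <- pmax(elem_mean(fem, C_p), 0)  # clip SUPG/solver undershoot
  cap_mask <- rep(1, length(cp_e))
  if (!flow$capillary_everywhere) cap_mask[regions$lymph_elements] <- 0
  cf_e <- hydraulic_permeability(cp_e, flow) * flow$S_over_V * cap_mask
  sg_e <- reflection_coefficient(cp_e, flow)

  ql_e <- lymph_drainage(P, flow, mesh = mesh, regions = regions) *
    lymph_density_of(fem, flow)

  # lumped storage/reaction quadrature (M-matrix, monotone step)
  A <- K + Diagonal(x = (S / dt) * w + elem_load(fem, cf_e))
  rhs <- (S / dt) * w * P +
    elem_load(fem, cf_e * (flow$P_c - sg_e * (flow$pi_c - flow$pi_i))) +
    elem_load(fem, ql_e)
  P_new <- solve_linear_system(A, rhs, "pressure step")
  if (any(P_new < -50) || any(P_new > 100))
    warning(sprintf("pressure outside the physiological sanity range: [%.2f, %.2f] mmHg",
                    min(P_new), max(P_new)))
  P_new
}
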