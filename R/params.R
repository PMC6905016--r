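# Model parameter containers.  Constructors take the values in the units in
# which they are usually reported (hydraulic quantities per second; moduli
# in mmHg or kPa as declared); convert_units() turns them into the internal
# cm / hour / mmHg system used by every solver.

KPA_TO_MMHG <- 7.50062

#' Immune-model parameters
#'
#' Rates of the pathogen / leukocyte reaction-diffusion-chemotaxis system.
#' Concentrations are measured in 10^10 cell/cm^3 for the pathogen and
#' 10^7 cell/cm^3 for leukocytes, which makes every rate product consistent
#' without further scaling.  All defaults are the reference myocarditis
#' values; units are already cm / h.
#'
#' @param phi_f interstitial fluid volume fraction (porosity), in (0,1).
#' @param D_b pathogen diffusion coefficient, cm^2/h.
#' @param c_p pathogen reproduction rate, 1/h.
#' @param lambda_nb phagocytosis rate, cm^3/(h 10^7 cell).
#' @param D_n leukocyte diffusion coefficient, cm^2/h.
#' @param chi_nb chemotaxis rate, cm^5/(h 10^7 cell).
#' @param lambda_bn leukocyte death rate after phagocytosis,
#'   cm^3/(h 10^10 cell).
#' @param gamma_n leukocyte capillary-wall permeability, cm^3/(h 10^7 cell).
#' @param C_n_max leukocyte concentration in the bloodstream, 10^7 cell/cm^3.
#' @param mu_n leukocyte apoptosis rate, 1/h.
#' @return object of class `immune_params`.
#' @export
immune_params <- function(phi_f = 0.2, D_b = 5e-5, c_p = 0.15,
                          lambda_nb = 1.8, D_n = 5e-5, chi_nb = 1e-4,
                          lambda_bn = 0.1, gamma_n = 0.1, C_n_max = 0.55,
                          mu_n = 0.2) {
  p <- list(phi_f = phi_f, D_b = D_b, c_p = c_p, lambda_nb = lambda_nb,
            D_n = D_n, chi_nb = chi_nb, lambda_bn = lambda_bn,
            gamma_n = gamma_n, C_n_max = C_n_max, mu_n = mu_n)
  if (any(unlist(p) < 0)) stop("immune parameters must be non-negative")
  if (!(phi_f > 0 && phi_f < 1)) stop("phi_f must lie in (0, 1)")
  structure(p, class = "immune_params")
}

#' Interstitial-flow parameters
#'
#' Starling capillary filtration and Hill-type lymphatic drainage.  The
#' microvascular surface density `S_over_V`, the Darcy mobility, the lymph
#' surface-density factor and `c_br` are not fixed by the reference tables;
#' their defaults are physiologically motivated and are meant to be
#' calibrated (see the methods vignette).
#'
#' @param P_c capillary hydrostatic pressure, mmHg.
#' @param L_p0 healthy-tissue capillary-wall hydraulic permeability,
#'   cm/(s mmHg).
#' @param sigma_0 oncotic reflection coefficient of non-inflamed tissue,
#'   in [0,1].
#' @param pi_c,pi_i capillary and interstitial oncotic pressures, mmHg.
#' @param c_bp pathogen influence on hydraulic permeability, cm^3/10^10 cell.
#' @param q_0 normal lymph flow, cm/s.
#' @param V_max maximum relative increase of lymph flow (dimensionless).
#' @param K_m pressure of half-maximal lymph-flow increase, mmHg.
#' @param P_0 normal interstitial pressure, mmHg.
#' @param n_hill Hill exponent (>= 1).
#' @param S_over_V capillary surface area per tissue volume, 1/cm.
#' @param c_br pathogen influence on the reflection coefficient,
#'   cm^3/10^10 cell; defaults to `c_bp`.
#' @param mobility Darcy mobility K/mu of the interstitium, cm^2/(mmHg h);
#'   the default keeps the pressure dips at single-element lymph sinks
#'   within a few mmHg while still localizing pressure inside the wall.
#' @param lymph_density surface density of lymph vessels, 1/cm, converting
#'   the lymph wall flux (cm/h) into a volumetric drainage rate (1/h).
#'   The default 1 makes the lymph numerals act directly as volumetric
#'   rates, the weak-sink reading under which the edema area is insensitive
#'   to the random lymph placement; `NULL` uses `1/sqrt(element area)` per
#'   lymph element (strong single-element sinks).
#' @param capillary_everywhere logical; apply the capillary source on every
#'   element (default), lymph elements then carrying both capillary
#'   filtration and lymph drainage.  `FALSE` restricts filtration to the
#'   non-lymph elements; the infection-amplified Starling source then has
#'   random holes at the lymph elements, which makes the edema area
#'   placement-sensitive.
#' @return object of class `flow_params` (printed units; see
#'   [convert_units()]).
#' @export
flow_params <- function(P_c = 20.0, L_p0 = 3.6e-8, sigma_0 = 0.91,
                        pi_c = 20.0, pi_i = 10.0, c_bp = 60.0, q_0 = 1e-4,
                        V_max = 20.0, K_m = 6.5, P_0 = 0.0, n_hill = 5.0,
                        S_over_V = 174, c_br = NULL, mobility = 3.6e-3,
                        lymph_density = 1, capillary_everywhere = TRUE) {
  if (is.null(c_br)) c_br <- c_bp
  p <- list(P_c = P_c, L_p0 = L_p0, sigma_0 = sigma_0, pi_c = pi_c,
            pi_i = pi_i, c_bp = c_bp, q_0 = q_0, V_max = V_max, K_m = K_m,
            P_0 = P_0, n_hill = n_hill, S_over_V = S_over_V, c_br = c_br,
            mobility = mobility, lymph_density = lymph_density,
            capillary_everywhere = isTRUE(capillary_everywhere))
  if (!(sigma_0 >= 0 && sigma_0 <= 1)) stop("sigma_0 must lie in [0, 1]")
  if (n_hill < 1) stop("n_hill must be >= 1")
  num <- unlist(p[c("P_c", "L_p0", "pi_c", "pi_i", "c_bp", "q_0", "V_max",
                    "K_m", "n_hill", "S_over_V", "c_br", "mobility")])
  if (any(num < 0)) stop("flow parameters must be non-negative")
  structure(p, class = "flow_params")
}

#' Poroelastic solid parameters
#'
#' The Lame moduli of the solid skeleton.  `unit` states the pressure unit
#' the numbers are given in: `"mmHg"` (the default) uses them directly in
#' the internal mmHg system, `"kPa"` converts them (x 7.50062) in
#' [convert_units()].  The reference myocarditis scenario uses the moduli
#' numerals 27.293 / 3.103 in the model's working pressure unit (mmHg):
#' under that reading the simulated pressures (bounded by the 20 mmHg
#' capillary pressure) produce peak dilatations of ~0.26 and a well-defined
#' 10% solid-loss edema region, consistent with the reported edema areas;
#' the dimensional kPa reading caps dilatation at ~0.08 and yields an empty
#' edema region (see the methods vignette).
#'
#' @param lambda_s Lame first parameter of the solid skeleton.
#' @param mu_s shear modulus.
#' @param phi_s0 baseline solid fraction (1 - porosity).
#' @param unit pressure unit of the moduli: `"mmHg"` or `"kPa"`.
#' @param form variational form of the displacement equation:
#'   `"grad_div"` (grad-div + vector Laplacian, the default) or
#'   `"full_stress"` (divergence of the full symmetric stress).
#' @return object of class `elastic_params` (see [convert_units()]).
#' @export
elastic_params <- function(lambda_s = 27.293, mu_s = 3.103, phi_s0 = 0.8,
                           unit = c("mmHg", "kPa"),
                           form = c("grad_div", "full_stress")) {
  if (!(mu_s > 0)) stop("mu_s must be positive")
  if (!(phi_s0 > 0 && phi_s0 < 1)) stop("phi_s0 must lie in (0, 1)")
  structure(list(lambda_s = lambda_s, mu_s = mu_s, phi_s0 = phi_s0,
                 unit = match.arg(unit), form = match.arg(form)),
            class = "elastic_params")
}

#' Convert printed-unit parameters to the internal cm / h / mmHg system
#'
#' `L_p0` and `q_0` are converted from per-second to per-hour (x 3600); the
#' Lame moduli from kPa to mmHg (x 7.50062) when declared in kPa.  The
#' poroelastic storage coefficient `3 / (3 lambda_s + 2 mu_s)` (1/mmHg) is
#' attached to the elastic parameter set.  Already-converted objects pass
#' through unchanged.
#'
#' @param flow a [flow_params()] object.
#' @param elastic an [elastic_params()] object.
#' @return list with converted `flow` and `elastic` (marked with attribute
#'   `units = "internal"`).
#' @export
convert_units <- function(flow, elastic) {
  if (!is(flow, "flow_params") || !is(elastic, "elastic_params"))
    stop("convert_units expects flow_params and elastic_params objects")
  if (!identical(attr(flow, "units"), "internal")) {
    flow$L_p0 <- flow$L_p0 * 3600
    flow$q_0 <- flow$q_0 * 3600
    attr(flow, "units") <- "internal"
  }
  if (!identical(attr(elastic, "units"), "internal")) {
    if (identical(elastic$unit, "kPa")) {
      elastic$lambda_s <- elastic$lambda_s * KPA_TO_MMHG
      elastic$mu_s <- elastic$mu_s * KPA_TO_MMHG
    }
    attr(elastic, "units") <- "internal"
  }
  elastic$storage <- 3 / (3 * elastic$lambda_s + 2 * elastic$mu_s)
  list(flow = flow, elastic = elastic)
}
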