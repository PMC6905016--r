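# Simulation driver: configuration, the time loop with the one-way coupling
# order (pathogen -> leukocytes -> pressure -> displacement), snapshots,
# parameter sweeps and the lymph-placement seed study.

#' Build a simulation configuration
#'
#' Collects geometry (or a mesh / MSH file), all model parameters, initial
#' conditions, time-stepping controls and the random seed.  Defaults
#' reproduce the base myocarditis scenario on the synthetic curved-wall
#' geometry: a half-annular wall (endocardial radius 2 cm, epicardial
#' radius 3 cm) with the initial pathogen load `C_p = 0.2` on the central
#' fifth of the epicardial arc, `C_l = 0` and `P = 0` everywhere, 2.9% lymph
#' elements, dt = 0.01 h and a 10 h horizon.
#'
#' @param geometry list with `inner_radius`, `outer_radius`,
#'   `angular_extent`, `target_edge_length` for [generate_wall_mesh()].
#' @param mesh optional `wall_mesh` (overrides `geometry`).
#' @param msh_file optional path to a Gmsh MSH file (overrides both).
#' @param immune,flow,elastic parameter objects (printed units; converted
#'   internally).
#' @param infection list with `arc` (boundary arc name), `start`, `end`
#'   (arc-length fractions) and `amplitude` (initial pathogen concentration).
#' @param lymph_fraction fraction of lymph-vessel elements.
#' @param dt time step, h.
#' @param t_end final time, h.
#' @param snapshot_dt output cadence, h (5 h and 10 h are always included
#'   when inside the horizon).
#' @param seed integer seed for the lymph placement.
#' @param edema_threshold solid-phase-decrease level delineating edema.
#' @param reference_area optional reference edema area (cm^2) for the final
#'   report.
#' @param output_dir optional directory for VTK/CSV/JSON output.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(geometry = list(inner_radius = 2.0,
                                              outer_radius = 3.0,
                                              angular_extent = pi,
                                              target_edge_length = 0.055),
                              mesh = NULL, msh_file = NULL,
                              immune = immune_params(),
                              flow = flow_params(),
                              elastic = elastic_params(),
                              infection = list(arc = "epicardium",
                                               start = 0.40, end = 0.60,
                                               amplitude = 0.2),
                              lymph_fraction = 0.029,
                              dt = 0.01, t_end = 10, snapshot_dt = 0.5,
                              seed = 1L, edema_threshold = 0.10,
                              reference_area = NULL, output_dir = NULL) {
  if (!(t_end > 0)) stop("t_end must be positive")
  if (!(dt > 0 && dt <= t_end)) stop("require 0 < dt <= t_end")
  structure(list(geometry = geometry, mesh = mesh, msh_file = msh_file,
                 immune = immune, flow = flow, elastic = elastic,
                 infection = infection, lymph_fraction = lymph_fraction,
                 dt = dt, t_end = t_end, snapshot_dt = snapshot_dt,
                 seed = as.integer(seed), edema_threshold = edema_threshold,
                 reference_area = reference_area, output_dir = output_dir),
            class = "simulation_config")
}

#' Write / read a configuration as YAML
#'
#' Round-trips every numeric parameter losslessly (full double precision).
#'
#' @param config a `simulation_config`.
#' @param path YAML file path.
#' @return `path` invisibly / the restored `simulation_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$mesh <- NULL  # meshes travel as MSH files, not through YAML
  x$immune <- unclass(x$immune)
  x$flow <- unclass(x$flow)
  x$elastic <- unclass(x$elastic)
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- simulation_config(
    geometry = x$geometry, msh_file = x$msh_file,
    immune = do.call(immune_params, x$immune),
    flow = do.call(flow_params, x$flow),
    elastic = do.call(elastic_params, x$elastic),
    infection = x$infection, lymph_fraction = x$lymph_fraction,
    dt = x$dt, t_end = x$t_end, snapshot_dt = x$snapshot_dt,
    seed = x$seed, edema_threshold = x$edema_threshold,
    reference_area = x$reference_area, output_dir = x$output_dir)
  cfg
}

config_mesh <- function(config) {
  mesh <- if (!is.null(config$mesh)) config$mesh
  else if (!is.null(config$msh_file)) load_msh(config$msh_file)
  else do.call(generate_wall_mesh, config$geometry)
  fem_attach(mesh)
}

# FNV-1a hash of the YAML rendering, for provenance records
config_hash <- function(config) {
  x <- unclass(config); x$mesh <- NULL
  s <- utf8ToInt(yaml::as.yaml(x, precision = 17L))
  h <- 5381
  for (b in s) h <- (h * 33 + b) %% 2147483647  # djb2 mod 2^31-1
  sprintf("%08x", h)
}

#' Run the coupled edema-formation simulation
#'
#' Time loop with the one-way coupling order per step: (1) pathogen,
#' (2) leukocytes seeing the new pathogen field, (3) interstitial pressure
#' using the new pathogen field, (4) quasi-static displacement from the new
#' pressure, (5) porosity update, (6) snapshot output on cadence.
#' Deterministic for a fixed configuration and seed.
#'
#' @param config a [simulation_config()].
#' @param init optional initial state (list with `C_p`, `C_l`, `P`), e.g. the
#'   `state` of a previous [run_simulation()] summary, for restarts.
#' @param t_start start time of this segment, h (default 0).
#' @return object of class `run_summary`: `series` (per-snapshot data frame
#'   with t, max_Cp, max_Cl, mean_P, max_U, edema_area), `report` (final
#'   [extract_edema_region()] report), `state`, `mesh`, `regions`,
#'   `provenance`.
#' @export
run_simulation <- function(config, init = NULL, t_start = 0) {
  mesh <- config_mesh(config)
  regions <- assign_lymph_elements(mesh, config$lymph_fraction, config$seed)
  regions$infection_nodes <- mark_infection_region(
    mesh, config$infection$arc, config$infection$start, config$infection$end)

  cv <- convert_units(config$flow, config$elastic)
  flow <- cv$flow; elastic <- cv$elastic
  immune <- config$immune
  n <- nrow(mesh$nodes)

  if (is.null(init)) {
    C_p <- numeric(n)
    C_p[regions$infection_nodes] <- config$infection$amplitude
    C_l <- numeric(n)
    P <- rep(flow$P_0, n)
  } else {
    C_p <- init$C_p; C_l <- init$C_l; P <- init$P
    stopifnot(length(C_p) == n, length(C_l) == n, length(P) == n)
  }

  dcache <- displacement_cache(mesh, elastic)
  nsteps <- as.integer(round((config$t_end - t_start) / config$dt))
  snap_every <- max(1L, as.integer(round(config$snapshot_dt / config$dt)))
  forced <- as.integer(round((c(5, 10) - t_start) / config$dt))
  is_snap <- function(k) k %% snap_every == 0L || k == nsteps || k %in% forced

  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log_lines <- c(sprintf("poroedema run: seed %d, config %s", config$seed,
                         config_hash(config)),
                 sprintf("mesh: %d nodes, %d triangles, area %.4f cm^2",
                         n, nrow(mesh$triangles), mesh_area(mesh)),
                 sprintf("lymph elements: %d (fraction %.4f)",
                         length(regions$lymph_elements), config$lymph_fraction),
                 "parameter provenance: table values unless overridden; S_over_V, mobility, c_br, lymph_density are calibration inputs")

  snapshot_row <- function(t, disp, report) {
    data.frame(t = t, max_Cp = max(C_p), max_Cl = max(C_l),
               mean_P = mean(P), max_U = max(sqrt(rowSums(disp$U^2))),
               edema_area = report$edema_area)
  }
  take_snapshot <- function(t, disp) {
    d <- solid_phase_decrease(disp, mesh, config$elastic$phi_s0)
    report <- extract_edema_region(d, mesh, config$edema_threshold)
    if (!is.null(out_dir)) {
      tag <- sprintf("%07.3f", t)
      write_vtk(mesh, file.path(out_dir, sprintf("fields_t%s.vtk", tag)),
                point_data = list(C_p = C_p, C_l = C_l, P = P, U = disp$U,
                                  solid_decrease = d),
                cell_data = list(phi_f = disp$phi_f, dilatation = disp$e))
      ckpt <- data.frame(C_p = C_p, C_l = C_l, P = P,
                         Ux = disp$U[, 1L], Uy = disp$U[, 2L])
      utils::write.csv(ckpt, file.path(out_dir, sprintf("state_t%s.csv", tag)),
                       row.names = FALSE)
    }
    list(row = snapshot_row(t, disp, report), report = report, d = d)
  }

  disp <- solve_displacement(P, mesh, elastic, cache = dcache)
  snap <- take_snapshot(t_start, disp)
  series <- snap$row
  state0 <- immune_state(C_p, C_l, t_start)

  for (k in seq_len(nsteps)) {
    t <- t_start + k * config$dt
    step_err <- function(e, stage)
      stop(sprintf("%s failed at step %d (t = %.3f h): %s",
                   stage, k, t, conditionMessage(e)), call. = FALSE)
    st <- immune_state(C_p, C_l, t)
    C_p_new <- tryCatch(step_pathogen(st, mesh, immune, config$dt),
                        error = function(e) step_err(e, "pathogen step"))
    C_l <- tryCatch(step_leukocyte(st, mesh, immune, config$dt, C_p_new),
                    error = function(e) step_err(e, "leukocyte step"))
    C_p <- C_p_new
    P <- tryCatch(step_pressure(P, C_p, mesh, regions, flow, elastic,
                                config$dt),
                  error = function(e) step_err(e, "pressure step"))
    if (is_snap(k)) {
      # the displacement problem is elliptic and memoryless: solving it at
      # output times only is identical to solving it every step
      disp <- solve_displacement(P, mesh, elastic, cache = dcache)
      snap <- take_snapshot(t, disp)
      series <- rbind(series, snap$row)
    }
  }

  report <- snap$report
  if (!is.null(config$reference_area))
    report <- with_reference_area(report, config$reference_area)
  summary <- structure(
    list(series = series, report = report,
         state = list(C_p = C_p, C_l = C_l, P = P, U = disp$U,
                      phi_s = disp$phi_s, phi_f = disp$phi_f, e = disp$e,
                      d = snap$d, t = t_start + nsteps * config$dt),
         mesh = mesh, regions = regions,
         provenance = list(seed = config$seed, config_hash = config_hash(config),
                           package_version = as.character(utils::packageVersion("poroedema"))),
         log = log_lines),
    class = "run_summary")
  if (!is.null(out_dir)) {
    utils::write.csv(series, file.path(out_dir, "series.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(edema_area = report$edema_area,
           reference_area = report$reference_area,
           relative_error = report$relative_error,
           threshold = report$threshold,
           provenance = summary$provenance),
      file.path(out_dir, "area_report.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  summary
}

#' @exportS3Method
print.run_summary <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("run_summary: %d snapshots to t = %.2f h; final edema area %.4f cm^2\n",
              n, x$series$t[n], x$report$edema_area))
  invisible(x)
}

#' Sweep the immune-to-flow coupling strength c_bp
#'
#' One full simulation per value, all else (mesh, seed, lymph placement)
#' fixed.  When `c_br` was tied to `c_bp` in the base configuration the tie
#' is preserved.  Per-run failures are recorded as `NA` and the sweep
#' continues.
#'
#' @param config base [simulation_config()].
#' @param values numeric vector of `c_bp` values, cm^3/10^10 cell.
#' @return data frame with `c_bp`, `edema_area` and `pct_change` relative to
#'   the `c_bp` = 60 baseline.
#' @export
sweep_cbp <- function(config, values = c(40, 50, 60, 70, 80)) {
  if (length(values) == 0L) stop("values must be non-empty")
  tied <- isTRUE(all.equal(config$flow$c_br, config$flow$c_bp))
  run_one <- function(v) {
    cfg <- config
    cfg$flow$c_bp <- v
    if (tied) cfg$flow$c_br <- v
    tryCatch(run_simulation(cfg)$report$edema_area,
             error = function(e) {
               warning(sprintf("sweep run c_bp = %g failed: %s", v,
                               conditionMessage(e)))
               NA_real_
             })
  }
  areas <- vapply(values, run_one, numeric(1))
  base <- if (60 %in% values) areas[match(60, values)] else run_one(60)
  data.frame(c_bp = values, edema_area = areas,
             pct_change = (areas - base) / base * 100)
}

#' Lymph-placement seed study
#'
#' Repeats the full simulation under distinct random lymph-vessel
#' placements and reports the dispersion of the final edema area, probing
#' the robustness of the result to the (unobserved) lymph microanatomy.
#'
#' @param config base [simulation_config()].
#' @param n_seeds number of placements (>= 2); seeds are
#'   `config$seed + 0:(n_seeds-1)` unless `seeds` is given.
#' @param seeds optional explicit integer seeds (must be distinct).
#' @return list with `areas` (named by seed), `mean`, `sd` and `cv`
#'   (coefficient of variation, SD/mean).
#' @export
seed_sensitivity <- function(config, n_seeds = 12, seeds = NULL) {
  if (is.null(seeds)) {
    if (n_seeds < 2) stop("n_seeds must be >= 2")
    seeds <- config$seed + seq_len(n_seeds) - 1L
  }
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  areas <- vapply(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    tryCatch(run_simulation(cfg)$report$edema_area,
             error = function(e) {
               warning(sprintf("seed %d failed: %s", s, conditionMessage(e)))
               NA_real_
             })
  }, numeric(1))
  names(areas) <- seeds
  m <- mean(areas, na.rm = TRUE)
  s <- stats::sd(areas, na.rm = TRUE)
  list(areas = areas, mean = m, sd = s, cv = s / m)
}
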