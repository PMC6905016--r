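#' @importFrom methods as is new
#' @importFrom stats setNames
NULL

# ---- mesh container ---------------------------------------------------------

#' Construct a 2D triangular mesh object
#'
#' Builds the container used by all solvers: node coordinates (cm), triangle
#' connectivity (1-based, re-oriented counter-clockwise), element areas,
#' oriented boundary edges and named boundary arcs.  Triangles with negative
#' signed area are silently re-oriented; degenerate (zero-area) triangles are
#' an error.
#'
#' @param nodes numeric matrix (n x 2) of coordinates in cm.
#' @param triangles integer matrix (m x 3) of 1-based node indices.
#' @param arcs optional named list of ordered node-index vectors describing
#'   boundary arcs.  When `NULL` the whole boundary is exposed as arcs named
#'   `"boundary"` (one per closed loop, suffixed `_2`, `_3`, ... if several).
#' @param element_groups optional named list of triangle-index vectors
#'   (e.g. physical surface groups of a Gmsh file).
#' @return object of class `wall_mesh` with fields `nodes`, `triangles`,
#'   `element_areas`, `boundary_edges` (oriented so the domain lies on the
#'   left, i.e. the outward normal points right of the edge direction),
#'   `arcs`, `element_groups`.
#' @export
wall_mesh <- function(nodes, triangles, arcs = NULL, element_groups = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 2L) stop("nodes must be an n x 2 matrix")
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  if (nrow(triangles) < 1L) stop("mesh has no triangles")
  if (min(triangles) < 1L || max(triangles) > nrow(nodes))
    stop("triangle node indices out of range")

  a <- signed_areas(nodes, triangles)
  flip <- a < 0
  if (any(flip)) {
    tmp <- triangles[flip, 2L]
    triangles[flip, 2L] <- triangles[flip, 3L]
    triangles[flip, 3L] <- tmp
    a <- abs(a)
  }
  if (any(a <= .Machine$double.eps * 100))
    stop("mesh contains degenerate (zero-area) triangles")

  be <- boundary_edges_of(triangles)
  if (is.null(arcs)) {
    loops <- chain_edges(be)
    arcs <- setNames(loops, paste0("boundary",
                                   ifelse(seq_along(loops) == 1L, "",
                                          paste0("_", seq_along(loops)))))
  }
  structure(list(nodes = nodes, triangles = triangles,
                 element_areas = a, boundary_edges = be,
                 arcs = arcs, element_groups = element_groups),
            class = "wall_mesh")
}

signed_areas <- function(nodes, triangles) {
  x1 <- nodes[triangles[, 1L], 1L]; y1 <- nodes[triangles[, 1L], 2L]
  x2 <- nodes[triangles[, 2L], 1L]; y2 <- nodes[triangles[, 2L], 2L]
  x3 <- nodes[triangles[, 3L], 1L]; y3 <- nodes[triangles[, 3L], 2L]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

# Directed edges of CCW triangles traverse the boundary with the domain on
# the left; an edge is on the boundary iff its reverse never occurs.
boundary_edges_of <- function(triangles) {
  e <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)], triangles[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(key)
  e[cnt[key] == 1L, , drop = FALSE]
}

# Chain directed edges into ordered node paths (closed loops or open chains).
chain_edges <- function(edges) {
  if (nrow(edges) == 0L) return(list())
  nxt <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(edges)))
    assign(as.character(edges[i, 1L]), edges[i, 2L], envir = nxt)
  used <- new.env(hash = TRUE, parent = emptyenv())
  loops <- list()
  for (i in seq_len(nrow(edges))) {
    s <- edges[i, 1L]
    if (!is.null(used[[as.character(s)]])) next
    path <- s
    cur <- s
    repeat {
      used[[as.character(cur)]] <- TRUE
      nx <- nxt[[as.character(cur)]]
      if (is.null(nx) || nx == s) break
      path <- c(path, nx)
      cur <- nx
    }
    loops[[length(loops) + 1L]] <- path
  }
  loops
}

#' Total mesh area
#' @param mesh a `wall_mesh`.
#' @return total area in cm^2.
#' @export
mesh_area <- function(mesh) sum(mesh$element_areas)

#' @exportS3Method
print.wall_mesh <- function(x, ...) {
  cat(sprintf("wall_mesh: %d nodes, %d triangles, area %.4f cm^2\n",
              nrow(x$nodes), nrow(x$triangles), mesh_area(x)))
  cat("  arcs:", paste(names(x$arcs), collapse = ", "), "\n")
  invisible(x)
}

# ---- synthetic ventricular wall --------------------------------------------

#' Generate a synthetic curved-wall mesh (annular sector)
#'
#' Structured triangulation of an annular sector used as a reproducible
#' stand-in for a patient-specific long-axis ventricular wall slice: a thin
#' curved wall bounded by an endocardial and an epicardial arc.  For a full
#' annulus (`angular_extent` = 2*pi) the seam is stitched and the boundary
#' consists of the two circles only.
#'
#' @param inner_radius,outer_radius wall radii in cm (0 < inner < outer).
#' @param angular_extent sector opening angle in radians, in (0, 2*pi].
#' @param target_edge_length requested edge length h in cm; must be smaller
#'   than the wall thickness.
#' @return a [wall_mesh()] whose arcs are named `endocardium`, `epicardium`
#'   and (for open sectors) `cut_start`, `cut_end`.
#' @examples
#' m <- generate_wall_mesh(2, 3, pi / 2, 0.2)
#' mesh_area(m)  # close to 0.5 * (pi/2) * (9 - 4)
#' @export
generate_wall_mesh <- function(inner_radius, outer_radius, angular_extent,
                               target_edge_length) {
  if (!(inner_radius > 0) || !(outer_radius > inner_radius))
    stop("invalid geometry: require 0 < inner_radius < outer_radius")
  if (!(angular_extent > 0) || angular_extent > 2 * pi + 1e-12)
    stop("invalid geometry: angular_extent must be in (0, 2*pi]")
  if (!(target_edge_length > 0) ||
      target_edge_length >= (outer_radius - inner_radius))
    stop("invalid geometry: target_edge_length must be < wall thickness")

  h <- target_edge_length
  closed <- abs(angular_extent - 2 * pi) < 1e-9
  n_r <- max(2L, as.integer(ceiling((outer_radius - inner_radius) / h)) + 1L)
  r_mid <- (inner_radius + outer_radius) / 2
  n_seg_t <- max(if (closed) 3L else 1L,
                 as.integer(ceiling(angular_extent * r_mid / h)))
  n_t <- if (closed) n_seg_t else n_seg_t + 1L

  radii <- seq(inner_radius, outer_radius, length.out = n_r)
  ang <- if (closed) seq(0, angular_extent, length.out = n_seg_t + 1L)[-(n_seg_t + 1L)]
         else seq(0, angular_extent, length.out = n_t)

  id <- function(ir, it) (it - 1L) * n_r + ir  # column-major over (r, theta)
  nodes <- cbind(rep(radii, times = n_t) * cos(rep(ang, each = n_r)),
                 rep(radii, times = n_t) * sin(rep(ang, each = n_r)))

  tris <- vector("list", n_seg_t * (n_r - 1L))
  k <- 0L
  for (it in seq_len(n_seg_t)) {
    itp <- if (closed && it == n_seg_t) 1L else it + 1L
    for (ir in seq_len(n_r - 1L)) {
      a <- id(ir, it); b <- id(ir + 1L, it)
      c_ <- id(ir + 1L, itp); d <- id(ir, itp)
      k <- k + 1L
      # alternate the quad diagonal for a more isotropic triangulation
      if ((ir + it) %% 2L == 0L)
        tris[[k]] <- rbind(c(a, b, c_), c(a, c_, d))
      else
        tris[[k]] <- rbind(c(a, b, d), c(b, c_, d))
    }
  }
  triangles <- do.call(rbind, tris)

  endo <- id(1L, c(seq_len(n_t), if (closed) 1L))
  epi  <- id(n_r, c(seq_len(n_t), if (closed) 1L))
  arcs <- list(endocardium = endo, epicardium = epi)
  if (!closed) {
    arcs$cut_start <- id(seq_len(n_r), 1L)
    arcs$cut_end <- id(seq_len(n_r), n_t)
  }
  wall_mesh(nodes, triangles, arcs = arcs)
}

# ---- lymph / capillary partition -------------------------------------------

#' Randomly place lymph-vessel elements
#'
#' Marks a fraction of the triangles, drawn uniformly at random without
#' replacement, as lymph vessels (each vessel the size of one element); all
#' remaining triangles are under blood-capillary influence only.  The count
#' is `fraction * m` rounded half-up, e.g. 2.9% of 5015 elements gives 145.
#'
#' @param mesh a `wall_mesh`.
#' @param fraction fraction of elements occupied by lymph vessels
#'   (default 0.029).
#' @param seed integer seed; the selection is deterministic for a fixed seed
#'   and does not disturb the caller's RNG state.
#' @return object of class `region_map` with integer vectors
#'   `lymph_elements`, `capillary_elements` (a partition of all triangles),
#'   `seed` and `fraction`.
#' @export
assign_lymph_elements <- function(mesh, fraction = 0.029, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  m <- nrow(mesh$triangles)
  k <- as.integer(floor(fraction * m + 0.5))  # round half-up
  lymph <- if (k == 0L) integer(0) else
    sort(with_seed(seed, sample.int(m, k, replace = FALSE)))
  structure(list(lymph_elements = lymph,
                 capillary_elements = setdiff(seq_len(m), lymph),
                 infection_nodes = integer(0),
                 seed = as.integer(seed), fraction = fraction),
            class = "region_map")
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Select the initially infected boundary nodes
#'
#' Returns the nodes of a named boundary arc whose normalized arc-length
#' coordinate lies in `[arc_fraction_start, arc_fraction_end]`.  Used to place
#' the initial pathogen load on a strip of the epicardium (the boundary of
#' the target edema).
#'
#' @param mesh a `wall_mesh`.
#' @param arc_name name of one of `mesh$arcs`.
#' @param arc_fraction_start,arc_fraction_end interval in [0, 1] of the arc's
#'   normalized length.
#' @return integer vector of node indices (possibly empty, with a warning).
#' @export
mark_infection_region <- function(mesh, arc_name, arc_fraction_start = 0,
                                  arc_fraction_end = 1) {
  if (!arc_name %in% names(mesh$arcs))
    stop(sprintf("unknown boundary arc '%s' (have: %s)", arc_name,
                 paste(names(mesh$arcs), collapse = ", ")))
  if (!(arc_fraction_start >= 0 && arc_fraction_end <= 1 &&
        arc_fraction_start < arc_fraction_end))
    stop("require 0 <= arc_fraction_start < arc_fraction_end <= 1")
  path <- mesh$arcs[[arc_name]]
  xy <- mesh$nodes[path, , drop = FALSE]
  seg <- sqrt(rowSums((xy[-1L, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  s <- s / s[length(s)]
  sel <- path[s >= arc_fraction_start & s <= arc_fraction_end]
  sel <- unique(sel)
  if (length(sel) == 0L)
    warning("infection interval contains no boundary nodes")
  sel
}
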