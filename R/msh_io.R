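# Gmsh MSH (ASCII v2.2 and v4.x) reading and writing, plus a legacy-VTK
# writer for inspection in ParaView.  Only 2D triangle meshes are accepted;
# 1D line elements become boundary arcs, named after their physical group
# when one is present.

#' Load a Gmsh MSH mesh
#'
#' Reads an ASCII MSH file (format 2.2 or 4.x), keeps the triangles as the
#' domain and the line elements as boundary arcs.  Physical-group names, when
#' present, name the arcs and element groups; otherwise the whole boundary is
#' exposed as a single arc named `"boundary"`.  Clockwise triangles are
#' re-oriented on load.
#'
#' @param path path to an ASCII `.msh` file.
#' @return a [wall_mesh()].
#' @export
load_msh <- function(path) {
  if (!file.exists(path)) stop(sprintf("MSH file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (length(lines) == 0L || all(lines == ""))
    stop("MSH parse error in $MeshFormat: file is empty")

  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    if (is.na(i0)) return(NULL)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i1) || i1 <= i0)
      stop(sprintf("MSH parse error in $%s: unterminated section", name))
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- sec("MeshFormat")
  if (is.null(fmt)) stop("MSH parse error in $MeshFormat: section missing")
  ver <- as.numeric(strsplit(fmt[1L], "\\s+")[[1L]][1L])
  if (is.na(ver)) stop("MSH parse error in $MeshFormat: unreadable version")
  binary <- as.integer(strsplit(fmt[1L], "\\s+")[[1L]][2L])
  if (!is.na(binary) && binary != 0L)
    stop("MSH parse error in $MeshFormat: binary files are not supported")

  phys <- sec("PhysicalNames")
  phys_names <- list()  # key "dim.tag" -> name
  if (!is.null(phys)) {
    for (ln in phys[-1L]) {
      p <- strsplit(ln, "\\s+")[[1L]]
      if (length(p) >= 3L)
        phys_names[[paste(p[1L], p[2L], sep = ".")]] <-
          gsub('"', "", paste(p[-(1:2)], collapse = " "))
    }
  }

  if (ver < 3) parse_msh2(sec, phys_names) else parse_msh4(sec, phys_names)
}

msh_nums <- function(lines) {
  as.numeric(unlist(strsplit(lines[lines != ""], "\\s+"), use.names = FALSE))
}

parse_msh2 <- function(sec, phys_names) {
  nl <- sec("Nodes")
  if (is.null(nl)) stop("MSH parse error in $Nodes: section missing")
  nn <- as.integer(nl[1L])
  nd <- matrix(msh_nums(nl[-1L]), ncol = 4L, byrow = TRUE)
  if (nrow(nd) != nn) stop("MSH parse error in $Nodes: count mismatch")
  ids <- as.integer(nd[, 1L])
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  nodes <- nd[, 2:3, drop = FALSE]

  el <- sec("Elements")
  if (is.null(el)) stop("MSH parse error in $Elements: section missing")
  tris <- list(); tri_phys <- integer(0)
  segs <- list(); seg_phys <- integer(0)
  for (ln in el[-1L]) {
    if (ln == "") next
    p <- as.integer(strsplit(ln, "\\s+")[[1L]])
    type <- p[2L]; ntags <- p[3L]
    ptag <- if (ntags >= 1L) p[4L] else 0L
    conn <- p[(4L + ntags):length(p)]
    if (type == 2L) { tris[[length(tris) + 1L]] <- conn; tri_phys <- c(tri_phys, ptag) }
    else if (type == 1L) { segs[[length(segs) + 1L]] <- conn; seg_phys <- c(seg_phys, ptag) }
    else if (type %in% c(4L, 5L, 6L, 7L, 11L, 17L))
      stop("MSH parse error in $Elements: 3D elements present, expected a 2D mesh")
    # points (15) and other low-order entities are ignored
  }
  if (length(tris) == 0L)
    stop("MSH parse error in $Elements: no triangles found")
  triangles <- matrix(remap[do.call(rbind, tris)], ncol = 3L)
  build_msh_mesh(nodes, triangles, tri_phys, segs, seg_phys, remap, phys_names)
}

parse_msh4 <- function(sec, phys_names) {
  # $Entities maps (dim, entityTag) -> physical tag, needed to name groups
  ent_phys <- list()
  en <- sec("Entities")
  if (!is.null(en)) {
    counts <- as.integer(strsplit(en[1L], "\\s+")[[1L]])
    i <- 2L
    for (dim in 0:3) {
      nent <- counts[dim + 1L]
      if (is.na(nent)) nent <- 0L
      for (k in seq_len(nent)) {
        p <- as.numeric(strsplit(en[i], "\\s+")[[1L]]); i <- i + 1L
        tag <- as.integer(p[1L])
        # points: tag x y z numPhys ...; others: tag 6 bbox coords numPhys ...
        off <- if (dim == 0L) 5L else 8L
        nph <- as.integer(p[off])
        if (!is.na(nph) && nph >= 1L)
          ent_phys[[paste(dim, tag, sep = ".")]] <- as.integer(p[off + 1L])
      }
    }
  }

  nl <- sec("Nodes")
  if (is.null(nl)) stop("MSH parse error in $Nodes: section missing")
  hdr <- as.integer(strsplit(nl[1L], "\\s+")[[1L]])
  nblocks <- hdr[1L]; nn <- hdr[2L]
  ids <- integer(0); coords <- list()
  i <- 2L
  for (b in seq_len(nblocks)) {
    bh <- as.integer(strsplit(nl[i], "\\s+")[[1L]]); i <- i + 1L
    nb <- bh[4L]
    if (nb > 0L) {
      ids <- c(ids, as.integer(nl[i:(i + nb - 1L)])); i <- i + nb
      cc <- matrix(msh_nums(nl[i:(i + nb - 1L)]), ncol = 3L, byrow = TRUE)
      coords[[length(coords) + 1L]] <- cc[, 1:2, drop = FALSE]
      i <- i + nb
    }
  }
  nodes <- do.call(rbind, coords)
  if (is.null(nodes) || nrow(nodes) != nn)
    stop("MSH parse error in $Nodes: count mismatch")
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)

  el <- sec("Elements")
  if (is.null(el)) stop("MSH parse error in $Elements: section missing")
  hdr <- as.integer(strsplit(el[1L], "\\s+")[[1L]])
  nblocks <- hdr[1L]
  tris <- list(); tri_phys <- integer(0)
  segs <- list(); seg_phys <- integer(0)
  i <- 2L
  for (b in seq_len(nblocks)) {
    bh <- as.integer(strsplit(el[i], "\\s+")[[1L]]); i <- i + 1L
    dim <- bh[1L]; etag <- bh[2L]; type <- bh[3L]; nb <- bh[4L]
    ptag <- ent_phys[[paste(dim, etag, sep = ".")]]
    if (is.null(ptag)) ptag <- 0L
    if (nb == 0L) next
    rows <- lapply(el[i:(i + nb - 1L)],
                   function(ln) as.integer(strsplit(ln, "\\s+")[[1L]]))
    i <- i + nb
    if (type == 2L) {
      tris <- c(tris, lapply(rows, function(r) r[-1L]))
      tri_phys <- c(tri_phys, rep(ptag, nb))
    } else if (type == 1L) {
      segs <- c(segs, lapply(rows, function(r) r[-1L]))
      seg_phys <- c(seg_phys, rep(ptag, nb))
    } else if (type %in% c(4L, 5L, 6L, 7L, 11L, 17L))
      stop("MSH parse error in $Elements: 3D elements present, expected a 2D mesh")
  }
  if (length(tris) == 0L)
    stop("MSH parse error in $Elements: no triangles found")
  triangles <- matrix(remap[do.call(rbind, tris)], ncol = 3L)
  build_msh_mesh(nodes, triangles, tri_phys, segs, seg_phys, remap,
                 phys_names, dim_line = 1L, dim_surf = 2L)
}

build_msh_mesh <- function(nodes, triangles, tri_phys, segs, seg_phys, remap,
                           phys_names, dim_line = 1L, dim_surf = 2L) {
  arcs <- NULL
  if (length(segs) > 0L) {
    edges <- matrix(remap[do.call(rbind, segs)], ncol = 2L)
    arcs <- list()
    for (tag in unique(seg_phys)) {
      paths <- chain_edges(edges[seg_phys == tag, , drop = FALSE])
      nm <- phys_names[[paste(dim_line, tag, sep = ".")]]
      if (is.null(nm)) nm <- if (tag == 0L) "boundary" else paste0("arc_", tag)
      for (j in seq_along(paths))
        arcs[[if (j == 1L) nm else paste0(nm, "_", j)]] <- paths[[j]]
    }
  }
  groups <- NULL
  if (length(unique(tri_phys)) > 1L || any(tri_phys != 0L)) {
    groups <- list()
    for (tag in unique(tri_phys)) {
      nm <- phys_names[[paste(dim_surf, tag, sep = ".")]]
      if (is.null(nm)) nm <- paste0("surface_", tag)
      groups[[nm]] <- which(tri_phys == tag)
    }
  }
  wall_mesh(nodes, triangles, arcs = arcs, element_groups = groups)
}

#' Write a mesh to Gmsh MSH v2.2 (ASCII)
#' @param mesh a `wall_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes", n), con)
  writeLines(sprintf("%d %.16g %.16g 0", seq_len(n),
                     mesh$nodes[, 1L], mesh$nodes[, 2L]), con)
  writeLines(c("$EndNodes", "$Elements", m), con)
  writeLines(sprintf("%d 2 2 0 1 %d %d %d", seq_len(m),
                     mesh$triangles[, 1L], mesh$triangles[, 2L],
                     mesh$triangles[, 3L]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Write a mesh (with optional fields) as legacy VTK
#'
#' ASCII legacy-VTK unstructured grid, one scalar array per entry of
#' `point_data` / `cell_data`; vector point data (two columns) is padded to
#' 3D vectors.
#'
#' @param mesh a `wall_mesh`.
#' @param path output `.vtk` path.
#' @param point_data named list of per-node numeric vectors or n x 2 matrices.
#' @param cell_data named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "poroedema output", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.10g %.10g 0", mesh$nodes[, 1L], mesh$nodes[, 2L]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1L] - 1L,
                     mesh$triangles[, 2L] - 1L, mesh$triangles[, 3L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.10g %.10g 0", v[, 1L], v[, 2L]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.10g", v), con)
      }
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", cell_data[[nm]]), con)
    }
  }
  invisible(path)
}
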