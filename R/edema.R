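# Edema quantification: the edematous region is delineated by the isoline of
# 10% relative solid-phase decrease; the area enclosed between that isoline
# and the domain boundary quantifies the edema and is compared against a
# reference (imaging-derived) area.

#' Nodal solid-phase-decrease field
#'
#' `d = (phi_s0 - phi_s)/phi_s0`, averaged from element values onto nodes
#' with element-area weights (element dilatation is piecewise constant; the
#' node-averaged field is continuous, which permits isoline extraction).
#'
#' @param state a `displacement_state` (from [solve_displacement()]) or a
#'   per-element numeric vector of solid fractions.
#' @param mesh a `wall_mesh`.
#' @param phi_s0 baseline solid fraction.
#' @return nodal field `d` (dimensionless).
#' @export
solid_phase_decrease <- function(state, mesh, phi_s0 = 0.8) {
  phi_s <- if (is.list(state)) state$phi_s else state
  fem <- fem_cache(mesh)
  d_e <- (phi_s0 - phi_s) / phi_s0
  num <- numeric(fem$n_nodes)
  den <- numeric(fem$n_nodes)
  for (k in 1:3) {
    s <- rowsum(cbind(d_e * fem$areas, fem$areas), fem$tri[, k])
    ix <- as.integer(rownames(s))
    num[ix] <- num[ix] + s[, 1L]
    den[ix] <- den[ix] + s[, 2L]
  }
  num / den
}

#' Extract the edematous region from a nodal field
#'
#' Marching-triangles isoline of the linear interpolant of `d` at the given
#' threshold.  The edema area is the exact area of the sub-triangle polygons
#' where the interpolant exceeds the threshold (exact for P1 fields, so the
#' accuracy is independent of element counting).  Crossing segments are
#' chained into ordered polylines.
#'
#' @param d nodal scalar field.
#' @param mesh a `wall_mesh`.
#' @param threshold isoline level (default 0.10, i.e. a 10% solid-phase
#'   decrease).
#' @return object of class `area_report`: `edema_area` (cm^2), `isolines`
#'   (list of k x 2 coordinate matrices), `threshold`, `d`, and slots
#'   `reference_area` / `relative_error` filled by [compare_areas()].
#' @export
extract_edema_region <- function(d, mesh, threshold = 0.10) {
  if (any(!is.finite(d))) stop("field d must be finite")
  fem <- fem_cache(mesh)
  tri <- fem$tri
  dv <- matrix(d[tri], ncol = 3L)
  above <- dv >= threshold
  nab <- rowSums(above)
  area <- sum(fem$areas[nab == 3L])
  segs <- list()

  mixed <- which(nab == 1L | nab == 2L)
  nodes <- mesh$nodes
  for (e in mixed) {
    vid <- tri[e, ]
    xy <- nodes[vid, , drop = FALSE]
    val <- dv[e, ]
    poly <- matrix(numeric(0), 0L, 2L)
    cross <- matrix(numeric(0), 0L, 2L)
    for (k in 1:3) {
      k2 <- if (k == 3L) 1L else k + 1L
      if (val[k] >= threshold) poly <- rbind(poly, xy[k, ])
      s1 <- val[k] - threshold; s2 <- val[k2] - threshold
      if ((s1 > 0 && s2 < 0) || (s1 < 0 && s2 > 0)) {
        tt <- s1 / (s1 - s2)
        pt <- xy[k, ] + tt * (xy[k2, ] - xy[k, ])
        poly <- rbind(poly, pt)
        cross <- rbind(cross, pt)
      }
    }
    if (nrow(poly) >= 3L) {
      xs <- poly[, 1L]; ys <- poly[, 2L]
      area <- area + abs(sum(xs * c(ys[-1L], ys[1L]) - c(xs[-1L], xs[1L]) * ys)) / 2
    }
    if (nrow(cross) == 2L) segs[[length(segs) + 1L]] <- cross
  }
  structure(list(edema_area = area,
                 isolines = chain_isoline_segments(segs),
                 threshold = threshold, d = d,
                 reference_area = NULL, relative_error = NULL),
            class = "area_report")
}

# chain loose 2-point segments into ordered polylines by endpoint matching
chain_isoline_segments <- function(segs) {
  if (length(segs) == 0L) return(list())
  key <- function(p) paste(sprintf("%.9g", p[1L]), sprintf("%.9g", p[2L]))
  ends <- new.env(hash = TRUE, parent = emptyenv())  # endpoint key -> seg ids
  for (i in seq_along(segs)) for (r in 1:2) {
    k <- key(segs[[i]][r, ])
    ends[[k]] <- c(ends[[k]], i)
  }
  used <- logical(length(segs))
  polylines <- list()
  for (i in seq_along(segs)) {
    if (used[i]) next
    used[i] <- TRUE
    path <- segs[[i]]
    # extend forward then backward
    for (dir in 1:2) {
      repeat {
        tip <- if (dir == 1L) path[nrow(path), ] else path[1L, ]
        cand <- setdiff(ends[[key(tip)]], which(used))
        if (length(cand) == 0L) break
        j <- cand[1L]
        used[j] <- TRUE
        sj <- segs[[j]]
        nxt <- if (key(sj[1L, ]) == key(tip)) sj[2L, ] else sj[1L, ]
        path <- if (dir == 1L) rbind(path, nxt) else rbind(nxt, path)
      }
    }
    polylines[[length(polylines) + 1L]] <- unname(path)
  }
  polylines
}

#' Relative error between simulated and reference edema areas
#'
#' `|reference - simulated| / simulated * 100`, normalized by the simulated
#' area.
#'
#' @param simulated_area simulated edema area, cm^2 (> 0).
#' @param reference_area reference (e.g. imaging-derived) area, cm^2.
#' @return relative error in percent.
#' @examples
#' compare_areas(1.728, 1.755)  # 1.5625
#' @export
compare_areas <- function(simulated_area, reference_area) {
  if (!(simulated_area > 0))
    stop("relative error undefined for a zero simulated area")
  abs(reference_area - simulated_area) / simulated_area * 100
}

#' Attach a reference area to an area report
#' @param report an `area_report`.
#' @param reference_area reference area, cm^2.
#' @return the report with `reference_area` and `relative_error` filled.
#' @export
with_reference_area <- function(report, reference_area) {
  report$reference_area <- reference_area
  report$relative_error <- compare_areas(report$edema_area, reference_area)
  report
}

#' @exportS3Method
print.area_report <- function(x, ...) {
  cat(sprintf("area_report: edema area %.4f cm^2 at threshold %.3g (%d isoline polyline%s)\n",
              x$edema_area, x$threshold, length(x$isolines),
              if (length(x$isolines) == 1L) "" else "s"))
  if (!is.null(x$reference_area))
    cat(sprintf("  reference %.4f cm^2, relative error %.2f%%\n",
                x$reference_area, x$relative_error))
  invisible(x)
}

#' Write isoline polylines as CSV
#'
#' One row per vertex with columns `polyline`, `x`, `y` (cm), in drawing
#' order.
#'
#' @param report an `area_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_isolines_csv <- function(report, path) {
  rows <- do.call(rbind, lapply(seq_along(report$isolines), function(i) {
    p <- report$isolines[[i]]
    data.frame(polyline = i, x = p[, 1L], y = p[, 2L])
  }))
  if (is.null(rows)) rows <- data.frame(polyline = integer(0),
                                        x = numeric(0), y = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Rasterize the edematous region to a binary mask
#'
#' Samples the linear interpolant of the report's nodal field on a regular
#' pixel grid over the mesh bounding box; pixels whose center lies in a
#' triangle with interpolated value >= threshold are set to 1.
#'
#' @param report an `area_report` (carries the nodal field and threshold).
#' @param mesh a `wall_mesh`.
#' @param pixel_size pixel edge length, cm.
#' @return binary integer matrix (rows = y from top, columns = x), with
#'   attributes `origin` (lower-left corner) and `pixel_size`.
#' @export
rasterize_mask <- function(report, mesh, pixel_size) {
  if (!(pixel_size > 0)) stop("pixel_size must be positive")
  fem <- fem_cache(mesh)
  d <- report$d; thr <- report$threshold
  bb <- apply(mesh$nodes, 2L, range)
  nx <- max(1L, as.integer(ceiling((bb[2L, 1L] - bb[1L, 1L]) / pixel_size)))
  ny <- max(1L, as.integer(ceiling((bb[2L, 2L] - bb[1L, 2L]) / pixel_size)))
  xc <- bb[1L, 1L] + (seq_len(nx) - 0.5) * pixel_size
  yc <- bb[1L, 2L] + (seq_len(ny) - 0.5) * pixel_size
  img <- matrix(0L, nrow = ny, ncol = nx)
  tri <- fem$tri; nodes <- mesh$nodes
  for (e in seq_len(nrow(tri))) {
    vv <- d[tri[e, ]]
    if (max(vv) < thr) next
    xy <- nodes[tri[e, ], , drop = FALSE]
    jx <- which(xc >= min(xy[, 1L]) - pixel_size & xc <= max(xy[, 1L]) + pixel_size)
    jy <- which(yc >= min(xy[, 2L]) - pixel_size & yc <= max(xy[, 2L]) + pixel_size)
    if (!length(jx) || !length(jy)) next
    px <- rep(xc[jx], times = length(jy))
    py <- rep(yc[jy], each = length(jx))
    det <- (xy[2L, 1L] - xy[1L, 1L]) * (xy[3L, 2L] - xy[1L, 2L]) -
           (xy[3L, 1L] - xy[1L, 1L]) * (xy[2L, 2L] - xy[1L, 2L])
    l2 <- ((px - xy[1L, 1L]) * (xy[3L, 2L] - xy[1L, 2L]) -
           (py - xy[1L, 2L]) * (xy[3L, 1L] - xy[1L, 1L])) / det
    l3 <- ((py - xy[1L, 2L]) * (xy[2L, 1L] - xy[1L, 1L]) -
           (px - xy[1L, 1L]) * (xy[2L, 2L] - xy[1L, 2L])) / det
    l1 <- 1 - l2 - l3
    tol <- 1e-12
    inside <- l1 >= -tol & l2 >= -tol & l3 >= -tol
    val <- l1 * vv[1L] + l2 * vv[2L] + l3 * vv[3L]
    hit <- inside & val >= thr
    if (any(hit)) {
      rows <- ny - (rep(jy, each = length(jx))[hit]) + 1L  # y up -> row down
      cols <- rep(jx, times = length(jy))[hit]
      img[cbind(rows, cols)] <- 1L
    }
  }
  attr(img, "origin") <- bb[1L, ]
  attr(img, "pixel_size") <- pixel_size
  img
}

#' Write a binary mask as plain PGM (P2) or PNG
#' @param mask binary matrix from [rasterize_mask()].
#' @param path output path; format chosen by extension (`.pgm` or `.png`;
#'   PNG requires the `png` package).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG masks requires the 'png' package")
    png::writePNG(mask * 1.0, path)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(mask), nrow(mask)), "1"), con)
    writeLines(apply(mask, 1L, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#' @param path `.pgm` (P2/P1) or `.png` file.
#' @return binary integer matrix.
#' @export
read_mask <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG masks requires the 'png' package")
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(matrix(as.integer(img > 0.5), nrow = nrow(img)))
  }
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (!toks[1L] %in% c("P1", "P2")) stop("unsupported PGM flavor")
  w <- as.integer(toks[2L]); h <- as.integer(toks[3L])
  off <- if (toks[1L] == "P2") 4L else 3L
  vals <- as.integer(toks[(off + 1L):(off + w * h)])
  matrix(as.integer(vals > 0L), nrow = h, byrow = TRUE)
}
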