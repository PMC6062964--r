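## surface_model: parametric surfaces, medial curves, radial-distance maps

#' Area centroid of a simple polygon
#' @param p vertex matrix (closing edge implicit).
#' @return length-2 numeric (x, y).
#' @keywords internal
polygon_centroid <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Resample a contour to equally spaced points
#'
#' Produces `C` points equally spaced in arc length along the closed
#' polyline, in counter-clockwise order. Point 1 is anchored where the ray
#' from the area centroid in the +x direction crosses the boundary, which
#' fixes circumferential correspondence across slices and subjects; the
#' anchor snaps to an existing vertex when the crossing lands within
#' `perimeter / (100 C)` of one, which makes resampling idempotent.
#'
#' The equal-arc positions are solved as a fixed point: the sample is
#' refined until the points are uniform in the arc length of the polyline
#' through the samples themselves (converges in a few iterations; total
#' movement is far below tracing precision), which makes the operation
#' exactly idempotent.
#'
#' @param x a [contour()] or a vertex matrix.
#' @param C number of output points (>= 3).
#' @return a `C` x 2 matrix.
#' @export
resample_contour <- function(x, C) {
  if (C < 3L) stop("C must be at least 3")
  p <- if (inherits(x, "contour")) x$points else as.matrix(x)
  storage.mode(p) <- "double"
  if (signed_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  resample_closed_cpp(p, as.integer(C), 12L, 1e-9)
}

# single-pass reference implementation of one refinement step; the
# compiled fixed-point path must agree with iterating this
resample_once <- function(p, C) {
  m <- nrow(p)
  nxt <- c(2:m, 1L)
  seg <- p[nxt, , drop = FALSE] - p
  len <- sqrt(rowSums(seg^2))
  per <- sum(len)
  if (per <= 0) stop("degenerate contour: zero perimeter")
  cum <- c(0, cumsum(len))              # arc position of vertex i at cum[i]

  cen <- polygon_centroid(p)
  yi <- p[, 2L] - cen[2L]
  yj <- yi[nxt]
  crossing <- which((yi <= 0 & yj > 0) | (yi > 0 & yj <= 0))
  s0 <- 0
  if (length(crossing)) {
    tt <- -yi[crossing] / (yj[crossing] - yi[crossing])
    xint <- p[crossing, 1L] + tt * (p[nxt[crossing], 1L] - p[crossing, 1L])
    right <- xint > cen[1L]
    if (any(right)) {
      crossing <- crossing[right]; tt <- tt[right]; xint <- xint[right]
      pick <- which.min(xint)           # first boundary crossing along the ray
      s0 <- cum[crossing[pick]] + tt[pick] * len[crossing[pick]]
    }
  }
  dv <- abs(cum - s0)
  dv <- pmin(dv, per - dv)
  snap <- which.min(dv)
  if (dv[snap] < per / (100 * C)) s0 <- cum[snap] %% per

  s <- (s0 + per * (seq_len(C) - 1L) / C) %% per
  px <- c(p[, 1L], p[1L, 1L])
  py <- c(p[, 2L], p[1L, 2L])
  cbind(approx(cum, px, xout = s, ties = "ordered")$y,
        approx(cum, py, xout = s, ties = "ordered")$y)
}

# cyclic shift of `ring` minimizing summed squared distance to `ref`;
# cost(k) = ||ring||^2 + ||ref||^2 - 2 sum_j ring[j+k] . ref[j], so the
# best shift maximizes the circular cross-correlation (compiled)
best_rotation <- function(ring, ref) {
  best_rotation_cpp(ring, ref)
}

#' Interpolate a contour stack onto a fixed parametric surface grid
#'
#' Each usable slice is resampled to `C` equally spaced circumferential
#' points with a common anchoring rule; a minimal-twist pass re-anchors
#' each slice to the cyclic rotation closest to its predecessor. `L`
#' longitudinal levels are then generated by piecewise-linear interpolation
#' between adjacent slices at uniform normalized positions along the slice
#' ordering, giving every subject the same L x C vertex lattice
#' (anterior-posterior by circumferential) with fixed correspondence.
#'
#' @param stack a [contour_stack()].
#' @param L number of longitudinal levels (default 150).
#' @param C number of circumferential points per level (default 100).
#' @param min_area slices with traced area at or below this (mm^2) are
#'   dropped with a warning; tiny terminal slices from freehand tracing
#'   destabilize resampling.
#' @return an object of class `"parametric_surface"`: an L x C x 3 array of
#'   vertex coordinates (mm) with attributes `subject_id` and `side`.
#' @export
parameterize <- function(stack, L = 150L, C = 100L, min_area = 0.5) {
  stopifnot(inherits(stack, "contour_stack"))
  if (L < 2L) stop("L must be at least 2")
  if (C < 3L) stop("C must be at least 3")
  areas <- vapply(stack$contours, polygon_area, numeric(1))
  keep <- areas > min_area
  if (!all(keep))
    warning(sprintf("subject %s: dropping %d slice(s) with area <= %g mm^2",
                    stack$subject_id, sum(!keep), min_area))
  ks <- stack$contours[keep]
  S <- length(ks)
  if (S < 3L) stop("fewer than 3 usable slices after area filtering")
  rings <- lapply(ks, resample_contour, C = C)
  zs <- vapply(ks, function(k) k$z, numeric(1))
  for (i in 2:S) rings[[i]] <- best_rotation(rings[[i]], rings[[i - 1L]])

  u <- seq(0, S - 1L, length.out = L)
  i0 <- pmin(floor(u), S - 2L)
  fr <- u - i0
  grid <- array(NA_real_, c(L, C, 3L))
  for (l in seq_len(L)) {
    a <- rings[[i0[l] + 1L]]
    b <- rings[[i0[l] + 2L]]
    w <- fr[l]
    grid[l, , 1:2] <- (1 - w) * a + w * b
    grid[l, , 3L] <- (1 - w) * zs[i0[l] + 1L] + w * zs[i0[l] + 2L]
  }
  structure(grid, class = "parametric_surface",
            subject_id = stack$subject_id, side = stack$side)
}

#' @export
print.parametric_surface <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Parametric surface '%s': %d levels x %d circumferential points\n",
              attr(x, "subject_id") %||% "?", d[1L], d[2L]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Medial curve of a parametric surface
#'
#' The central (midline) curve along the anterior-posterior axis: at each
#' level the arithmetic centroid of that level's `C` grid points. Because
#' the points are equally spaced in arc length this is a perimeter-weighted
#' boundary center, exact for symmetric cross-sections.
#'
#' @param surface a [parameterize()] result.
#' @return an object of class `"medial_curve"`: an L x 3 matrix.
#' @export
medial_curve <- function(surface) {
  stopifnot(inherits(surface, "parametric_surface"))
  m <- cbind(rowMeans(surface[, , 1L]),
             rowMeans(surface[, , 2L]),
             rowMeans(surface[, , 3L]))
  structure(m, class = "medial_curve", subject_id = attr(surface, "subject_id"))
}

#' Radial-distance map
#'
#' Per-vertex Euclidean distance from the medial curve point of a level to
#' each surface vertex of that level - the dependent variable of
#' vertex-wise shape statistics. Levels are planar, so the 3D distance
#' equals the in-plane distance.
#'
#' @param surface a [parameterize()] result.
#' @param medial matching [medial_curve()]; computed if omitted.
#' @return an object of class `"radial_map"`: an L x C matrix of
#'   nonnegative distances (mm).
#' @export
radial_map <- function(surface, medial = medial_curve(surface)) {
  stopifnot(inherits(surface, "parametric_surface"))
  if (nrow(medial) != dim(surface)[1L])
    stop("medial curve length does not match surface levels")
  d <- sqrt((surface[, , 1L] - medial[, 1L])^2 +
            (surface[, , 2L] - medial[, 2L])^2 +
            (surface[, , 3L] - medial[, 3L])^2)
  structure(d, class = "radial_map", subject_id = attr(surface, "subject_id"))
}

#' Vertex-wise average of corresponded surfaces
#'
#' Produces the cohort template surface onto which statistical maps are
#' displayed. All surfaces must share the grid dimensions and live in a
#' common (rigidly pre-aligned) space.
#'
#' @param surfaces list of [parameterize()] results.
#' @return a `"parametric_surface"` (subject id `"average"`).
#' @export
average_surface <- function(surfaces) {
  if (!length(surfaces)) stop("empty surface collection")
  dims <- lapply(surfaces, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("surfaces have mixed grid dimensions")
  acc <- Reduce(`+`, lapply(surfaces, unclass)) / length(surfaces)
  structure(acc, class = "parametric_surface", subject_id = "average",
            side = attr(surfaces[[1L]], "side"))
}

## ------------------------------------------------------------------ meshes

#' Triangulate a parametric surface
#'
#' Quads between adjacent levels are split into two triangles; the
#' circumferential wrap (column C to column 1) is closed. Optional end caps
#' fan each terminal ring to its centroid.
#'
#' @param surface a [parameterize()] result.
#' @param caps close the tube ends with triangle fans.
#' @return an object of class `"surface_mesh"`: list with `vertices`
#'   (V x 3) and `faces` (F x 3, 1-based). Vertex `(l-1)*C + c` is grid
#'   point (l, c).
#' @export
surface_to_mesh <- function(surface, caps = FALSE) {
  stopifnot(inherits(surface, "parametric_surface"))
  d <- dim(surface)
  L <- d[1L]; C <- d[2L]
  verts <- cbind(as.vector(t(surface[, , 1L])),
                 as.vector(t(surface[, , 2L])),
                 as.vector(t(surface[, , 3L])))
  l <- rep(seq_len(L - 1L), each = C)
  c0 <- rep(seq_len(C), times = L - 1L)
  c1 <- c0 %% C + 1L
  a <- (l - 1L) * C + c0
  b <- (l - 1L) * C + c1
  cc <- l * C + c1
  dd <- l * C + c0
  faces <- rbind(cbind(a, b, cc), cbind(a, cc, dd))
  if (caps) {
    top <- colMeans(verts[seq_len(C), , drop = FALSE])
    bot <- colMeans(verts[(L - 1L) * C + seq_len(C), , drop = FALSE])
    vt <- nrow(verts) + 1L
    vb <- nrow(verts) + 2L
    verts <- rbind(verts, top, bot)
    j <- seq_len(C); jn <- j %% C + 1L
    faces <- rbind(faces,
                   cbind(jn, j, vt),
                   cbind((L - 1L) * C + j, (L - 1L) * C + jn, vb))
  }
  structure(list(vertices = unname(verts), faces = unname(faces),
                 subject_id = attr(surface, "subject_id")),
            class = "surface_mesh")
}

#' Total triangle area of a mesh
#' @param mesh a [surface_to_mesh()] result.
#' @return area in mm^2.
#' @export
mesh_surface_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], ] - v[f[, 1L], ]
  e2 <- v[f[, 3L], ] - v[f[, 1L], ]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Write a mesh as Wavefront OBJ
#' @param mesh a [surface_to_mesh()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
  f <- mesh$faces
  writeLines(sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  invisible(path)
}

#' Read a Wavefront OBJ mesh (vertices and triangular faces)
#' @param path OBJ path.
#' @return a `"surface_mesh"`.
#' @export
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(t) as.numeric(t[2:4])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(t)
    as.integer(sub("/.*", "", t[2:4]))))
  structure(list(vertices = v, faces = f, subject_id = NA_character_),
            class = "surface_mesh")
}

#' Write a mesh as ASCII PLY, optionally with a per-vertex scalar overlay
#'
#' @param mesh a [surface_to_mesh()] result.
#' @param path output path.
#' @param scalars optional numeric per-vertex values (e.g. t statistics),
#'   written as a `quality` property for external viewers.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, scalars = NULL) {
  v <- mesh$vertices; f <- mesh$faces
  if (!is.null(scalars) && length(scalars) != nrow(v))
    stop("scalars length must equal the vertex count")
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z")
  if (!is.null(scalars)) hdr <- c(hdr, "property float quality")
  hdr <- c(hdr, sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (is.null(scalars)) {
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
  } else {
    writeLines(sprintf("%.9g %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L],
                       scalars), con)
  }
  writeLines(sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L),
             con)
  invisible(path)
}

## -------------------------------------------------------- radial map I/O

#' Write a radial-distance map as CSV
#'
#' L rows x C columns, preceded by comment lines carrying the subject id
#' and grid dimensions.
#'
#' @param map a [radial_map()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_radial_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# subject %s", attr(map, "subject_id") %||% "NA"),
               sprintf("# L %d C %d", nrow(map), ncol(map))), con)
  utils::write.table(unclass(map), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a radial-distance map written by [write_radial_map()]
#' @param path CSV path.
#' @return a `"radial_map"` matrix.
#' @export
read_radial_map <- function(path) {
  hdr <- readLines(path, n = 2L)
  sid <- sub("^# subject ", "", hdr[1L])
  m <- as.matrix(read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(m) <- NULL
  structure(m, class = "radial_map",
            subject_id = if (identical(sid, "NA")) NA_character_ else sid)
}
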