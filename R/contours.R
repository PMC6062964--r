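## contour_io: contour stacks, planimetric volumes, covariate tables

#' Create a single planar contour
#'
#' A contour is one closed tracing of the structure boundary on a coronal
#' slice, stored as an open polygon (the closing edge from the last vertex
#' back to the first is implicit; a duplicated terminal vertex is removed).
#' Orientation is normalized to counter-clockwise.
#'
#' @param points numeric matrix with >= 3 rows and 2 columns (x, y in mm).
#' @param slice_index integer slice number (rostral to caudal).
#' @param z slice position along the anterior-posterior axis, in mm.
#' @param validate check that the polygon is simple (non-self-intersecting)
#'   and non-degenerate.
#' @return an object of class `"contour"`: a list with elements `points`,
#'   `slice_index`, `z`.
#' @export
contour <- function(points, slice_index, z, validate = TRUE) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("contour points must be a numeric matrix with columns x, y")
  n <- nrow(points)
  if (n >= 2L && all(abs(points[1L, ] - points[n, ]) < 1e-12)) {
    points <- points[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L)
    stop(sprintf("contour at slice %s has fewer than 3 distinct vertices",
                 slice_index))
  if (!all(is.finite(points)))
    stop(sprintf("contour at slice %s contains non-finite coordinates",
                 slice_index))
  sa <- signed_area(points)
  if (validate && abs(sa) < 1e-12)
    stop(sprintf("contour at slice %s is degenerate (collinear vertices)",
                 slice_index))
  if (sa < 0) points <- points[rev(seq_len(n)), , drop = FALSE]
  if (validate && polygon_self_intersects(points))
    stop(sprintf("contour at slice %s is self-intersecting", slice_index))
  structure(list(points = points,
                 slice_index = as.integer(slice_index),
                 z = as.numeric(z)),
            class = "contour")
}

signed_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# proper-crossing test over all non-adjacent edge pairs (vectorized)
polygon_self_intersects <- function(p) {
  m <- nrow(p)
  if (m < 4L) return(FALSE)
  a1 <- p
  a2 <- p[c(2:m, 1L), , drop = FALSE]
  ij <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  keep <- ij[, 2L] > ij[, 1L] + 1L & !(ij[, 1L] == 1L & ij[, 2L] == m)
  ij <- ij[keep, , drop = FALSE]
  if (nrow(ij) == 0L) return(FALSE)
  i <- ij[, 1L]; j <- ij[, 2L]
  cr <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cr(a1[i, 1L], a1[i, 2L], a2[i, 1L], a2[i, 2L], a1[j, 1L], a1[j, 2L])
  d2 <- cr(a1[i, 1L], a1[i, 2L], a2[i, 1L], a2[i, 2L], a2[j, 1L], a2[j, 2L])
  d3 <- cr(a1[j, 1L], a1[j, 2L], a2[j, 1L], a2[j, 2L], a1[i, 1L], a1[i, 2L])
  d4 <- cr(a1[j, 1L], a1[j, 2L], a2[j, 1L], a2[j, 2L], a2[i, 1L], a2[i, 2L])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Create a contour stack for one subject
#'
#' @param subject_id character scalar.
#' @param contours list of [contour()] objects, ordered rostral to caudal.
#' @param slice_thickness slice spacing in mm.
#' @param side `"left"` or `"right"`.
#' @param validate check stack invariants (strictly increasing slice
#'   indices, z spacing equal to the thickness, >= 3 slices).
#' @return an object of class `"contour_stack"`.
#' @export
contour_stack <- function(subject_id, contours, slice_thickness,
                          side = c("left", "right"), validate = TRUE) {
  side <- match.arg(side)
  if (validate) {
    if (length(contours) < 3L)
      stop("a contour stack needs at least 3 slices")
    idx <- vapply(contours, function(k) k$slice_index, integer(1))
    if (any(diff(idx) <= 0L))
      stop("slice indices must be strictly increasing")
    if (anyDuplicated(idx))
      stop(sprintf("multiple contours on slice %d; one contour per slice",
                   idx[anyDuplicated(idx)]))
    z <- vapply(contours, function(k) k$z, numeric(1))
    dz <- diff(z) / diff(idx)
    if (any(abs(dz - slice_thickness) > 1e-6 * max(1, slice_thickness)))
      stop("z spacing does not equal the slice thickness")
  }
  structure(list(subject_id = as.character(subject_id),
                 contours = contours,
                 slice_thickness = as.numeric(slice_thickness),
                 side = side),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  cat(sprintf("Contour stack '%s' (%s): %d slices, thickness %g mm, volume %.1f mm^3\n",
              x$subject_id, x$side, length(x$contours), x$slice_thickness,
              stack_volume(x)))
  invisible(x)
}

#' Planar polygon area by the shoelace formula
#'
#' @param x a [contour()] or a numeric matrix of ordered vertices (one
#'   vertex per row, columns x and y, closing edge implicit).
#' @return area in mm^2 (always positive).
#' @export
polygon_area <- function(x) {
  p <- if (inherits(x, "contour")) x$points else as.matrix(x)
  if (nrow(p) < 3L) stop("polygon needs at least 3 vertices")
  a <- abs(signed_area(p))
  if (a < 1e-12) stop("degenerate polygon: collinear vertices")
  a
}

#' Planimetric volume of a contour stack
#'
#' The classical manual-volumetry estimator: the sum over slices of the
#' traced cross-sectional area times the slice thickness.
#'
#' @param stack a [contour_stack()].
#' @return volume in mm^3.
#' @export
stack_volume <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  areas <- vapply(stack$contours, polygon_area, numeric(1))
  sum(areas) * stack$slice_thickness
}

## ---------------------------------------------------------------- file I/O

#' Read a contour stack from file
#'
#' Two formats are supported and auto-detected by extension: the
#' line-oriented `.ctr` text format (header lines `subject`, `side`,
#' `thickness`; then per slice a `slice <index> <z>` line followed by
#' `x y` vertex lines) and a JSON equivalent (`.json`) mirroring the same
#' fields.
#'
#' @param path file path.
#' @param validate validate contours and stack invariants on read.
#' @return a [contour_stack()].
#' @export
read_contour_stack <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    return(read_contour_stack_json(path, validate))
  lines <- readLines(path, warn = FALSE)
  subject_id <- NULL; side <- NULL; thickness <- NULL
  contours <- list()
  cur_idx <- NULL; cur_z <- NULL; cur_pts <- NULL
  flush_slice <- function() {
    if (is.null(cur_idx)) return()
    pts <- do.call(rbind, cur_pts)
    contours[[length(contours) + 1L]] <<-
      contour(pts, cur_idx, cur_z, validate = validate)
  }
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[[ln]])
    if (raw == "" || startsWith(raw, "#")) next
    tok <- strsplit(raw, "\\s+")[[1L]]
    bad <- function(what) stop(sprintf("parse error at line %d of %s: %s",
                                       ln, path, what))
    if (tok[1L] == "subject") {
      if (length(tok) < 2L) bad("missing subject id")
      subject_id <- tok[2L]
    } else if (tok[1L] == "side") {
      if (length(tok) < 2L || !tok[2L] %in% c("left", "right"))
        bad("side must be 'left' or 'right'")
      side <- tok[2L]
    } else if (tok[1L] == "thickness") {
      thickness <- suppressWarnings(as.numeric(tok[2L]))
      if (is.na(thickness)) bad("non-numeric thickness")
    } else if (tok[1L] == "slice") {
      flush_slice()
      if (length(tok) < 3L) bad("slice line needs '<index> <z>'")
      cur_idx <- suppressWarnings(as.integer(tok[2L]))
      cur_z <- suppressWarnings(as.numeric(tok[3L]))
      if (is.na(cur_idx) || is.na(cur_z)) bad("non-numeric slice index or z")
      cur_pts <- list()
    } else {
      xy <- suppressWarnings(as.numeric(tok))
      if (length(xy) != 2L || anyNA(xy)) bad(sprintf("expected 'x y', got '%s'", raw))
      if (is.null(cur_idx)) bad("vertex line before any 'slice' header")
      cur_pts[[length(cur_pts) + 1L]] <- xy
    }
  }
  flush_slice()
  if (is.null(subject_id) || is.null(side) || is.null(thickness))
    stop(sprintf("parse error in %s: missing subject/side/thickness header", path))
  contour_stack(subject_id, contours, thickness, side, validate = validate)
}

read_contour_stack_json <- function(path, validate = TRUE) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("subject_id", "side", "slice_thickness", "contours")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop(sprintf("parse error in %s: missing fields %s", path,
                 paste(miss, collapse = ", ")))
  contours <- lapply(obj$contours, function(k) {
    pts <- matrix(unlist(k$points), ncol = 2L, byrow = TRUE)
    contour(pts, k$slice_index, k$z, validate = validate)
  })
  contour_stack(obj$subject_id, contours, obj$slice_thickness, obj$side,
                validate = validate)
}

#' Write a contour stack to file
#'
#' @param stack a [contour_stack()].
#' @param path output path.
#' @param format `"ctr"` (line-oriented text) or `"json"`; default inferred
#'   from the path extension.
#' @param digits coordinate precision.
#' @return `path`, invisibly.
#' @export
write_contour_stack <- function(stack, path,
                                format = c("auto", "ctr", "json"),
                                digits = 15L) {
  stopifnot(inherits(stack, "contour_stack"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "ctr"
  if (format == "json") {
    obj <- list(
      subject_id = stack$subject_id,
      side = stack$side,
      slice_thickness = stack$slice_thickness,
      contours = lapply(stack$contours, function(k)
        list(slice_index = k$slice_index, z = k$z,
             points = lapply(seq_len(nrow(k$points)), function(i)
               unname(k$points[i, ])))))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    fmt <- function(v) formatC(v, digits = digits, format = "g")
    writeLines(c(paste("subject", stack$subject_id),
                 paste("side", stack$side),
                 paste("thickness", fmt(stack$slice_thickness))), con)
    for (k in stack$contours) {
      writeLines(paste("slice", k$slice_index, fmt(k$z)), con)
      writeLines(paste(fmt(k$points[, 1L]), fmt(k$points[, 2L])), con)
    }
  }
  invisible(path)
}

## ---------------------------------------------------------- covariate table

#' Read and validate a subject covariate table
#'
#' Expects a CSV with header `id,group,age,tiv` and optional columns
#' `alsfrs_r` and `duration_months`. The group column must have exactly two
#' levels; the level given by `control` becomes the factor reference so the
#' group coefficient in downstream models is patient minus control.
#'
#' @param path CSV path.
#' @param control label of the control group (default `"HC"`).
#' @return a `data.frame` with class `"cohort_table"` prepended; `group` is
#'   a two-level factor with the control level first.
#' @export
read_cohort_table <- function(path, control = "HC") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_cohort_table(df, control = control)
}

#' Coerce a data frame to a validated cohort table
#'
#' @param df data frame with columns `id,group,age,tiv` (plus optional
#'   clinical columns).
#' @inheritParams read_cohort_table
#' @return see [read_cohort_table()].
#' @export
as_cohort_table <- function(df, control = "HC") {
  required <- c("id", "group", "age", "tiv")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("covariate table is missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(df$id))
    stop(sprintf("duplicate subject id(s): %s",
                 paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
  if (any(!is.finite(df$tiv)) || any(df$tiv <= 0))
    stop("TIV must be positive for every subject")
  lev <- unique(as.character(df$group))
  if (length(lev) != 2L)
    stop(sprintf("group must have exactly two levels, found: %s",
                 paste(lev, collapse = ", ")))
  if (!control %in% lev)
    stop(sprintf("control level '%s' not present in group column (%s)",
                 control, paste(lev, collapse = ", ")))
  patient <- setdiff(lev, control)
  df$group <- factor(as.character(df$group), levels = c(control, patient))
  df$age <- as.numeric(df$age)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write analysis result tables
#'
#' Thin CSV writer used by the pipeline stages; kept exported so results
#' round-trip through the same conventions as the inputs.
#'
#' @param df data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
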