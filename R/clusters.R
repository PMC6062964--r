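## connected components on the tube grid, TFCE, ROI partition

#' Label connected components of a supra-threshold mask
#'
#' Components are found under 4-neighbour connectivity (8-neighbour
#' optionally) on the L x C parametric grid. The grid is a tube: column C
#' is adjacent to column 1 (circumferential wrap); rows never wrap.
#'
#' @param mask logical L x C matrix.
#' @param connectivity 4 (default) or 8.
#' @param wrap join columns 1 and C (default `TRUE`).
#' @return list with `labels` (integer L x C, 0 = background, clusters
#'   numbered 1..K in decreasing size) and `sizes` (vertices per cluster,
#'   decreasing).
#' @export
flood_fill_clusters <- function(mask, connectivity = 4L, wrap = TRUE) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  storage.mode(mask) <- "logical"
  lab <- label_components_cpp(mask, wrap, connectivity == 8L)
  k <- max(lab)
  if (k == 0L) return(list(labels = lab, sizes = integer(0)))
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  ord <- order(sizes, decreasing = TRUE)
  relab <- integer(k)
  relab[ord] <- seq_len(k)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  list(labels = lab, sizes = sizes[ord])
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' Each vertex's statistic is replaced by the discrete integral, over
#' thresholds `h = dh, 2dh, ...` up to the vertex's value, of
#' `extent(h)^E * h^H * dh`, where `extent(h)` is the size (in vertices)
#' of the connected component containing the vertex at threshold `h`
#' (same tube connectivity as [flood_fill_clusters()]). Negative values
#' are enhanced on the negated map and returned with negative sign, so
#' inward and outward effects stay distinguishable.
#'
#' @param t_map numeric L x C matrix (e.g. `shape_lm()$t`).
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step; default `max(abs(t_map))/100`.
#' @param connectivity,wrap as in [flood_fill_clusters()].
#' @return enhanced map, same dimensions.
#' @export
tfce_enhance <- function(t_map, E = 0.5, H = 2, dh = NULL,
                         connectivity = 4L, wrap = TRUE) {
  if (!all(is.finite(t_map))) stop("t_map must be finite")
  hmax <- max(abs(t_map))
  if (is.null(dh)) dh <- hmax / 100
  if (!is.finite(dh) || dh <= 0) {
    if (hmax == 0) return(t_map * 0)
    stop("dh must be positive")
  }
  out <- t_map * 0
  for (sgn in c(1, -1)) {
    m <- sgn * t_map
    top <- max(m)
    if (top < dh) next
    hs <- seq(dh, top, by = dh)
    acc <- m * 0
    for (h in hs) {
      cl <- flood_fill_clusters(m >= h, connectivity, wrap)
      if (!length(cl$sizes)) next
      inside <- cl$labels > 0L
      acc[inside] <- acc[inside] + cl$sizes[cl$labels[inside]]^E * h^H * dh
    }
    out <- out + sgn * acc
  }
  out
}

#' Partition the longitudinal axis into head, body, and tail bands
#'
#' Anterior band = head, middle = body, posterior = tail; each band is a
#' contiguous run of whole levels. Boundary fractions default to equal
#' thirds; the anatomical head/body/tail boundaries are a convention, not
#' a measurement, so they are configurable.
#'
#' @param L number of longitudinal levels.
#' @param C number of circumferential points.
#' @param fractions positive length-3 vector summing to 1.
#' @return an object of class `"roi_partition"`: named list of logical
#'   L x C masks (`head`, `body`, `tail`) that partition the grid.
#' @export
roi_partition <- function(L, C, fractions = c(1, 1, 1) / 3) {
  if (length(fractions) != 3L || any(fractions <= 0))
    stop("fractions must be 3 positive values")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1")
  bnd <- round(cumsum(fractions) * L)
  bnd[3L] <- L
  starts <- c(1L, bnd[1L] + 1L, bnd[2L] + 1L)
  ends <- bnd
  if (any(ends < starts))
    stop("a band contains zero levels; increase L or adjust fractions")
  masks <- Map(function(s, e) {
    m <- matrix(FALSE, L, C)
    m[s:e, ] <- TRUE
    m
  }, starts, ends)
  names(masks) <- c("head", "body", "tail")
  structure(masks, class = "roi_partition",
            boundaries = ends, fractions = fractions)
}

#' @export
print.roi_partition <- function(x, ...) {
  b <- attr(x, "boundaries")
  cat(sprintf("ROI partition: head levels 1-%d, body %d-%d, tail %d-%d\n",
              b[1L], b[1L] + 1L, b[2L], b[2L] + 1L, b[3L]))
  invisible(x)
}
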