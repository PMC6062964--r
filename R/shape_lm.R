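## vertex-wise general linear model on radial-distance maps

#' Fit a vertex-wise linear model to radial-distance maps
#'
#' At every vertex of the L x C parametric grid, the subject radial
#' distances are regressed on a common design (typically
#' `~ group + age + tiv`: group as the effect of interest, age and total
#' intracranial volume as covariates of no interest). The fit is ordinary
#' least squares, independently per vertex; the t statistic of the tested
#' term and its two-sided p value (Student t, `n - p` residual degrees of
#' freedom) are returned as maps.
#'
#' With the group factor coded control-first (as [read_cohort_table()]
#' does), the group coefficient is patient minus control, so negative t
#' values index inward deformation (surface shrinkage) in patients and
#' positive values outward coves.
#'
#' @param formula right-hand-side formula evaluated in `data`, e.g.
#'   `~ group + age + tiv`.
#' @param data data frame of per-subject covariates, one row per map.
#' @param maps list of [radial_map()] matrices (one per subject, equal
#'   dimensions, same order as `data` rows).
#' @param term name of the model term whose effect is tested (default
#'   `"group"`); must map to a single design-matrix column.
#' @return an object of class `"shape_lm"` with components `t`, `p`
#'   (L x C matrices), `coefficients` (parameters x L x C array), `df`,
#'   the design matrix `X`, the response matrix `Y` (subjects x vertices,
#'   column-major vertex order), and bookkeeping fields.
#' @seealso [permutation_cluster_test()], [tfce_enhance()]
#' @export
shape_lm <- function(formula, data, maps, term = "group") {
  cl <- match.call()
  if (!is.list(maps) || !length(maps)) stop("maps must be a non-empty list")
  d <- dim(maps[[1L]])
  if (!all(vapply(maps, function(m) identical(dim(m), d), logical(1))))
    stop("all radial maps must share the same L x C dimensions")
  n <- length(maps)
  if (n != nrow(data)) stop("length(maps) must equal nrow(data)")

  X <- model.matrix(formula, data)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  if (n < p + 2L) stop("need at least ncol(design) + 2 subjects")

  tl <- attr(terms(formula, data = data), "term.labels")
  ti <- match(term, tl)
  if (is.na(ti)) stop(sprintf("term '%s' not found in the formula", term))
  j <- which(attr(X, "assign") == ti)
  if (length(j) != 1L)
    stop(sprintf("term '%s' maps to %d design columns; a single column is required (use a two-level factor or numeric indicator)",
                 term, length(j)))

  Y <- do.call(rbind, lapply(maps, as.vector))   # n x V, column-major grid
  qrX <- qr(X)
  coefs <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  df <- n - p
  sigma2 <- colSums(res^2) / df
  cjj <- solve(crossprod(X))[j, j]
  se <- sqrt(sigma2 * cjj)
  tv <- coefs[j, ] / se
  # zero-residual vertices: a real effect saturates at +-1e8, numerical
  # dust (coefficient at rounding level) is a true zero
  tol <- 1e-10 * (max(abs(Y)) + 1)
  degen <- se < tol
  tv[degen] <- ifelse(abs(coefs[j, degen]) < tol, 0,
                      sign(coefs[j, degen]) * 1e8)
  tv[!is.finite(tv)] <- 0
  pv <- pmax(2 * pt(-abs(tv), df), .Machine$double.xmin)

  structure(list(
    call = cl, formula = formula, term = term,
    X = X, Y = Y, contrast_index = j, df = df,
    coefficients = array(coefs, c(p, d),
                         dimnames = list(colnames(X), NULL, NULL)),
    t = matrix(tv, d[1L], d[2L]),
    p = matrix(pv, d[1L], d[2L]),
    sigma = matrix(sqrt(sigma2), d[1L], d[2L]),
    dims = d, n = n,
    subjects = if (!is.null(data$id)) as.character(data$id) else rownames(data)
  ), class = "shape_lm")
}

#' @export
print.shape_lm <- function(x, ...) {
  cat("Vertex-wise linear model on radial-distance maps\n")
  cat(sprintf("  grid: %d levels x %d circumferential points (%d vertices)\n",
              x$dims[1L], x$dims[2L], prod(x$dims)))
  cat(sprintf("  design: %s, tested term: '%s', n = %d, residual df = %d\n",
              deparse(x$formula), x$term, x$n, x$df))
  cat(sprintf("  t range: [%.3f, %.3f]\n", min(x$t), max(x$t)))
  invisible(x)
}

#' @export
summary.shape_lm <- function(object, cluster_forming_p = 0.05, ...) {
  supra <- object$p < cluster_forming_p
  out <- list(
    dims = object$dims, n = object$n, df = object$df, term = object$term,
    formula = object$formula,
    t_range = range(object$t),
    n_supra = sum(supra),
    n_supra_neg = sum(supra & object$t < 0),
    n_supra_pos = sum(supra & object$t > 0),
    cluster_forming_p = cluster_forming_p,
    min_p = min(object$p))
  class(out) <- "summary.shape_lm"
  out
}

#' @export
print.summary.shape_lm <- function(x, ...) {
  cat("Vertex-wise linear model on radial-distance maps\n")
  cat(sprintf("  %d x %d grid, n = %d subjects, residual df = %d, term '%s'\n",
              x$dims[1L], x$dims[2L], x$n, x$df, x$term))
  cat(sprintf("  t range [%.3f, %.3f], smallest uncorrected p = %.3g\n",
              x$t_range[1L], x$t_range[2L], x$min_p))
  cat(sprintf("  vertices below p < %g: %d (%d inward, %d outward)\n",
              x$cluster_forming_p, x$n_supra, x$n_supra_neg, x$n_supra_pos))
  invisible(x)
}

#' @export
coef.shape_lm <- function(object, ...) object$coefficients

#' @export
residuals.shape_lm <- function(object, ...) qr.resid(qr(object$X), object$Y)

#' @export
fitted.shape_lm <- function(object, ...) qr.fitted(qr(object$X), object$Y)

#' Flat-map display of a fitted shape model
#'
#' Displays the t (or p, or group-effect) map as an image in grid
#' coordinates: longitudinal level (anterior at the left) against
#' circumferential position. Optionally outlines clusters from a
#' [permutation_cluster_test()].
#'
#' @param x a [shape_lm()] fit.
#' @param what which map to draw.
#' @param clusters optional `"cluster_result"` whose labelled clusters are
#'   outlined.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.shape_lm <- function(x, what = c("t", "p", "effect"), clusters = NULL,
                          ...) {
  what <- match.arg(what)
  m <- switch(what, t = x$t, p = log10(x$p),
              effect = matrix(x$coefficients[x$contrast_index, , ],
                              x$dims[1L], x$dims[2L]))
  lab <- switch(what, t = "t value", p = "log10 p", effect = "effect (mm)")
  lim <- max(abs(m))
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  col = grDevices::hcl.colors(65, "Blue-Red 3"),
                  zlim = c(-lim, lim),
                  xlab = "longitudinal level (anterior → posterior)",
                  ylab = "circumferential position",
                  main = sprintf("%s map (%s)", lab, x$term), ...)
  if (!is.null(clusters)) {
    lm_ <- clusters$label_map
    graphics::contour(seq_len(nrow(lm_)), seq_len(ncol(lm_)),
                      (lm_ > 0) + 0, levels = 0.5, add = TRUE,
                      drawlabels = FALSE, lwd = 2)
  }
  invisible(x)
}
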