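## volume statistics: TIV covariance adjustment, group tests, correlations

#' Fit the TIV covariance adjustment on control subjects
#'
#' Head-size normalization of regional volumes by the covariance method:
#' the slope alpha of the ordinary least-squares regression of volume on
#' total intracranial volume (TIV) is estimated in controls only, together
#' with the control mean TIV. Adjusted volumes are then
#' `HV - alpha * (TIV - mean TIV of controls)`.
#'
#' @param volumes control-group regional volumes (mm^3).
#' @param tivs control-group TIVs (mm^3).
#' @return an object of class `"tiv_adjustment"` with elements `alpha`,
#'   `control_mean_tiv`, `n`.
#' @export
fit_tiv_adjustment <- function(volumes, tivs) {
  if (length(volumes) != length(tivs))
    stop("volumes and tivs must have equal length")
  ok <- is.finite(volumes) & is.finite(tivs)
  volumes <- volumes[ok]; tivs <- tivs[ok]
  if (length(volumes) < 3L)
    stop("at least 3 control subjects are required")
  if (var(tivs) <= 0)
    stop("control TIVs have zero variance; slope is undefined")
  alpha <- stats::cov(volumes, tivs) / var(tivs)
  structure(list(alpha = alpha, control_mean_tiv = mean(tivs),
                 n = length(volumes)),
            class = "tiv_adjustment")
}

#' @export
print.tiv_adjustment <- function(x, ...) {
  cat(sprintf("TIV adjustment: alpha = %.6g (mm^3 per mm^3 TIV), control mean TIV = %.6g mm^3 (n = %d controls)\n",
              x$alpha, x$control_mean_tiv, x$n))
  invisible(x)
}

#' @export
coef.tiv_adjustment <- function(object, ...) {
  c(alpha = object$alpha, control_mean_tiv = object$control_mean_tiv)
}

#' Apply a fitted TIV adjustment
#'
#' @param model a [fit_tiv_adjustment()] result.
#' @param volumes volumes to adjust (mm^3), any subjects.
#' @param tivs matching TIVs (mm^3).
#' @return adjusted volumes (mm^3). A subject at the control mean TIV is
#'   returned unchanged.
#' @export
apply_tiv_adjustment <- function(model, volumes, tivs) {
  stopifnot(inherits(model, "tiv_adjustment"))
  volumes - model$alpha * (tivs - model$control_mean_tiv)
}

#' Group difference in adjusted volumes
#'
#' Fixed-effects linear model of adjusted volume on group and age; reports
#' the partial (drop-one) F test for the group term. Significance is
#' flagged at a Bonferroni-adjusted level (default 0.025, two hemispheres
#' tested separately).
#'
#' @param volumes adjusted volumes (mm^3).
#' @param group two-level factor (control level first).
#' @param age ages in years.
#' @param alpha_level significance level after Bonferroni adjustment.
#' @return list with `F`, `p`, `df`, `significant`, and the fitted `lm`.
#' @export
group_volume_test <- function(volumes, group, age, alpha_level = 0.025) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  if (min(table(group)) < 3L) stop("at least 3 subjects per group")
  df <- data.frame(v = volumes, group = group, age = age)
  fit <- lm(v ~ group + age, data = df)
  if (fit$rank < 3L) stop("rank-deficient design (group or age constant)")
  dr <- stats::drop1(fit, scope = ~group, test = "F")
  Fv <- dr[["F value"]][2L]
  pv <- dr[["Pr(>F)"]][2L]
  list(F = Fv, p = pv, df = c(1L, fit$df.residual),
       significant = pv < alpha_level, model = fit)
}

#' Spearman rank correlation between volumes and a clinical score
#'
#' Pairs with a missing value in either variable are dropped.
#'
#' @param volumes volumes (mm^3).
#' @param scores clinical scores (e.g. ALSFRS-R, disease duration).
#' @return list with `rho`, `p` (two-sided), and `n` pairs used.
#' @export
clinical_correlation <- function(volumes, scores) {
  ok <- is.finite(volumes) & is.finite(scores)
  x <- volumes[ok]; y <- scores[ok]
  if (length(x) < 5L) stop("fewer than 5 complete pairs")
  if (var(y) == 0 || var(x) == 0) stop("a variable is constant (all tied)")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
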