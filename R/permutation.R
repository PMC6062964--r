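## permutation-based family-wise error correction by maximum cluster size

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Permutation test of supra-threshold cluster sizes
#'
#' Corrects the vertex-wise group test of a [shape_lm()] fit for multiple
#' comparisons by the maximum-cluster-size permutation method. Vertices
#' with uncorrected two-sided p below `cluster_forming_p` form
#' sign-segregated masks (inward and outward deformations are clustered
#' separately); connected components of those masks are the observed
#' clusters. The null distribution of the maximum cluster size (over both
#' signs) is built by permutation, and each observed cluster receives the
#' family-wise corrected p value
#' `(1 + #permutation maxima >= size) / (n_perm + 1)`.
#'
#' Covariates are respected by Freedman-Lane residual permutation by
#' default: residuals of the reduced model (design without the tested
#' term) are permuted across subjects, the reduced-model fit is added
#' back, and the full model is refit. Plain permutation of the group
#' column is available via `scheme = "labels"`. When fewer distinct
#' permutations than `n_perm` exist (tiny cohorts) the test enumerates
#' all of them exhaustively, with a warning.
#'
#' @param fit a [shape_lm()] object.
#' @param cluster_forming_p vertex-level two-sided p threshold forming
#'   clusters (default 0.05).
#' @param n_perm number of permutations (>= 100; default 10000).
#' @param seed integer seed, mandatory: permutation analyses must be
#'   reproducible.
#' @param scheme `"freedman_lane"` (default) or `"labels"`.
#' @param mask optional logical L x C matrix restricting the analysis
#'   (cluster forming and the null maximum) to a region of interest.
#' @param connectivity,wrap cluster connectivity, see
#'   [flood_fill_clusters()].
#' @return an object of class `"cluster_result"`: `label_map` (L x C,
#'   0 background, clusters numbered by decreasing size), `sizes`, `sign`
#'   (+1 outward / -1 inward per cluster), `corrected_p`, `null_max`
#'   (permutation maxima), plus the thresholds, scheme, seed and
#'   `n_perm` used.
#' @export
permutation_cluster_test <- function(fit, cluster_forming_p = 0.05,
                                     n_perm = 10000L, seed,
                                     scheme = c("freedman_lane", "labels"),
                                     mask = NULL, connectivity = 4L,
                                     wrap = TRUE) {
  stopifnot(inherits(fit, "shape_lm"))
  scheme <- match.arg(scheme)
  if (missing(seed)) stop("an explicit integer seed is required")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  L <- fit$dims[1L]; C <- fit$dims[2L]; n <- fit$n
  if (!is.null(mask)) {
    mask <- matrix(as.logical(mask), L, C)
    if (!any(mask)) stop("mask is empty")
  }

  ## observed clusters, sign-segregated
  supra <- fit$p < cluster_forming_p
  if (!is.null(mask)) supra <- supra & mask
  pos <- flood_fill_clusters(supra & fit$t > 0, connectivity, wrap)
  neg <- flood_fill_clusters(supra & fit$t < 0, connectivity, wrap)
  label_map <- pos$labels
  off <- length(pos$sizes)
  label_map[neg$labels > 0L] <- neg$labels[neg$labels > 0L] + off
  sizes <- c(pos$sizes, neg$sizes)
  signs <- c(rep(1L, length(pos$sizes)), rep(-1L, length(neg$sizes)))
  if (length(sizes)) {
    ord <- order(sizes, decreasing = TRUE)
    relab <- integer(length(sizes))
    relab[ord] <- seq_along(sizes)
    label_map[label_map > 0L] <- relab[label_map[label_map > 0L]]
    sizes <- sizes[ord]
    signs <- signs[ord]
  }

  ## permutation null of the maximum cluster size
  n_distinct <- suppressWarnings(factorial(n))
  exhaustive <- is.finite(n_distinct) && n_distinct <= n_perm
  if (exhaustive) {
    warning(sprintf("only %d distinct permutations exist; enumerating exhaustively",
                    as.integer(n_distinct)))
    perms <- all_permutations(n)
  } else {
    perms <- with_local_seed(seed, {
      t(replicate(n_perm, sample.int(n)))
    })
  }
  t_thr <- qt(1 - cluster_forming_p / 2, fit$df)
  null_max <- perm_maxcluster_cpp(fit$Y, fit$X, fit$contrast_index, perms,
                                  scheme, t_thr, L, C, mask, wrap,
                                  connectivity == 8L)
  corrected_p <- if (exhaustive) {
    vapply(sizes, function(s) mean(null_max >= s), numeric(1))
  } else {
    vapply(sizes, function(s) (1 + sum(null_max >= s)) / (n_perm + 1),
           numeric(1))
  }

  structure(list(label_map = label_map, sizes = sizes, sign = signs,
                 corrected_p = corrected_p, null_max = as.integer(null_max),
                 n_perm = nrow(perms), seed = seed,
                 cluster_forming_p = cluster_forming_p, scheme = scheme,
                 exhaustive = exhaustive, mask = mask,
                 connectivity = connectivity, wrap = wrap, df = fit$df),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Permutation max-cluster test: %d permutations (%s%s), cluster-forming p < %g\n",
              x$n_perm, x$scheme, if (x$exhaustive) ", exhaustive" else "",
              x$cluster_forming_p))
  if (!length(x$sizes)) {
    cat("  no supra-threshold clusters\n")
  } else {
    tab <- cluster_table(x)
    print(head(tab, 10L), row.names = FALSE)
    if (nrow(tab) > 10L)
      cat(sprintf("  ... and %d smaller cluster(s)\n", nrow(tab) - 10L))
  }
  invisible(x)
}

#' Tabulate a cluster result
#'
#' @param x a [permutation_cluster_test()] result, or a named list of them
#'   (e.g. from [roi_cluster_test()]).
#' @return data frame with columns `cluster_id`, `size`, `corrected_p`,
#'   `sign`, `roi`.
#' @export
cluster_table <- function(x) {
  if (inherits(x, "cluster_result")) x <- list(whole = x)
  do.call(rbind, lapply(names(x), function(nm) {
    r <- x[[nm]]
    if (!length(r$sizes))
      return(data.frame(cluster_id = integer(0), size = integer(0),
                        corrected_p = numeric(0), sign = character(0),
                        roi = character(0)))
    data.frame(cluster_id = seq_along(r$sizes), size = r$sizes,
               corrected_p = r$corrected_p,
               sign = ifelse(r$sign < 0, "inward", "outward"),
               roi = nm)
  }))
}

#' Region-of-interest cluster tests
#'
#' Re-runs [permutation_cluster_test()] restricted to each band of a
#' [roi_partition()] (the null maximum is computed within the band), as in
#' head/body/tail analyses of the hippocampus.
#'
#' @param fit a [shape_lm()] object.
#' @param partition a [roi_partition()]; defaults to equal thirds.
#' @param ... passed to [permutation_cluster_test()] (`seed` is required).
#' @return named list of `"cluster_result"` objects, one per band.
#' @export
roi_cluster_test <- function(fit,
                             partition = roi_partition(fit$dims[1L],
                                                       fit$dims[2L]),
                             ...) {
  stopifnot(inherits(partition, "roi_partition"))
  lapply(partition, function(m) permutation_cluster_test(fit, mask = m, ...))
}
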