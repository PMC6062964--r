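# fixtures and independent oracles used across the test files

# regular n-gon of circumradius r (counter-clockwise, open)
ngon <- function(r, n = 100L, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
}

# stack of identical polygons at spacing `thickness`
polygon_stack <- function(poly, n_slices, thickness = 1, id = "s") {
  contour_stack(id, lapply(seq_len(n_slices), function(i)
    contour(poly, i, (i - 1L) * thickness)), thickness, "left")
}

# brute-force depth-first component labelling with circumferential wrap;
# independent of the package's C++ implementation
dfs_components <- function(mask, wrap = TRUE, eight = FALSE) {
  L <- nrow(mask); C <- ncol(mask)
  lab <- matrix(0L, L, C)
  k <- 0L
  nb <- if (eight)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (c0 in seq_len(C)) for (l0 in seq_len(L)) {
    if (!mask[l0, c0] || lab[l0, c0]) next
    k <- k + 1L
    st <- list(c(l0, c0))
    lab[l0, c0] <- k
    while (length(st)) {
      cur <- st[[length(st)]]
      st[[length(st)]] <- NULL
      for (d in nb) {
        ll <- cur[1L] + d[1L]; cc <- cur[2L] + d[2L]
        if (ll < 1L || ll > L) next
        if (wrap) cc <- ((cc - 1L) %% C) + 1L else if (cc < 1L || cc > C) next
        if (mask[ll, cc] && !lab[ll, cc]) {
          lab[ll, cc] <- k
          st[[length(st) + 1L]] <- c(ll, cc)
        }
      }
    }
  }
  lab
}

# canonical form of a labelling: replace every label by the smallest cell
# index of its component, so two labelings can be compared as partitions
canon_labels <- function(lab) {
  out <- lab
  for (k in setdiff(unique(as.vector(lab)), 0L))
    out[lab == k] <- min(which(lab == k))
  out
}

# normal-equations OLS t statistic for coefficient j (independent oracle)
ols_t_oracle <- function(y, X, j) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  b[j] / sqrt(s2 * solve(XtX)[j, j])
}

# partial F for dropping column set `drop` (independent oracle)
ols_F_oracle <- function(y, X, drop) {
  rss <- function(M) {
    b <- solve(crossprod(M), crossprod(M, y))
    sum((y - M %*% b)^2)
  }
  r1 <- rss(X); r0 <- rss(X[, -drop, drop = FALSE])
  df2 <- nrow(X) - ncol(X)
  ((r0 - r1) / length(drop)) / (r1 / df2)
}

# independent geometric route to the expected deformed/undeformed volume
# ratio: noiseless polygon stacks through the planimetric estimator
noiseless_deformed_ratio <- function(cfg) {
  d <- list(patch = cfg$patch, delta = cfg$delta)
  v1 <- stack_volume(generate_subject_stack(cfg$template, "d",
                                            deformation = d, sigma = 0,
                                            seed = 1L, L = cfg$L, C = cfg$C))
  v0 <- stack_volume(generate_subject_stack(cfg$template, "u", sigma = 0,
                                            seed = 1L, L = cfg$L, C = cfg$C))
  v1 / v0
}

# small deterministic cohort of radial maps with an optional patch effect
toy_map_cohort <- function(n_per = 6L, L = 8L, C = 6L, effect = 0,
                           patch = NULL, sigma = 0.1, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per
  group <- factor(rep(c("HC", "ALS"), each = n_per), levels = c("HC", "ALS"))
  data <- data.frame(id = sprintf("s%02d", seq_len(n)), group = group,
                     age = rnorm(n, 60, 8), tiv = rnorm(n, 1.5e6, 1e5))
  maps <- lapply(seq_len(n), function(i) {
    m <- matrix(5, L, C) + matrix(rnorm(L * C, 0, sigma), L, C)
    if (group[i] == "ALS" && !is.null(patch)) m[patch] <- m[patch] - effect
    m
  })
  list(data = data, maps = maps)
}
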