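test_that("resampling spaces points uniformly in arc length", {
  # near-circle: C = 4 gives points at 90 degree spacing, radius preserved
  pts <- resample_contour(ngon(1, 1000L), 4L)
  d <- sqrt(rowSums(pts^2))
  expect_equal(d, rep(1, 4), tolerance = 1e-3)
  gaps <- sqrt(rowSums((pts[c(2:4, 1), ] - pts)^2))
  expect_equal(gaps, rep(sqrt(2), 4), tolerance = 1e-3)

  # unit square with C = 8: all consecutive gaps equal perimeter / C = 0.5
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  pts <- resample_contour(sq, 8L)
  gaps <- sqrt(rowSums((pts[c(2:8, 1), ] - pts)^2))
  expect_equal(gaps, rep(0.5, 8), tolerance = 1e-9)

  expect_error(resample_contour(sq, 2L), "at least 3")
})

test_that("resampling preserves perimeter and is idempotent", {
  set.seed(21)
  th <- 2 * pi * (0:199) / 200
  wavy <- cbind(3 * (1 + 0.15 * sin(3 * th)) * cos(th),
                3 * (1 + 0.15 * sin(3 * th)) * sin(th))
  shapes <- list(wavy, ngon(1.5, 77L), sweep(ngon(2, 120L), 2, c(4, -1), "+"))
  for (p in shapes) {
    per0 <- sum(sqrt(rowSums((p[c(2:nrow(p), 1), ] - p)^2)))
    r1 <- resample_contour(p, 100L)
    per1 <- sum(sqrt(rowSums((r1[c(2:100, 1), ] - r1)^2)))
    expect_lt(abs(per1 - per0) / per0, 0.01)
    r2 <- resample_contour(r1, 100L)
    expect_equal(r2, r1, tolerance = 1e-6)
  }
})

test_that("parameterization interpolates radii linearly between slices", {
  ks <- lapply(1:3, function(i) contour(ngon(i, 200L), i, i - 1))
  st <- contour_stack("s", ks, 1, "left")
  surf <- parameterize(st, L = 5L, C = 60L)
  expect_equal(dim(surf), c(5L, 60L, 3L))
  radii <- rowMeans(radial_map(surf))
  expect_equal(radii, c(1, 1.5, 2, 2.5, 3), tolerance = 1e-3)
  expect_equal(surf[, 1, 3][c(1, 5)], c(0, 2), tolerance = 1e-12)
})

test_that("the default grid has 100 x 150 = 15000 vertices", {
  st <- polygon_stack(ngon(3, 80L), 6L, 1)
  surf <- parameterize(st)
  expect_identical(dim(surf), c(150L, 100L, 3L))
  expect_equal(prod(dim(surf)[1:2]), 15000)
})

test_that("identical circular slices give a constant radial map", {
  st <- polygon_stack(ngon(1, 500L), 5L, 1)
  rm_ <- radial_map(parameterize(st, L = 10L, C = 50L))
  expect_true(all(abs(rm_ - 1) < 1e-3))
})

test_that("medial curve is the per-level centroid", {
  # circles centered at (3, 4, z)
  ks <- lapply(1:4, function(i)
    contour(ngon(2, 300L, center = c(3, 4)), i, i - 1))
  st <- contour_stack("s", ks, 1, "left")
  med <- medial_curve(parameterize(st, L = 6L, C = 100L))
  expect_equal(med[, 1], rep(3, 6), tolerance = 1e-6)
  expect_equal(med[, 2], rep(4, 6), tolerance = 1e-6)

  # ellipse semi-axes (2, 1): centroid of the equal-arc sample near origin
  th <- 2 * pi * (0:999) / 1000
  ell <- cbind(2 * cos(th), sin(th))
  st <- polygon_stack(ell, 4L, 1)
  med <- medial_curve(parameterize(st, L = 4L, C = 100L))
  expect_lt(max(abs(med[, 1:2])), 0.02)
})

test_that("radial map recovers analytic ellipse radii and scales exactly", {
  th <- 2 * pi * (0:999) / 1000
  ell <- cbind(2 * cos(th), sin(th))
  st <- polygon_stack(ell, 4L, 1)
  surf <- parameterize(st, L = 4L, C = 100L)
  rm_ <- radial_map(surf)
  expect_equal(min(rm_), 1, tolerance = 5e-3)
  expect_equal(max(rm_), 2, tolerance = 5e-3)

  k <- 2.5
  surf_k <- surf
  surf_k[] <- surf[] * k
  expect_equal(unclass(radial_map(surf_k)), unclass(rm_) * k,
               tolerance = 1e-12)
})

test_that("rigid translation moves surface and medial curve, not the map", {
  set.seed(31)
  st <- polygon_stack(ngon(2, 150L) * (1 + 0.05 * runif(150)), 5L, 1)
  surf <- parameterize(st, L = 12L, C = 40L)
  d <- c(7.3, -2.1, 4.4)
  ks2 <- lapply(seq_along(st$contours), function(i) {
    k <- st$contours[[i]]
    contour(sweep(k$points, 2, d[1:2], "+"), k$slice_index, k$z + d[3])
  })
  # shifted stack: z offset changes z but spacing is intact
  st2 <- contour_stack("s", ks2, 1, "left", validate = FALSE)
  surf2 <- parameterize(st2, L = 12L, C = 40L)
  expect_equal(unclass(surf2) - unclass(surf),
               array(rep(d, each = 12 * 40), dim = dim(surf)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unclass(radial_map(surf2)), unclass(radial_map(surf)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unclass(medial_curve(surf2)) - unclass(medial_curve(surf)),
               matrix(rep(d, each = 12), 12, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("average surface is the vertex-wise mean", {
  st1 <- polygon_stack(ngon(1, 300L), 4L, 1)
  st3 <- polygon_stack(ngon(3, 300L), 4L, 1)
  s1 <- parameterize(st1, L = 6L, C = 50L)
  s3 <- parameterize(st3, L = 6L, C = 50L)
  expect_equal(unclass(average_surface(list(s1))), unclass(s1),
               ignore_attr = TRUE)
  avg <- average_surface(list(s1, s3))
  expect_equal(mean(radial_map(avg)), 2, tolerance = 1e-3)
  expect_error(average_surface(list()), "empty")
  expect_error(average_surface(list(s1, parameterize(st1, L = 5L, C = 50L))),
               "mixed")
})

test_that("meshing counts triangles and matches analytic cylinder area", {
  st <- polygon_stack(ngon(1, 100L), 3L, 1)
  surf <- parameterize(st, L = 2L, C = 3L)
  mesh <- surface_to_mesh(surf)
  expect_identical(nrow(mesh$faces), 6L)       # 3 quads -> 6 triangles
  expect_identical(nrow(mesh$vertices), 6L)
  capped <- surface_to_mesh(surf, caps = TRUE)
  expect_identical(nrow(capped$faces), 12L)

  cyl <- polygon_stack(ngon(5, 400L), 40L, 1)
  area <- mesh_surface_area(surface_to_mesh(parameterize(cyl, 150L, 100L)))
  expect_lt(abs(area - 2 * pi * 5 * 39) / (2 * pi * 5 * 39), 0.01)
})

test_that("OBJ, PLY and radial-map files round-trip", {
  st <- polygon_stack(ngon(2, 80L), 4L, 1)
  surf <- parameterize(st, L = 5L, C = 12L)
  mesh <- surface_to_mesh(surf)
  obj <- file.path(tempdir(), "m.obj")
  write_obj(mesh, obj)
  m2 <- read_obj(obj)
  expect_equal(m2$vertices, mesh$vertices, tolerance = 1e-6)
  expect_identical(m2$faces, mesh$faces)

  ply <- file.path(tempdir(), "m.ply")
  write_ply(mesh, ply, scalars = seq_len(nrow(mesh$vertices)))
  expect_match(readLines(ply, n = 7)[7], "quality")

  rmp <- file.path(tempdir(), "r.csv")
  map <- radial_map(surf)
  write_radial_map(map, rmp)
  map2 <- read_radial_map(rmp)
  expect_equal(unclass(map2), unclass(map), tolerance = 1e-9)
  expect_identical(attr(map2, "subject_id"), "s")
})

test_that("tiny terminal slices are dropped with a warning", {
  ks <- c(lapply(1:4, function(i) contour(ngon(2, 60L), i, i - 1)),
          list(contour(ngon(0.3, 60L), 5L, 4)))   # area ~0.28 mm^2
  st <- contour_stack("s", ks, 1, "left")
  expect_warning(surf <- parameterize(st, L = 5L, C = 30L), "dropping 1")
  expect_true(all(abs(radial_map(surf) - 2) < 0.01))
})
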