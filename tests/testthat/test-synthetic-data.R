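test_that("template geometry stays within plausible hippocampal ranges", {
  tpl <- shape_template()
  tt <- seq(0, 1, length.out = 401)
  r <- template_rho(tpl, rep(tt, each = 60),
                    rep(2 * pi * (0:59) / 60, times = 401))
  expect_true(all(r >= 2 & r <= 8))
  # arc length of the medial curve ~ 40 mm
  ctr <- template_center(tpl, tt)
  arc <- sum(sqrt(rowSums(diff(ctr)^2)))
  expect_gt(arc, 35)
  expect_lt(arc, 50)
})

test_that("subject stacks are deterministic under the seed", {
  tpl <- shape_template(n_slices = 12L)
  s1 <- generate_subject_stack(tpl, "a", sigma = 0.3, seed = 5L,
                               L = 30L, C = 24L)
  s2 <- generate_subject_stack(tpl, "a", sigma = 0.3, seed = 5L,
                               L = 30L, C = 24L)
  expect_identical(s1, s2)
  s3 <- generate_subject_stack(tpl, "a", sigma = 0.3, seed = 6L,
                               L = 30L, C = 24L)
  expect_false(identical(s1$contours[[1]]$points, s3$contours[[1]]$points))
})

test_that("noiseless radial maps recover the analytic profile within 2%", {
  tpl <- shape_template()
  st <- generate_subject_stack(tpl, "a", sigma = 0, seed = 1L,
                               L = 150L, C = 100L)
  surf <- parameterize(st, L = 150L, C = 100L)
  rm_ <- radial_map(surf)
  tt <- (seq_len(150L) - 1L) / 149
  th <- 2 * pi * (seq_len(100L) - 1L) / 100
  rho <- outer(tt, th, function(a, b) template_rho(tpl, a, b))
  expect_lt(max(abs(rm_ - rho) / rho), 0.02)
})

test_that("the deformation is the exact radius ratio at the boundary", {
  # grid aligned with slices (L = n_slices) so patch levels are exact
  tpl <- shape_template(n_slices = 40L)
  patch <- list(levels = c(0.1, 0.3), circ = c(0.1, 0.4))
  st0 <- generate_subject_stack(tpl, "hc", sigma = 0, seed = 1L,
                                L = 40L, C = 50L)
  st1 <- generate_subject_stack(tpl, "als",
                                deformation = list(patch = patch,
                                                   delta = 0.15),
                                sigma = 0, seed = 1L, L = 40L, C = 50L)
  pm <- patch_mask(40L, 50L, patch)
  # boundary-point radii about the arc center: (1 - delta) inside, 1 outside
  for (i in seq_len(40L)) {
    ctr <- template_center(tpl, (i - 1) / 39)
    rad <- function(st) sqrt(rowSums(sweep(st$contours[[i]]$points, 2,
                                           ctr[1:2], "-")^2))
    ratio_i <- rad(st1) / rad(st0)
    expect_equal(ratio_i, ifelse(pm[i, ], 0.85, 1), tolerance = 1e-9)
  }
})

test_that("map-level simulation carries the exact deformation; extracted maps show it attenuated", {
  patch <- list(levels = c(0.1, 0.3), circ = c(0.1, 0.4))
  cfg <- cohort_config(n_patients = 3L, n_controls = 3L, L = 40L, C = 50L,
                       patch = patch, delta = 0.15, sigma = 0,
                       scale_sdlog = 0, seed = 2L,
                       template = shape_template(n_slices = 40L))
  sim <- simulate_radial_maps(cfg)
  pm <- sim$ground_truth$patch_mask
  ratio <- sim$maps[[1]] / sim$maps[[4]]      # patient / control, sigma = 0
  expect_equal(unname(ratio[pm]), rep(0.85, sum(pm)), tolerance = 1e-12)
  expect_equal(unname(ratio[!pm]), rep(1, sum(!pm)), tolerance = 1e-12)

  # through contours -> surface -> medial curve, the measured deficit is
  # attenuated (the centroid shifts with the deformation) but clearly there
  coh <- generate_cohort(cfg)
  r1 <- radial_map(parameterize(coh$stacks[[1]], 40L, 50L))
  r0 <- radial_map(parameterize(coh$stacks[[4]], 40L, 50L))
  ratio <- r1 / r0
  lrows <- which(rowSums(pm) > 0)
  ccols <- which(colSums(pm) > 0)
  inner <- matrix(FALSE, 40L, 50L)
  inner[lrows[3:(length(lrows) - 2L)], ccols[3:(length(ccols) - 2L)]] <- TRUE
  expect_gt(mean(ratio[inner]), 0.85)
  expect_lt(mean(ratio[inner]), 0.95)
  outside <- !pm
  outside[, ccols] <- FALSE
  expect_equal(mean(ratio[outside]), 1.0, tolerance = 0.02)
})

test_that("cohorts reproduce the configured demographic structure", {
  cfg <- cohort_config(L = 40L, C = 30L, sigma = 0.2, seed = 33L,
                       template = shape_template(n_slices = 12L))
  coh <- generate_cohort(cfg)
  tab <- coh$covariates
  expect_identical(nrow(tab), 60L)
  expect_identical(sum(tab$group == "ALS"), 31L)
  expect_identical(sum(tab$group == "HC"), 29L)
  # age moments within sampling error of the configured distributions
  expect_lt(abs(mean(tab$age[tab$group == "ALS"]) - 62.8),
            3 * 13.0 / sqrt(31))
  expect_lt(abs(mean(tab$age[tab$group == "HC"]) - 61.8),
            3 * 5.9 / sqrt(29))
  expect_true(all(is.finite(tab$alsfrs_r[tab$group == "ALS"])))
  expect_true(all(is.na(tab$alsfrs_r[tab$group == "HC"])))
  # TIV tracks scale^3: strong rank correlation with noiseless volume
  expect_gt(cor(tab$tiv, coh$ground_truth$noiseless_volumes,
                method = "spearman"), 0.5)
})

test_that("cohort generation is deterministic and delta = 0 nulls the groups", {
  cfg <- cohort_config(n_patients = 4L, n_controls = 4L, L = 20L, C = 16L,
                       delta = 0, sigma = 0.25, seed = 7L,
                       template = shape_template(n_slices = 10L))
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$stacks, c2$stacks)
  expect_identical(c1$covariates, c2$covariates)
  # delta = 0: patient stacks drawn from the same distribution as controls
  v <- vapply(c1$stacks, stack_volume, numeric(1))
  expect_equal(unname(c1$ground_truth$noiseless_volumes / v),
               rep(1, 8), tolerance = 0.02)
})

test_that("ground-truth volumes equal the planimetric volume at sigma = 0", {
  cfg <- cohort_config(n_patients = 3L, n_controls = 3L, L = 30L, C = 24L,
                       sigma = 0, seed = 13L,
                       template = shape_template(n_slices = 15L))
  coh <- generate_cohort(cfg)
  v <- vapply(coh$stacks, stack_volume, numeric(1))
  expect_equal(unname(coh$ground_truth$noiseless_volumes), unname(v),
               tolerance = 1e-9)
})

test_that("analytic effect summary matches geometry", {
  cfg0 <- cohort_config(delta = 0, seed = 1L)
  expect_equal(true_effect_summary(cfg0)$volume_ratio, 1.0)
  # whole-surface patch of depth 0.1: area ratio (1 - 0.1)^2 = 0.81
  cfg1 <- cohort_config(patch = list(levels = c(0, 1), circ = c(0, 1)),
                        delta = 0.1, seed = 1L)
  expect_equal(true_effect_summary(cfg1)$volume_ratio, 0.81,
               tolerance = 1e-9)
  # partial patch: matches an independent discrete integration of rho^2
  cfg <- cohort_config(seed = 1L)
  want <- noiseless_deformed_ratio(cfg)
  got <- true_effect_summary(cfg)$volume_ratio
  expect_lt(abs(got - want) / want, 0.01)
})

test_that("group volume ratio at sigma = 0 matches the analytic ratio", {
  cfg <- cohort_config(n_patients = 6L, n_controls = 6L, L = 40L, C = 40L,
                       sigma = 0, scale_sdlog = 0, seed = 3L,
                       template = shape_template(n_slices = 20L))
  coh <- generate_cohort(cfg)
  v <- vapply(coh$stacks, stack_volume, numeric(1))
  ratio <- mean(v[coh$covariates$group == "ALS"]) /
    mean(v[coh$covariates$group == "HC"])
  expect_equal(ratio, true_effect_summary(cfg)$volume_ratio,
               tolerance = 0.02)
})

test_that("map-level simulation mirrors the cohort covariate stream", {
  cfg <- cohort_config(n_patients = 5L, n_controls = 5L, L = 20L, C = 16L,
                       sigma = 0.3, seed = 44L,
                       template = shape_template(n_slices = 10L))
  sim <- simulate_radial_maps(cfg)
  coh <- generate_cohort(cfg)
  expect_identical(sim$covariates$id, as.character(coh$covariates$id))
  expect_identical(sim$covariates$tiv, coh$covariates$tiv)
  expect_identical(dim(sim$maps[[1]]), c(20L, 16L))
  # same seed -> identical maps
  sim2 <- simulate_radial_maps(cfg)
  expect_identical(sim$maps, sim2$maps)
})

test_that("configuration errors are caught by name", {
  expect_error(cohort_config(delta = 0.9), "deformation.depth")
  expect_error(cohort_config(n_patients = 2L), "at least 3")
  expect_error(cohort_config(sigma = -1), "nonnegative")
  expect_error(cohort_config(patch = list(levels = c(0.5, 0.2),
                                          circ = c(0, 1))), "increasing")
})
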