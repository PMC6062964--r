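## cli_pipeline: file-based stages (simulate -> extract -> stats -> report)

#' Read a pipeline run configuration
#'
#' JSON (always available) or YAML (if the yaml package is installed),
#' selected by extension. Recognized keys are the arguments of
#' [cohort_config()] (with `template` as a nested list of
#' [shape_template()] arguments) plus the analysis settings used by
#' [run_stats()].
#'
#' @param path config file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Build a cohort configuration from a plain list
#' @param lst named list of [cohort_config()] arguments; `template` may be
#'   a nested list of [shape_template()] arguments.
#' @return a [cohort_config()].
#' @export
config_from_list <- function(lst) {
  known <- names(formals(cohort_config))
  lst <- lst[intersect(names(lst), known)]
  if (!is.null(lst$template) && !inherits(lst$template, "shape_template"))
    lst$template <- do.call(shape_template, as.list(lst$template))
  if (!is.null(lst$patch)) lst$patch <- lapply(lst$patch, as.numeric)
  do.call(cohort_config, lst)
}

stage_meta <- function(out_dir, stage, started, inputs, outputs, extra = list()) {
  meta <- c(list(stage = stage,
                 elapsed_sec = round(as.numeric(Sys.time()) - started, 3),
                 inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
                 outputs = as.list(tools::md5sum(outputs[file.exists(outputs)]))),
            extra)
  jsonlite::write_json(meta, file.path(out_dir, sprintf("%s_meta.json", stage)),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Simulate a cohort directory
#'
#' Writes `contours/<id>.ctr`, `covariates.csv` and `ground_truth.json`
#' (patch, depth, seed, full config echo) under `out_dir`. Reruns with the
#' same configuration produce byte-identical files.
#'
#' @param config a [cohort_config()] (or plain list, see
#'   [config_from_list()]).
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  started <- as.numeric(Sys.time())
  if (!inherits(config, "cohort_config")) config <- config_from_list(config)
  cohort <- generate_cohort(config)
  dir.create(file.path(out_dir, "contours"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- vapply(cohort$stacks, function(s) {
    p <- file.path(out_dir, "contours", paste0(s$subject_id, ".ctr"))
    write_contour_stack(s, p)
    p
  }, character(1))
  cov_path <- file.path(out_dir, "covariates.csv")
  write.csv(cohort$covariates, cov_path, row.names = FALSE)
  gt <- cohort$ground_truth
  echo <- unclass(config)
  echo$template <- unclass(echo$template)
  jsonlite::write_json(
    list(patch = config$patch, delta = gt$delta, seed = gt$seed,
         L = config$L, C = config$C,
         noiseless_volumes = as.list(gt$noiseless_volumes),
         config = echo),
    file.path(out_dir, "ground_truth.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_meta(out_dir, "simulate", started, character(0),
             c(paths, cov_path, file.path(out_dir, "ground_truth.json")),
             list(n_subjects = length(paths), seed = config$seed))
  invisible(out_dir)
}

#' Extract surfaces, radial maps and volumes from a cohort directory
#'
#' Reads every `contours/*.ctr` file, computes the planimetric volume and
#' the L x C radial-distance map of each subject, the cohort-average
#' template surface, and writes `volumes.csv`, `radial/<id>.csv`,
#' `template.obj` / `template.ply`, and an `extract_meta.json` summary.
#' A subject whose contour file fails to read or parameterize is logged
#' and skipped; the run continues.
#'
#' @param cohort_dir directory produced by [run_simulate()] (or laid out
#'   the same way).
#' @param out_dir output directory.
#' @param L,C parametric grid dimensions (default 150 x 100).
#' @return invisibly, a list with `volumes`, `failures`, and output paths.
#' @export
run_extract <- function(cohort_dir, out_dir, L = 150L, C = 100L) {
  started <- as.numeric(Sys.time())
  files <- sort(Sys.glob(file.path(cohort_dir, "contours", "*.ctr")))
  if (!length(files)) stop(sprintf("no contour files under %s", cohort_dir))
  dir.create(file.path(out_dir, "radial"), recursive = TRUE,
             showWarnings = FALSE)
  failures <- character(0)
  ids <- character(0); vols <- numeric(0)
  surfaces <- list()
  for (f in files) {
    res <- tryCatch({
      stack <- read_contour_stack(f)
      surf <- parameterize(stack, L, C)
      map <- radial_map(surf)
      write_radial_map(map, file.path(out_dir, "radial",
                                      paste0(stack$subject_id, ".csv")))
      list(id = stack$subject_id, vol = stack_volume(stack), surf = surf)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("extraction failed for %s: %s", f, conditionMessage(res)))
      failures <- c(failures, basename(f))
      next
    }
    ids <- c(ids, res$id)
    vols <- c(vols, res$vol)
    surfaces[[res$id]] <- res$surf
  }
  if (!length(ids)) stop("extraction failed for every subject")
  volumes <- data.frame(id = ids, volume = vols)
  write.csv(volumes, file.path(out_dir, "volumes.csv"), row.names = FALSE)
  tmpl <- average_surface(surfaces)
  mesh <- surface_to_mesh(tmpl)
  write_obj(mesh, file.path(out_dir, "template.obj"))
  write_ply(mesh, file.path(out_dir, "template.ply"))
  stage_meta(out_dir, "extract", started, files,
             c(file.path(out_dir, "volumes.csv"),
               file.path(out_dir, "template.obj")),
             list(L = L, C = C, n_ok = length(ids), failures = failures))
  invisible(list(volumes = volumes, failures = failures, out_dir = out_dir))
}

#' Run the statistics stage
#'
#' TIV-adjusts the planimetric volumes (slope fitted on controls), tests
#' the group difference in adjusted volume (group + age fixed effects,
#' Bonferroni level 0.025), computes Spearman correlations of adjusted
#' volume with available clinical scores in patients, fits the vertex-wise
#' model `~ group + age + tiv` on the radial maps, and corrects the group
#' effect by whole-surface and head/body/tail permutation max-cluster
#' tests. Subjects missing covariates or a radial map are excluded with a
#' warning.
#'
#' @param extract_dir directory produced by [run_extract()].
#' @param covariates covariate CSV path or a cohort table.
#' @param out_dir output directory.
#' @param cluster_forming_p vertex threshold for cluster forming.
#' @param n_perm permutations for the cluster null.
#' @param seed integer seed for the permutation stream.
#' @param roi_fractions head/body/tail boundary fractions.
#' @param scheme permutation scheme, see [permutation_cluster_test()].
#' @param alpha_level significance level for the volume tests.
#' @param tfce also write the TFCE-enhanced t map.
#' @return invisibly, a list with the fitted objects and tables.
#' @export
run_stats <- function(extract_dir, covariates, out_dir,
                      cluster_forming_p = 0.05, n_perm = 1000L, seed,
                      roi_fractions = c(1, 1, 1) / 3,
                      scheme = "freedman_lane", alpha_level = 0.025,
                      tfce = FALSE) {
  started <- as.numeric(Sys.time())
  if (missing(seed)) stop("an explicit integer seed is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cov <- if (is.character(covariates)) read_cohort_table(covariates)
         else covariates
  volumes <- read.csv(file.path(extract_dir, "volumes.csv"),
                      stringsAsFactors = FALSE)
  map_files <- Sys.glob(file.path(extract_dir, "radial", "*.csv"))
  map_ids <- sub("\\.csv$", "", basename(map_files))

  ids <- Reduce(intersect, list(cov$id, volumes$id, map_ids))
  dropped <- setdiff(union(union(cov$id, volumes$id), map_ids), ids)
  if (length(dropped))
    warning(sprintf("excluding subject(s) without complete data: %s",
                    paste(dropped, collapse = ", ")))
  cov <- cov[match(ids, cov$id), ]
  volumes <- volumes[match(ids, volumes$id), ]
  if (min(table(cov$group)) < 3L)
    stop("fewer than 3 subjects per group after exclusions")
  maps <- lapply(file.path(extract_dir, "radial", paste0(ids, ".csv")),
                 read_radial_map)

  ## volumes: TIV adjustment, group test, clinical correlations
  ctrl <- cov$group == levels(cov$group)[1L]
  adj_model <- fit_tiv_adjustment(volumes$volume[ctrl], cov$tiv[ctrl])
  adjusted <- apply_tiv_adjustment(adj_model, volumes$volume, cov$tiv)
  vol_tab <- data.frame(id = ids, group = cov$group,
                        volume = volumes$volume, adjusted = adjusted)
  write_results(vol_tab, file.path(out_dir, "volumes_adjusted.csv"))
  gt <- group_volume_test(adjusted, cov$group, cov$age, alpha_level)
  write_results(data.frame(test = "adjusted_volume_group", F = gt$F,
                           p = gt$p, df1 = gt$df[1L], df2 = gt$df[2L],
                           significant = gt$significant,
                           alpha = unname(coef(adj_model)["alpha"]),
                           alpha_level = alpha_level),
                file.path(out_dir, "volume_tests.csv"))
  cors <- list()
  pat <- !ctrl
  for (sc in intersect(c("alsfrs_r", "duration_months"), names(cov))) {
    if (sum(is.finite(cov[[sc]][pat])) >= 5L) {
      cc <- clinical_correlation(adjusted[pat], cov[[sc]][pat])
      cors[[sc]] <- data.frame(score = sc, rho = cc$rho, p = cc$p, n = cc$n)
    }
  }
  if (length(cors))
    write_results(do.call(rbind, cors), file.path(out_dir, "correlations.csv"))

  ## vertex-wise shape statistics
  fit <- shape_lm(~ group + age + tiv, cov, maps)
  write.table(fit$t, file.path(out_dir, "t_map.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.table(fit$p, file.path(out_dir, "p_map.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  whole <- permutation_cluster_test(fit, cluster_forming_p, n_perm, seed,
                                    scheme)
  part <- roi_partition(fit$dims[1L], fit$dims[2L], roi_fractions)
  rois <- roi_cluster_test(fit, part, cluster_forming_p = cluster_forming_p,
                           n_perm = n_perm, seed = seed, scheme = scheme)
  clusters <- cluster_table(c(list(whole = whole), rois))
  write_results(clusters, file.path(out_dir, "clusters.csv"))
  if (tfce) {
    write.table(tfce_enhance(fit$t), file.path(out_dir, "tfce_map.csv"),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }

  ## overlay on the template mesh, if present
  tmpl_path <- file.path(extract_dir, "template.obj")
  if (file.exists(tmpl_path)) {
    mesh <- read_obj(tmpl_path)
    if (nrow(mesh$vertices) == prod(fit$dims))
      write_ply(mesh, file.path(out_dir, "template_t.ply"),
                scalars = as.vector(t(fit$t)))
  }

  jsonlite::write_json(
    list(seed = seed, n_perm = n_perm, cluster_forming_p = cluster_forming_p,
         scheme = scheme, roi_fractions = roi_fractions,
         alpha_level = alpha_level, L = fit$dims[1L], C = fit$dims[2L],
         n_subjects = length(ids), excluded = dropped,
         package_version = as.character(utils::packageVersion("hippomorph"))),
    file.path(out_dir, "metadata.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_meta(out_dir, "stats", started,
             file.path(extract_dir, "volumes.csv"),
             file.path(out_dir, c("clusters.csv", "volume_tests.csv")),
             list(seed = seed, n_perm = n_perm))
  invisible(list(fit = fit, whole = whole, rois = rois,
                 volume_test = gt, tiv_model = adj_model,
                 clusters = clusters, out_dir = out_dir))
}

#' Write a Markdown summary report
#'
#' Summarizes a [run_stats()] output directory: volume tests, cluster
#' tables, and flat-map PNG images of the t map and cluster labels.
#'
#' @param stats_dir directory produced by [run_stats()].
#' @param out_file report path (default `report.md` inside `stats_dir`).
#' @return `out_file`, invisibly.
#' @export
run_report <- function(stats_dir, out_file = file.path(stats_dir, "report.md")) {
  tmap <- as.matrix(read.csv(file.path(stats_dir, "t_map.csv"),
                             header = FALSE))
  clusters <- read.csv(file.path(stats_dir, "clusters.csv"),
                       stringsAsFactors = FALSE)
  vols <- read.csv(file.path(stats_dir, "volume_tests.csv"))
  meta <- jsonlite::read_json(file.path(stats_dir, "metadata.json"),
                              simplifyVector = TRUE)
  png_path <- file.path(stats_dir, "t_map.png")
  grDevices::png(png_path, width = 900, height = 600)
  lim <- max(abs(tmap))
  graphics::image(seq_len(nrow(tmap)), seq_len(ncol(tmap)), tmap,
                  col = grDevices::hcl.colors(65, "Blue-Red 3"),
                  zlim = c(-lim, lim),
                  xlab = "longitudinal level (anterior → posterior)",
                  ylab = "circumferential position",
                  main = "group t map (negative = inward in patients)")
  grDevices::dev.off()

  fmt_tab <- function(df) {
    hdr <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    rows <- apply(df, 1L, function(r) paste("|", paste(r, collapse = " | "), "|"))
    c(hdr, sep, rows)
  }
  lines <- c(
    "# Shape morphometry report", "",
    sprintf("Seed %s, %s permutations, cluster-forming p < %s, scheme %s.",
            meta$seed, meta$n_perm, meta$cluster_forming_p, meta$scheme),
    sprintf("Grid %s x %s, %s subjects.", meta$L, meta$C, meta$n_subjects), "",
    "## Adjusted volume test", "", fmt_tab(vols), "",
    "## Clusters (whole surface and head/body/tail)", "",
    if (nrow(clusters)) fmt_tab(clusters) else "No supra-threshold clusters.",
    "", sprintf("![group t map](%s)", basename(png_path)), "")
  writeLines(lines, out_file)
  invisible(out_file)
}
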