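# End-to-end orchestration: synthetic cohort (or supplied meshes) ->
# two-cut parameterization -> grid resampling -> fluid registration to the
# template -> MMS features -> group contrasts, ratio maps, CDF curves,
# volume and demographics tables.  Stages are cached on disk keyed by a
# content hash of their inputs, so re-running an unchanged configuration
# recomputes nothing and rewrites identical bytes.

content_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  # version-pinned serialization so hashes are stable across sessions
  saveRDS(obj, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

cache_get <- function(dir, key) {
  f <- file.path(dir, paste0(key, ".rds"))
  if (file.exists(f)) readRDS(f) else NULL
}

cache_put <- function(dir, key, value) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(value, file.path(dir, paste0(key, ".rds")), version = 2)
  value
}

#' Pipeline configuration
#'
#' Defaults mirror the printed analysis settings: 100 x 150 grid (15,000
#' vertices per side), 10,000 permutations, alpha 0.05, cap fraction 0.02.
#'
#' @param cohort a [cohort_spec()] for synthetic input, or NULL when
#'   `meshes` are supplied.
#' @param meshes optional named list of [hm_mesh()] with a parallel `labels`
#'   vector (alternative to synthetic generation).
#' @param labels group label per supplied mesh.
#' @param grid_nu,grid_nv analysis grid shape.
#' @param cap_fraction end-cap removal fraction for the two cuts.
#' @param n_perm permutations per contrast.
#' @param alpha vertex-level threshold.
#' @param contrasts list of 2-character vectors (group pairs); the default
#'   carriers-vs-NC, HT-vs-NC, HM-vs-NC, HT-vs-HM set is built from the
#'   group labels when NULL.
#' @param registration_params passed to [fluid_register()].
#' @param template_subject index of the reference subject whose grid is the
#'   template, or "template" to use the cohort's generating template.
#' @param seed seed for the permutation stage.
#' @param out_dir output directory (tables, VTK maps, run manifest).
#' @return An `hm_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            meshes = NULL, labels = NULL,
                            grid_nu = 100L, grid_nv = 150L,
                            cap_fraction = 0.02,
                            n_perm = 10000L, alpha = 0.05,
                            contrasts = NULL,
                            registration_params = list(),
                            template_subject = "template",
                            seed = 1L,
                            out_dir = tempfile("hm_run_")) {
  structure(list(cohort = cohort, meshes = meshes, labels = labels,
                 grid_nu = as.integer(grid_nu), grid_nv = as.integer(grid_nv),
                 cap_fraction = cap_fraction, n_perm = as.integer(n_perm),
                 alpha = alpha, contrasts = contrasts,
                 registration_params = registration_params,
                 template_subject = template_subject,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "hm_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; the
#' `cohort` block onto [cohort_spec()].
#'
#' @param path YAML file.
#' @return An `hm_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort)) {
    ca <- y$cohort
    if (!is.null(ca$group_sizes)) ca$group_sizes <- unlist(ca$group_sizes)
    if (!is.null(ca$effect_magnitudes))
      ca$effect_magnitudes <- unlist(ca$effect_magnitudes)
    if (!is.null(ca$patch_center)) ca$patch_center <- unlist(ca$patch_center)
    do.call(cohort_spec, ca)
  } else cohort_spec()
  args <- y[setdiff(names(y), "cohort")]
  do.call(pipeline_config, c(list(cohort = cohort), args))
}

subject_to_grid <- function(mesh, n_u, n_v, cap_fraction,
                            max_fallback_fraction = 0.02) {
  om <- compute_cuts(mesh, cap_fraction = cap_fraction)
  ps <- conformal_parameterize(om)
  grid <- resample_to_grid(ps, n_u, n_v,
                           max_fallback_fraction = max_fallback_fraction)
  grid <- align_grid_gauge(grid)
  grid$id <- mesh$id
  grid
}

#' Run the full morphometry pipeline
#'
#' Executes simulate/load -> cut -> parameterize -> resample -> register ->
#' features -> contrasts with per-stage caching under
#' `file.path(config$out_dir, "cache")`, and writes the statistical outputs
#' (contrast summaries as JSON, volume and demographics tables as CSV, maps
#' as VTK point data) plus a run manifest.
#'
#' @param config an [pipeline_config()].
#' @param verbose log stage timing.
#' @return A results bundle: `grids`, `mms`, `volumes`, `contrasts`
#'   (each with `contrast`, `ratio`, `cdf`), `volume_tests`, `demographics`,
#'   `truth_mask`, `manifest`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "hm_pipeline_config"))
  t0 <- Sys.time()
  cache_dir <- file.path(config$out_dir, "cache")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(name, t_start) {
    if (verbose)
      message(sprintf("[%s] %.1fs", name,
                      as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
  }

  # stage: cohort
  ts <- Sys.time()
  if (is.null(config$meshes)) {
    key <- content_hash(list("cohort", config$cohort))
    cohort <- cache_get(cache_dir, key)
    if (is.null(cohort))
      cohort <- cache_put(cache_dir, key, make_cohort(config$cohort))
    meshes <- cohort$meshes
    labels <- cohort$labels
    template_mesh <- cohort$template
    truth_weight <- cohort$truth_weight
  } else {
    if (is.null(config$labels) || length(config$labels) != length(config$meshes))
      stop("labels must accompany supplied meshes", call. = FALSE)
    meshes <- config$meshes
    labels <- config$labels
    template_mesh <- NULL
    truth_weight <- NULL
    cohort <- NULL
  }
  if (length(unique(labels)) < 2L || any(table(labels) < 2L))
    stop("need >= 2 groups with >= 2 subjects each", call. = FALSE)
  log_stage("cohort", ts)

  # stage: template grid
  ts <- Sys.time()
  tpl_input <- if (identical(config$template_subject, "template")) {
    if (is.null(template_mesh))
      stop("no generating template available; set template_subject to an index",
           call. = FALSE)
    template_mesh
  } else meshes[[config$template_subject]]
  key <- content_hash(list("template", tpl_input, config$grid_nu,
                           config$grid_nv, config$cap_fraction))
  template_grid <- cache_get(cache_dir, key)
  if (is.null(template_grid))
    template_grid <- cache_put(cache_dir, key,
                               subject_to_grid(tpl_input, config$grid_nu,
                                               config$grid_nv,
                                               config$cap_fraction))
  log_stage("template", ts)

  # truth mask on the template grid: nearest template-surface vertex weight
  truth_mask <- NULL
  if (!is.null(truth_weight)) {
    cp <- cpp_closest_points(grid_points(template_grid),
                             template_mesh$vertices, template_mesh$faces)
    fverts <- template_mesh$faces[cp$face, , drop = FALSE]
    wf <- matrix(truth_weight[fverts], ncol = 3)
    truth_mask <- rowMeans(wf) >= 0.5
  }

  # stage: per-subject correspondence + features
  ts <- Sys.time()
  mms <- vector("list", length(meshes))
  grids <- vector("list", length(meshes))
  volumes <- numeric(length(meshes))
  qc <- vector("list", length(meshes))
  for (i in seq_along(meshes)) {
    key <- content_hash(list("subject", meshes[[i]], config$grid_nu,
                             config$grid_nv, config$cap_fraction,
                             config$registration_params, template_grid))
    cached <- cache_get(cache_dir, key)
    if (is.null(cached)) {
      res <- tryCatch({
        grid <- subject_to_grid(meshes[[i]], config$grid_nu, config$grid_nv,
                                config$cap_fraction)
        field <- fluid_register(grid, template_grid,
                                config$registration_params)
        m <- compute_mms(grid, template_grid, field)
        m$id <- meshes[[i]]$id
        list(grid = grid, mms = m,
             volume = mesh_volume(meshes[[i]]),
             qc = list(ic_deviation = field$ic_deviation,
                       n_regrid = field$n_regrid,
                       n_fallback = grid$n_fallback,
                       final_mismatch = tail(field$trace, 1)))
      }, error = function(e) stop("subject ", meshes[[i]]$id,
                                  " failed at correspondence/features: ",
                                  conditionMessage(e), call. = FALSE))
      cached <- cache_put(cache_dir, key, res)
    }
    grids[[i]] <- cached$grid
    mms[[i]] <- cached$mms
    volumes[i] <- cached$volume
    qc[[i]] <- cached$qc
  }
  log_stage("features", ts)

  # stage: contrasts
  ts <- Sys.time()
  contrasts <- config$contrasts
  if (is.null(contrasts)) {
    gr <- unique(labels)
    contrasts <- list()
    if (length(gr) == 3L) {
      # carriers-vs-NC plus pairwise dose contrasts
      contrasts <- list(c(paste(gr[2], gr[3], sep = "+"), gr[1]),
                        c(gr[2], gr[1]), c(gr[3], gr[1]), c(gr[2], gr[3]))
    } else {
      for (a in seq_along(gr)) for (b in seq_len(a - 1L))
        contrasts[[length(contrasts) + 1L]] <- c(gr[b], gr[a])
    }
  }
  members <- function(tag) {
    parts <- strsplit(tag, "+", fixed = TRUE)[[1]]
    which(labels %in% parts)
  }
  contrast_results <- list()
  for (cp in contrasts) {
    ia <- members(cp[1]); ib <- members(cp[2])
    key <- content_hash(list("contrast", cp, lapply(mms[ia], `[[`, "features"),
                             lapply(mms[ib], `[[`, "features"),
                             config$n_perm, config$alpha, config$seed))
    cached <- cache_get(cache_dir, key)
    if (is.null(cached)) {
      ct <- permutation_pmap(mms[ia], mms[ib], n_perm = config$n_perm,
                             alpha = config$alpha, seed = config$seed)
      rm_ <- ratio_map(do.call(rbind, lapply(mms[ia], `[[`, "detj")),
                       do.call(rbind, lapply(mms[ib], `[[`, "detj")),
                       ct$mask)
      cached <- cache_put(cache_dir, key,
                          list(contrast = ct, ratio = rm_,
                               cdf = pvalue_cdf(ct)[[1]]))
    }
    contrast_results[[paste(cp[1], "vs", cp[2])]] <- cached
  }
  log_stage("contrasts", ts)

  # volume tests per contrast
  volume_tests <- lapply(contrasts, function(cp) {
    compare_volumes(volumes[members(cp[1])], volumes[members(cp[2])],
                    n_perm = config$n_perm, seed = config$seed)
  })
  names(volume_tests) <- names(contrast_results)

  # demographics (synthetic covariates matched to the group sizes)
  demo <- NULL
  if (!is.null(cohort)) {
    sizes <- table(factor(labels, levels = unique(labels)))
    dists <- default_demographic_distributions()
    have <- intersect(names(sizes), names(dists$age))
    demo <- if (length(have) == length(sizes))
      make_demographics(setNames(as.integer(sizes), names(sizes)),
                        seed = config$seed)
    else NULL
  }

  manifest <- list(package_version = as.character(utils::packageVersion("hippomorph")),
                   seed = config$seed, n_perm = config$n_perm,
                   alpha = config$alpha,
                   grid = c(config$grid_nu, config$grid_nv),
                   n_subjects = length(meshes),
                   groups = as.list(table(labels)),
                   contrasts = names(contrast_results))

  write_pipeline_outputs(config, labels, volumes, contrast_results,
                         volume_tests, demo, manifest)

  structure(list(grids = grids, mms = mms, volumes = volumes,
                 labels = labels, template_grid = template_grid,
                 contrasts = contrast_results, volume_tests = volume_tests,
                 demographics = demo, truth_mask = truth_mask, qc = qc,
                 manifest = manifest,
                 elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))),
            class = "hm_results")
}

write_pipeline_outputs <- function(config, labels, volumes, contrast_results,
                                   volume_tests, demo, manifest) {
  out <- config$out_dir
  voltab <- data.frame(subject = seq_along(volumes), group = labels,
                       volume_mm3 = volumes)
  write.csv(voltab, file.path(out, "volumes.csv"), row.names = FALSE)
  summ <- lapply(names(contrast_results), function(nm) {
    cr <- contrast_results[[nm]]
    list(contrast = nm, p_feature = cr$contrast$p_feature,
         corrected_p = cr$contrast$corrected_p,
         cdf_deviation = cr$cdf$deviation,
         volume_p = volume_tests[[nm]],
         n_perm = cr$contrast$n_perm, seed = cr$contrast$seed)
  })
  jsonlite::write_json(summ, file.path(out, "contrasts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(contrast_results)) {
    cr <- contrast_results[[nm]]
    cdf <- data.frame(p = cr$cdf$p_sorted, null = cr$cdf$null_quantiles)
    write.csv(cdf, file.path(out, paste0("cdf_", gsub("[^A-Za-z0-9]+", "_", nm),
                                         ".csv")), row.names = FALSE)
  }
  if (!is.null(demo))
    write.csv(demo, file.path(out, "demographics.csv"), row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
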