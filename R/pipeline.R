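# End-to-end orchestration: simulate -> gradients -> project -> icc ->
# decode, with every intermediate artefact written to disk and a JSON run
# manifest recording stages, outputs, checksums and timings.

#' Build a validated pipeline run configuration
#'
#' Defaults mirror the analysis conventions throughout the package: 1%
#' projection threshold, 0.75 alignment threshold with flips about 5.5,
#' 10,000 bootstrap resamples, Levina-Bickel neighbourhood range 8-20.
#'
#' @param out_dir output directory for all artefacts
#' @param n_subjects,n_sessions cohort size
#' @param m_true planted gradients in the synthetic cohort (1-3)
#' @param n_u,n_v seed sheet extent
#' @param n_targets_per_tract target voxels per tract
#' @param depth expected streamlines per seed vertex
#' @param sigma_subject,sigma_session latent perturbation scales
#' @param tau tuning-kernel width (latent units)
#' @param m modes to retain: `"auto"` (Levina-Bickel + common dimension)
#'   or a positive integer
#' @param k_range length-2 neighbourhood range for dimensionality MLE
#' @param frac projection-skeleton threshold fraction
#' @param n_boot bootstrap resamples for all CIs
#' @param profile_transform passed to [similarity_matrix()]
#' @param align_threshold flip threshold for [align_to_reference()]
#' @param n_noise_terms,term_noise_sd term-library composition
#' @param rng_seed master seed; all stage randomness derives from it
#' @return a `run_config` list
#' @export
run_config <- function(out_dir,
                       n_subjects = 6L, n_sessions = 2L,
                       m_true = 2L, n_u = 20L, n_v = 20L,
                       n_targets_per_tract = 50L, depth = 1e4,
                       sigma_subject = 0.10, sigma_session = 0.05,
                       tau = 0.25,
                       m = "auto", k_range = c(8L, 20L), frac = 0.01,
                       n_boot = 10000L,
                       profile_transform = "raw",
                       align_threshold = 0.75,
                       n_noise_terms = 10L, term_noise_sd = 0.2,
                       rng_seed = 1L) {
  if (!(identical(m, "auto") || (is.numeric(m) && m >= 1)))
    stop("m must be 'auto' or a positive integer", call. = FALSE)
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]", call. = FALSE)
  if (align_threshold < -1 || align_threshold > 1)
    stop("align_threshold must be a correlation", call. = FALSE)
  cfg <- list(out_dir = out_dir,
              n_subjects = as.integer(n_subjects),
              n_sessions = as.integer(n_sessions),
              m_true = as.integer(m_true),
              n_u = as.integer(n_u), n_v = as.integer(n_v),
              n_targets_per_tract = as.integer(n_targets_per_tract),
              depth = depth,
              sigma_subject = sigma_subject, sigma_session = sigma_session,
              tau = tau, m = m,
              k_range = as.integer(k_range), frac = frac,
              n_boot = as.integer(n_boot),
              profile_transform = profile_transform,
              align_threshold = align_threshold,
              n_noise_terms = as.integer(n_noise_terms),
              term_noise_sd = term_noise_sd,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys match [run_config()] arguments
#' @param ... overrides applied on top of the file
#' @return a `run_config`
#' @export
load_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  vals <- utils::modifyList(vals, list(...))
  do.call(run_config, vals)
}

#' Save a run configuration as YAML (round-trips through
#' [load_run_config()])
#' @param cfg a `run_config`
#' @param path output YAML file
#' @return invisibly, `path`
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

stage_record <- function(name, outputs, t0) {
  list(stage = name,
       outputs = as.list(outputs),
       checksums = as.list(unname(tools::md5sum(unlist(outputs)))),
       wall_time_s = as.numeric(Sys.time()) - t0)
}

#' Run the full connectopic-mapping pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation, gradient fitting (with
#' dimensionality selection when `m = "auto"`), alignment and group
#' averaging per session, projection images and tract summaries for a
#' representative subject, between-session and between-subject ICC, and
#' decile decoding of the session-1 group maps. Identical config and
#' seed reproduce identical outputs.
#'
#' @param cfg a [run_config()]
#' @return invisibly, the run manifest (also written as
#'   `manifest.json`), with the fitted objects attached as attribute
#'   `"results"`
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(cfg), stages = list())
  res <- list()

  ## stage 1: simulate ------------------------------------------------
  t0 <- as.numeric(Sys.time())
  mesh <- make_seed_mesh(cfg$n_u, cfg$n_v)
  truth <- plant_gradients(mesh, cfg$m_true, rng_seed = cfg$rng_seed)
  spec <- cohort_spec(cfg$n_subjects, cfg$n_sessions, depth = cfg$depth,
                      sigma_subject = cfg$sigma_subject,
                      sigma_session = cfg$sigma_session,
                      tau = cfg$tau, rng_seed = cfg$rng_seed)
  grid_shape <- default_grid_shape(mesh)
  v2v <- vertex_to_voxel_map(mesh, grid_shape)
  mat_dir <- file.path(cfg$out_dir, "matrices")
  dir.create(mat_dir, showWarnings = FALSE)
  cms <- list(); rows <- list()
  for (s in seq_len(cfg$n_subjects)) for (ss in seq_len(cfg$n_sessions)) {
    cm <- simulate_connectivity(truth, cfg$n_targets_per_tract, spec,
                                subject = s, session = ss,
                                grid_shape = grid_shape)
    key <- sprintf("sub-%02d_ses-%d", s, ss)
    write_connectivity_matrix(cm, file.path(mat_dir, key))
    cms[[key]] <- cm
    rows[[key]] <- data.frame(subject = s, session = ss,
                              path = file.path("matrices", key))
  }
  manifest_tsv <- file.path(cfg$out_dir, "cohort.tsv")
  write_tsv(do.call(rbind, rows), manifest_tsv)
  mesh_file <- file.path(cfg$out_dir, "seed.surf.gii")
  write_gifti_surface(mesh, mesh_file)
  truth_file <- file.path(cfg$out_dir, "truth_fields.func.gii")
  write_gifti_metric(truth$latent_fields, truth_file)
  atlas <- make_tract_atlas(cms[[1]])
  atlas_dir <- file.path(cfg$out_dir, "atlas")
  write_tract_atlas(atlas, atlas_dir)
  lib <- simulate_term_library(grid_shape, truth, v2v,
                               n_noise_terms = cfg$n_noise_terms,
                               rng_seed = cfg$rng_seed,
                               noise_sd = cfg$term_noise_sd, atlas = atlas)
  lib_dir <- file.path(cfg$out_dir, "term_library")
  write_term_library(lib, lib_dir)
  manifest$stages$simulate <- stage_record(
    "simulate", c(manifest_tsv, mesh_file, truth_file), t0)
  res$mesh <- mesh; res$truth <- truth; res$spec <- spec
  res$cms <- cms; res$atlas <- atlas; res$lib <- lib; res$v2v <- v2v

  ## stage 2: gradients ------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (identical(cfg$m, "auto")) {
    ests <- vapply(seq_len(cfg$n_subjects), function(s) {
      sim <- similarity_matrix(cms[[sprintf("sub-%02d_ses-1", s)]],
                               transform = cfg$profile_transform)
      estimate_intrinsic_dimension(sim, cfg$k_range[1], cfg$k_range[2])
    }, numeric(1))
    m_used <- common_dimension(ests)
    res$dim_estimates <- ests
  } else {
    m_used <- as.integer(cfg$m)
    res$dim_estimates <- NULL
  }
  res$m_used <- m_used
  maps <- lapply(cms, fit_connectopic_map, m = m_used,
                 transform = cfg$profile_transform)
  maps <- align_cohort(maps, threshold = cfg$align_threshold)
  res$maps <- maps
  map_dir <- file.path(cfg$out_dir, "maps")
  dir.create(map_dir, showWarnings = FALSE)
  map_files <- character(0)
  for (key in names(maps)) {
    f <- file.path(map_dir, paste0(key, "_gradients.func.gii"))
    write_gifti_metric(maps[[key]]$values, f)
    map_files <- c(map_files, f)
  }
  res$group_maps <- lapply(seq_len(cfg$n_sessions), function(ss) {
    group_average(maps[grepl(sprintf("_ses-%d$", ss), names(maps))])
  })
  group_files <- vapply(seq_len(cfg$n_sessions), function(ss) {
    f <- file.path(map_dir, sprintf("group_ses-%d_gradients.func.gii", ss))
    write_gifti_metric(res$group_maps[[ss]]$values, f)
    f
  }, character(1))
  eig_file <- file.path(map_dir, "eigenvalues.tsv")
  write_tsv(data.frame(
    map = names(maps),
    t(vapply(maps, `[[`, numeric(m_used), "eigenvalues"))), eig_file)
  manifest$stages$gradients <- stage_record(
    "gradients", c(map_files, group_files, eig_file), t0)
  manifest$stages$gradients$m_used <- m_used

  ## stage 3: project --------------------------------------------------
  t0 <- as.numeric(Sys.time())
  rep_key <- names(cms)[1]
  skel <- projection_skeleton(cms[[rep_key]], frac = cfg$frac)
  proj_dir <- file.path(cfg$out_dir, "projection")
  dir.create(proj_dir, showWarnings = FALSE)
  proj_files <- character(0)
  tract_imgs_by_mode <- lapply(seq_len(m_used), function(mode) {
    img <- make_projection_image(skel, cms[[rep_key]], maps[[rep_key]], mode)
    f <- file.path(proj_dir, sprintf("%s_g%d_projection.nii", rep_key, mode))
    write_volume(img, f, background = 0)
    proj_files <<- c(proj_files, f)
    tract_projection(img, atlas)
  })
  summ <- tract_summary(tract_imgs_by_mode, n_boot = cfg$n_boot,
                        rng_seed = cfg$rng_seed)
  summ_file <- file.path(proj_dir, "tract_summary.tsv")
  write_tsv(as.data.frame(summ), summ_file)
  res$tract_summary <- summ
  manifest$stages$project <- stage_record(
    "project", c(proj_files, summ_file), t0)

  ## stage 4: icc ------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  icc_rows <- list()
  for (mode in seq_len(m_used)) {
    if (cfg$n_sessions >= 2) {
      r <- between_session_icc(maps, mode = mode, n_boot = cfg$n_boot,
                               rng_seed = cfg$rng_seed)
      icc_rows[[length(icc_rows) + 1L]] <- data.frame(
        comparison = r$comparison, session = NA, mode = mode,
        mean = r$mean, ci_low = r$ci_low, ci_high = r$ci_high)
    }
    for (ss in seq_len(cfg$n_sessions)) {
      r <- between_subject_icc(maps, session = ss, mode = mode,
                               n_boot = cfg$n_boot, rng_seed = cfg$rng_seed)
      icc_rows[[length(icc_rows) + 1L]] <- data.frame(
        comparison = r$comparison, session = ss, mode = mode,
        mean = r$mean, ci_low = r$ci_low, ci_high = r$ci_high)
    }
  }
  icc_table <- do.call(rbind, icc_rows)
  icc_file <- file.path(cfg$out_dir, "icc.tsv")
  write_tsv(icc_table, icc_file)
  res$icc <- icc_table
  manifest$stages$icc <- stage_record("icc", icc_file, t0)

  ## stage 5: decode ---------------------------------------------------
  t0 <- as.numeric(Sys.time())
  dec_files <- character(0)
  res$decoding <- lapply(seq_len(m_used), function(mode) {
    tab <- decoding_table(res$group_maps[[1]], mode, lib, v2v)
    f <- file.path(cfg$out_dir, sprintf("decoding_g%d.tsv", mode))
    df <- data.frame(term = rownames(tab$r), round(tab$r, 6))
    write_tsv(df, f)
    dec_files <<- c(dec_files, f)
    tab
  })
  manifest$stages$decode <- stage_record("decode", dec_files, t0)

  manifest_file <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       digits = NA, null = "null")
  attr(manifest, "results") <- res
  invisible(manifest)
}
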