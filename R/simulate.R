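# Synthetic cohort generator.
#
# The generative model is Poisson-kernel based: each target voxel belongs
# to one "tract" sitting at a centre in latent space, and the expected
# visitation count from seed vertex i to voxel j falls off as a Gaussian
# kernel in the distance between the vertex's latent position g_i and the
# voxel's (jittered) tract centre. This reproduces the two properties the
# analysis pipeline exploits -- connectivity profiles that change smoothly
# along a small number of overlapping latent axes, and target voxels
# clustered into tracts occupying distinct latent regions -- without
# simulating diffusion signal or streamlines.

#' Describe a synthetic cohort
#'
#' @param n_subjects,n_sessions cohort dimensions
#' @param depth expected streamline count per seed vertex (the generator's
#'   analogue of streamlines seeded per vertex; default 10^4)
#' @param sigma_subject,sigma_session standard deviations of the additive
#'   Gaussian perturbations of the latent fields, in latent units. Subject
#'   perturbations are shared across a subject's sessions; session
#'   perturbations are not, so choosing `sigma_session < sigma_subject`
#'   makes between-session maps more alike than between-subject maps.
#' @param tau tuning-kernel width in latent units (> 0)
#' @param rng_seed master seed; all randomness in the cohort derives from it
#' @return a `cohort_spec` object
#' @export
cohort_spec <- function(n_subjects, n_sessions = 2L, depth = 1e4,
                        sigma_subject = 0.10, sigma_session = 0.05,
                        tau = 0.25, rng_seed = 1L) {
  stop_if_not_scalar_int(n_subjects, "n_subjects", min = 1)
  stop_if_not_scalar_int(n_sessions, "n_sessions", min = 1)
  if (!is.numeric(depth) || depth <= 0) stop("depth must be > 0", call. = FALSE)
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (sigma_subject < 0 || sigma_session < 0)
    stop("perturbation scales must be non-negative", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_sessions = as.integer(n_sessions),
         depth = depth,
         sigma_subject = sigma_subject, sigma_session = sigma_session,
         tau = tau, rng_seed = as.integer(rng_seed)),
    class = "cohort_spec")
}

#' Map seed vertices onto the top slice of the synthetic volume grid
#'
#' The sheet's (u, v) grid coordinates become (i, j) voxel indices; all
#' seed vertices live in the top slice `k = grid_shape[3]`, keeping them
#' disjoint from the white-matter target slices below.
#'
#' @param mesh a [make_seed_mesh()] sheet
#' @param grid_shape integer triple; must be at least (n_u, n_v, 2)
#' @return an n_vertices x 3 integer matrix of 1-based voxel indices
#' @export
vertex_to_voxel_map <- function(mesh, grid_shape = default_grid_shape(mesh)) {
  stopifnot(inherits(mesh, "seed_mesh"), length(grid_shape) == 3)
  if (grid_shape[1] < mesh$n_u || grid_shape[2] < mesh$n_v || grid_shape[3] < 2)
    stop("grid too small to host the seed sheet", call. = FALSE)
  cbind(i = mesh$u + 1L, j = mesh$v + 1L,
        k = rep(as.integer(grid_shape[3]), mesh$n_vertices))
}

#' @rdname vertex_to_voxel_map
#' @export
default_grid_shape <- function(mesh) c(mesh$n_u, mesh$n_v, 8L)

# Deterministic target layout: voxel positions, tract assignment and the
# per-voxel latent offsets. Along axis 1 a voxel sits at its tract's
# centre plus jitter delta_j ~ N(0, (tau/2)^2); along every higher axis
# the tract's voxels fan out evenly over the whole [0,1] range (plus a
# small jitter), emulating tracts that project across the full extent of
# the secondary gradients. Derived only from the truth, the per-tract
# count and the cohort master seed, never from subject/session, so every
# matrix in a cohort shares the same targets.
make_target_layout <- function(truth, n_targets_per_tract, spec,
                               grid_shape) {
  stopifnot(inherits(truth, "latent_truth"), inherits(spec, "cohort_spec"))
  stop_if_not_scalar_int(n_targets_per_tract, "n_targets_per_tract", min = 1)
  n_tracts <- length(truth$tract_names)
  if (grid_shape[3] - 1L < n_tracts)
    stop("grid too small: need one target slice per tract below the seed slice",
         call. = FALSE)
  slice_cap <- grid_shape[1] * grid_shape[2]
  if (n_targets_per_tract > slice_cap)
    stop("grid too small for n_targets_per_tract", call. = FALSE)
  m <- truth$m_true
  with_seed(derive_seed(spec$rng_seed, "target-layout", n_targets_per_tract), {
    ijk <- NULL; tract <- character(0); latent_pos <- NULL
    fan <- (seq_len(n_targets_per_tract) - 0.5) / n_targets_per_tract
    for (t in seq_len(n_tracts)) {
      pos <- sort(sample.int(slice_cap, n_targets_per_tract)) - 1L
      ijk_t <- cbind(i = pos %% grid_shape[1] + 1L,
                     j = pos %/% grid_shape[1] + 1L,
                     k = rep(t, n_targets_per_tract))
      ijk <- rbind(ijk, ijk_t)
      tract <- c(tract, rep(truth$tract_names[t], n_targets_per_tract))
      lp <- matrix(0, n_targets_per_tract, m)
      lp[, 1] <- truth$tract_centres[t, 1] +
        stats::rnorm(n_targets_per_tract, sd = spec$tau / 2)
      if (m >= 2)
        for (a in 2:m)
          lp[, a] <- fan + stats::rnorm(n_targets_per_tract,
                                        sd = spec$tau / 8)
      latent_pos <- rbind(latent_pos, lp)
    }
    list(target_ijk = ijk, tract_of_voxel = tract, latent_pos = latent_pos,
         grid_shape = as.integer(grid_shape))
  })
}

#' Simulate one subject/session visitation count matrix
#'
#' Expected counts follow `depth * K_ij / sum_j K_ij` with the Gaussian
#' tuning kernel `K_ij = exp(-||g_i - x_j||^2 / (2 tau^2))`, where `x_j`
#' is voxel j's latent position (its tract centre plus a fixed per-voxel
#' offset; see the layout rules in the package vignette) and `g_i` is
#' vertex i's latent field value coarse-grained to the planted per-axis
#' resolution. Realised counts are Poisson draws. Subject- and
#' session-level effects perturb the latent fields additively before
#' kernel evaluation; the subject perturbation is shared across that
#' subject's sessions. The result is bit-reproducible from
#' `(spec$rng_seed, subject, session)`.
#'
#' @param truth a [plant_gradients()] ground truth
#' @param n_targets_per_tract target voxels per synthetic tract
#' @param spec a [cohort_spec()]
#' @param subject,session positive integer labels
#' @param grid_shape volume grid hosting targets and the seed sheet
#'   (needs `n_u x n_v` in-plane and one slice per tract plus the seed slice)
#' @param mesh the seed mesh the truth was planted on (for grid sizing);
#'   only needed when `grid_shape` is not given explicitly
#' @return a `connectivity_matrix` (see [connectivity_matrix()]) with the
#'   tract assignment of each target voxel attached as `tract_of_voxel`
#' @export
simulate_connectivity <- function(truth, n_targets_per_tract, spec,
                                  subject, session,
                                  grid_shape = NULL, mesh = NULL) {
  stopifnot(inherits(truth, "latent_truth"), inherits(spec, "cohort_spec"))
  stop_if_not_scalar_int(subject, "subject", min = 1)
  stop_if_not_scalar_int(session, "session", min = 1)
  if (is.null(grid_shape)) {
    if (is.null(mesh)) stop("supply grid_shape or mesh", call. = FALSE)
    grid_shape <- default_grid_shape(mesh)
  }
  layout <- make_target_layout(truth, n_targets_per_tract, spec, grid_shape)
  g <- truth$latent_fields
  n <- nrow(g); m <- ncol(g)
  # the connectivity model resolves each gradient at finitely many levels
  for (a in seq_len(m)) g[, a] <- quantize_field(g[, a], truth$axis_levels[a])
  if (spec$sigma_subject > 0) {
    eps <- with_seed(derive_seed(spec$rng_seed, "subject", subject),
                     matrix(stats::rnorm(n * m), ncol = m))
    g <- g + spec$sigma_subject * eps
  }
  if (spec$sigma_session > 0) {
    eps <- with_seed(derive_seed(spec$rng_seed, "session", subject, session),
                     matrix(stats::rnorm(n * m), ncol = m))
    g <- g + spec$sigma_session * eps
  }
  centres <- layout$latent_pos
  # squared distances between vertex latent positions and voxel centres
  d2 <- outer(rowSums(g^2), rowSums(centres^2), "+") - 2 * tcrossprod(g, centres)
  K <- exp(-pmax(d2, 0) / (2 * spec$tau^2))
  mu <- spec$depth * K / rowSums(K)
  counts <- with_seed(derive_seed(spec$rng_seed, "counts", subject, session),
                      matrix(stats::rpois(length(mu), mu), nrow = n))
  connectivity_matrix(
    counts = counts,
    seed_ids = seq_len(n),
    target_ijk = layout$target_ijk,
    grid_shape = layout$grid_shape,
    per_seed_total = spec$depth,
    tract_of_voxel = layout$tract_of_voxel,
    subject = subject, session = session)
}

#' Build the binary tract atlas matching a synthetic connectivity matrix
#'
#' @param cm a `connectivity_matrix` carrying `tract_of_voxel`
#' @return a `tract_atlas`: named list of binary 3-D arrays on the grid
#' @export
make_tract_atlas <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (is.null(cm$tract_of_voxel))
    stop("connectivity matrix has no tract assignment", call. = FALSE)
  tract_atlas(
    masks = lapply(stats::setNames(nm = unique(cm$tract_of_voxel)), function(t) {
      mask <- array(0L, dim = cm$grid_shape)
      mask[cm$target_ijk[cm$tract_of_voxel == t, , drop = FALSE]] <- 1L
      mask
    }),
    grid_shape = cm$grid_shape)
}

#' Simulate a term-map library with planted decile signals
#'
#' For each planted gradient and each decile of its latent field, one
#' "signal" term map is created: the indicator volume of that decile's
#' vertices (optionally Gaussian-smoothed in-plane) plus voxelwise
#' Gaussian noise. Pure-noise maps emulate unrelated studies, and at
#' least one map is flagged anatomical (the seed-sheet footprint, plus
#' one map per tract when an atlas is supplied); anatomical maps are the
#' ones decoding must exclude.
#'
#' @param grid_shape integer triple
#' @param truth a [plant_gradients()] ground truth
#' @param vertex_to_voxel n_vertices x 3 matrix from [vertex_to_voxel_map()]
#' @param n_noise_terms number of pure-noise maps
#' @param rng_seed integer seed
#' @param noise_sd standard deviation of the additive map noise
#' @param atlas optional `tract_atlas`; adds one anatomical map per tract
#' @return a `term_library`: parallel vectors `terms`, `is_anatomical`,
#'   `synonym_group` and a list `maps` of numeric 3-D arrays
#' @export
simulate_term_library <- function(grid_shape, truth, vertex_to_voxel,
                                  n_noise_terms = 10L, rng_seed = 1L,
                                  noise_sd = 0.2, atlas = NULL) {
  stopifnot(inherits(truth, "latent_truth"))
  if (any(vertex_to_voxel < 1L) ||
      any(t(vertex_to_voxel) > grid_shape))
    stop("grid too small: seed vertices map outside the volume", call. = FALSE)
  stop_if_not_scalar_int(n_noise_terms, "n_noise_terms", min = 0)
  nvox <- prod(grid_shape)
  terms <- character(0); maps <- list()
  anat <- logical(0); syn <- character(0)
  with_seed(derive_seed(rng_seed, "term-library"), {
    for (gi in seq_len(truth$m_true)) {
      masks <- decile_partition_values(truth$latent_fields[, gi])
      for (d in 1:10) {
        vol <- mask_to_volume(masks[[d]], vertex_to_voxel, grid_shape)
        map <- array(as.numeric(vol), dim = grid_shape)
        if (noise_sd > 0)
          map <- map + array(stats::rnorm(nvox, sd = noise_sd), dim = grid_shape)
        nm <- sprintf("g%d_decile%02d", gi, d)
        terms <- c(terms, nm); syn <- c(syn, nm); anat <- c(anat, FALSE)
        maps[[length(maps) + 1L]] <- map
      }
    }
    for (t in seq_len(n_noise_terms)) {
      nm <- sprintf("noise%03d", t)
      terms <- c(terms, nm); syn <- c(syn, nm); anat <- c(anat, FALSE)
      maps[[length(maps) + 1L]] <-
        array(stats::rnorm(nvox), dim = grid_shape)
    }
  })
  # anatomical maps: seed footprint, plus tract masks when provided
  foot <- array(0, dim = grid_shape)
  foot[vertex_to_voxel] <- 1
  terms <- c(terms, "anat_seed_region")
  syn <- c(syn, "anat_seed_region"); anat <- c(anat, TRUE)
  maps[[length(maps) + 1L]] <- foot
  if (!is.null(atlas)) {
    for (t in names(atlas$masks)) {
      terms <- c(terms, paste0("anat_", t))
      syn <- c(syn, paste0("anat_", t)); anat <- c(anat, TRUE)
      maps[[length(maps) + 1L]] <- array(as.numeric(atlas$masks[[t]]),
                                         dim = grid_shape)
    }
  }
  names(maps) <- terms
  term_library(terms = terms, maps = maps, is_anatomical = anat,
               synonym_group = syn, grid_shape = as.integer(grid_shape))
}

# decile masks of a raw numeric field (used by the generator before any
# connectopic map exists); shares the rank/remainder rule of
# decile_partition()
decile_partition_values <- function(values) {
  n <- length(values)
  ord <- order(values, seq_len(n))
  base <- n %/% 10L; rem <- n %% 10L
  sizes <- rep(base, 10L) + c(rep(1L, rem), rep(0L, 10L - rem))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(1:10, function(d) {
    mask <- logical(n)
    if (sizes[d] > 0) mask[ord[starts[d]:ends[d]]] <- TRUE
    mask
  })
}
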