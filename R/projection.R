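# White-matter projection images and tract projections: carry surface
# gradient values into the voxels their streamlines traverse.

#' Threshold a connectivity matrix into a projection skeleton
#'
#' A target voxel survives for a seed vertex when at least `frac` of that
#' vertex's streamlines visited it (`counts >= frac * per_seed_total`);
#' the surviving entries are binarised. The default 1% threshold keeps
#' only robustly visited voxels.
#'
#' @param cm a [connectivity_matrix()]
#' @param frac threshold fraction in (0, 1]
#' @return a logical n_seed x n_target matrix (class
#'   `projection_skeleton`, with the threshold attached)
#' @export
projection_skeleton <- function(cm, frac = 0.01) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (!is.numeric(frac) || length(frac) != 1 || frac <= 0 || frac > 1)
    stop("frac must be in (0, 1]", call. = FALSE)
  keep <- cm$counts >= frac * cm$per_seed_total
  empty <- which(rowSums(keep) == 0)
  if (length(empty) > 0)
    message(length(empty), " seed vertex/vertices fall entirely below the ",
            "skeleton threshold (no surviving voxels)")
  structure(keep, class = c("projection_skeleton", "matrix", "array"),
            frac = frac)
}

#' Populate a projection image from a skeleton and a connectopic map
#'
#' Each voxel of the skeleton (any voxel surviving for at least one
#' vertex) receives the count-weighted average gradient value of the top
#' three vertices whose surviving streamline counts to that voxel are
#' highest (ties broken by ascending vertex index; voxels reached by
#' fewer than three vertices use all of them).
#'
#' @param skeleton a [projection_skeleton()]
#' @param cm the matching [connectivity_matrix()]
#' @param map a [connectopic_map()]
#' @param mode which gradient to project
#' @return a `projection_image`: 3-D array on the grid with `NA` outside
#'   the skeleton, plus `mode_index`
#' @export
make_projection_image <- function(skeleton, cm, map, mode = 1L) {
  stopifnot(inherits(cm, "connectivity_matrix"),
            inherits(map, "connectopic_map"))
  stop_if_not_scalar_int(mode, "mode", min = 1)
  if (mode > map$m) stop("mode exceeds number of fitted modes", call. = FALSE)
  if (!all(dim(skeleton) == dim(cm$counts)))
    stop("skeleton and counts are inconsistent", call. = FALSE)
  g <- map$values[, mode]
  img <- array(NA_real_, dim = cm$grid_shape)
  surv <- cm$counts * skeleton       # post-threshold counts
  hit_voxels <- which(colSums(skeleton) > 0)
  for (j in hit_voxels) {
    w <- surv[, j]
    hitters <- which(w > 0)
    top <- hitters[order(-w[hitters], hitters)][seq_len(min(3L, length(hitters)))]
    img[cm$target_ijk[j, 1], cm$target_ijk[j, 2], cm$target_ijk[j, 3]] <-
      sum(w[top] * g[top]) / sum(w[top])
  }
  structure(list(values = img, grid_shape = cm$grid_shape,
                 mode_index = as.integer(mode)),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("projection_image: mode %d, %d populated voxels on grid %s\n",
              x$mode_index, sum(!is.na(x$values)),
              paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

#' Restrict a projection image to each tract of an atlas
#'
#' @param img a [make_projection_image()] result
#' @param atlas a [tract_atlas()] on the same grid
#' @return named list of `projection_image`s, one per tract (voxels
#'   outside the tract mask set to background `NA`)
#' @export
tract_projection <- function(img, atlas) {
  stopifnot(inherits(img, "projection_image"), inherits(atlas, "tract_atlas"))
  if (!all(img$grid_shape == atlas$grid_shape))
    stop("projection image and atlas grids differ", call. = FALSE)
  out <- lapply(stats::setNames(nm = atlas$names), function(t) {
    v <- img$values
    v[atlas$masks[[t]] == 0] <- NA_real_
    if (all(is.na(v)))
      warning("tract '", t, "' has no populated projection voxels")
    structure(list(values = v, grid_shape = img$grid_shape,
                   mode_index = img$mode_index, tract = t),
              class = "projection_image")
  })
  out
}

#' Per-tract means of projection values with bootstrap confidence intervals
#'
#' For each tract and requested mode, the mean projection value over the
#' tract's populated voxels, with a percentile bootstrap (2.5/97.5) of
#' the mean over `n_boot` voxel resamples.
#'
#' @param tract_imgs_by_mode list indexed by mode of [tract_projection()]
#'   outputs (or a single such list for one mode)
#' @param n_boot bootstrap resamples (>= 100)
#' @param rng_seed integer seed for the bootstrap
#' @return a data.frame with columns tract, mode, n_voxels, mean, ci_low,
#'   ci_high (class `tract_summary`)
#' @export
tract_summary <- function(tract_imgs_by_mode, n_boot = 10000L, rng_seed = 1L) {
  stop_if_not_scalar_int(n_boot, "n_boot", min = 100)
  if (inherits(tract_imgs_by_mode[[1]], "projection_image"))
    tract_imgs_by_mode <- list(tract_imgs_by_mode)
  rows <- list()
  for (imgs in tract_imgs_by_mode) {
    for (t in names(imgs)) {
      vals <- imgs[[t]]$values
      vals <- vals[!is.na(vals)]
      mode <- imgs[[t]]$mode_index
      if (length(vals) == 0)
        stop("tract '", t, "' empty for mode ", mode, call. = FALSE)
      mu <- mean(vals)
      ci <- with_seed(derive_seed(rng_seed, "tract-boot", t, mode), {
        boot_means <- vapply(seq_len(n_boot), function(b)
          mean(vals[sample.int(length(vals), replace = TRUE)]), numeric(1))
        stats::quantile(boot_means, c(0.025, 0.975), names = FALSE, type = 7)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        tract = t, mode = mode, n_voxels = length(vals),
        mean = mu, ci_low = ci[1], ci_high = ci[2])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tract_summary", "data.frame")
  out
}
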