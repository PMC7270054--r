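# Validating constructors for the pipeline's data containers.

#' Construct and validate a connectivity matrix
#'
#' The pipeline's sole subject-level input: a seed-vertex x target-voxel
#' matrix of streamline visitation counts, with voxel grid coordinates and
#' the number of streamlines seeded per vertex. Rows with no visits at all
#' are rejected (such a vertex has no connectivity profile to compare).
#'
#' @param counts n_seed x n_target matrix of non-negative integers
#' @param seed_ids integer vertex indices (length n_seed)
#' @param target_ijk n_target x 3 matrix of 1-based voxel grid indices
#' @param grid_shape integer triple
#' @param per_seed_total streamlines seeded per vertex (> 0)
#' @param tract_of_voxel optional per-target tract labels
#' @param subject,session optional labels carried through the pipeline
#' @return a `connectivity_matrix` object
#' @export
connectivity_matrix <- function(counts, seed_ids, target_ijk, grid_shape,
                                per_seed_total, tract_of_voxel = NULL,
                                subject = NA, session = NA) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (length(seed_ids) != nrow(counts))
    stop("seed_ids length does not match counts rows", call. = FALSE)
  if (nrow(target_ijk) != ncol(counts) || ncol(target_ijk) != 3)
    stop("target_ijk must be n_target x 3", call. = FALSE)
  if (!is.null(tract_of_voxel) && length(tract_of_voxel) != ncol(counts))
    stop("tract_of_voxel length does not match counts columns", call. = FALSE)
  if (length(per_seed_total) != 1 || per_seed_total <= 0)
    stop("per_seed_total must be a single positive number", call. = FALSE)
  zero_rows <- which(rowSums(counts) == 0)
  if (length(zero_rows) > 0)
    stop("all-zero seed rows (no visits recorded) at vertex index: ",
         paste(utils::head(zero_rows, 5), collapse = ", "), call. = FALSE)
  structure(
    list(counts = counts,
         seed_ids = as.integer(seed_ids),
         target_ijk = target_ijk,
         grid_shape = as.integer(grid_shape),
         per_seed_total = per_seed_total,
         tract_of_voxel = tract_of_voxel,
         subject = subject, session = session),
    class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf(
    "connectivity_matrix: %d seed vertices x %d target voxels (grid %s), %g streamlines/vertex\n",
    nrow(x$counts), ncol(x$counts),
    paste(x$grid_shape, collapse = "x"), x$per_seed_total))
  invisible(x)
}

#' Construct a tract atlas of named binary voxel masks
#'
#' @param masks named list of binary 3-D arrays sharing one grid
#' @param grid_shape integer triple
#' @return a `tract_atlas` object
#' @export
tract_atlas <- function(masks, grid_shape) {
  if (is.null(names(masks)) || any(names(masks) == ""))
    stop("tract masks must be named", call. = FALSE)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!all(dim(m) == grid_shape))
      stop("mask '", nm, "' does not match grid_shape", call. = FALSE)
    if (!all(m %in% c(0, 1)))
      stop("mask '", nm, "' is not binary", call. = FALSE)
  }
  structure(list(masks = masks, names = names(masks),
                 grid_shape = as.integer(grid_shape)),
            class = "tract_atlas")
}

#' Construct a term-map library
#'
#' @param terms character term labels
#' @param maps named list of numeric 3-D voxel arrays on a shared grid
#' @param is_anatomical logical flag per term (anatomical terms are
#'   excluded from decoding)
#' @param synonym_group equivalence-class label per term; decoding keeps at
#'   most one member per group
#' @param grid_shape integer triple
#' @return a `term_library` object
#' @export
term_library <- function(terms, maps, is_anatomical,
                         synonym_group = terms, grid_shape) {
  n <- length(terms)
  if (length(maps) != n || length(is_anatomical) != n ||
      length(synonym_group) != n)
    stop("terms, maps, is_anatomical, synonym_group must be parallel",
         call. = FALSE)
  for (i in seq_len(n))
    if (!all(dim(maps[[i]]) == grid_shape))
      stop("term map '", terms[i], "' does not match grid_shape", call. = FALSE)
  structure(list(terms = terms, maps = maps,
                 is_anatomical = as.logical(is_anatomical),
                 synonym_group = as.character(synonym_group),
                 grid_shape = as.integer(grid_shape)),
            class = "term_library")
}

#' @export
print.term_library <- function(x, ...) {
  cat(sprintf("term_library: %d terms (%d anatomical) on grid %s\n",
              length(x$terms), sum(x$is_anatomical),
              paste(x$grid_shape, collapse = "x")))
  invisible(x)
}
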