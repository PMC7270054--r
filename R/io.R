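# File formats: MatrixMarket + JSON sidecar for connectivity matrices,
# NIfTI for volumes, TSV for tables and manifests.

#' Write a connectivity matrix as MatrixMarket plus a JSON sidecar
#'
#' The counts go to `<path>.mtx` (sparse MatrixMarket) and the metadata
#' (seed vertex IDs, target voxel ijk coordinates, grid shape, streamline
#' depth, optional tract labels) to `<path>.json`.
#'
#' @param cm a [connectivity_matrix()]
#' @param path output path without extension
#' @return invisibly, the two file paths
#' @export
write_connectivity_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  mtx <- paste0(path, ".mtx")
  json <- paste0(path, ".json")
  Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), mtx)
  jsonlite::write_json(
    list(seed_ids = cm$seed_ids,
         target_ijk = unname(as.matrix(cm$target_ijk)),
         grid_shape = cm$grid_shape,
         per_seed_total = cm$per_seed_total,
         tract_of_voxel = cm$tract_of_voxel,
         subject = cm$subject, session = cm$session),
    json, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(mtx = mtx, json = json))
}

#' Read a connectivity matrix written by [write_connectivity_matrix()]
#'
#' @param path path without extension (expects `.mtx` and `.json`)
#' @return a validated [connectivity_matrix()]
#' @export
read_connectivity_matrix <- function(path) {
  counts <- as.matrix(Matrix::readMM(paste0(path, ".mtx")))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  connectivity_matrix(
    counts = counts,
    seed_ids = meta$seed_ids,
    target_ijk = matrix(as.integer(meta$target_ijk), ncol = 3),
    grid_shape = meta$grid_shape,
    per_seed_total = meta$per_seed_total,
    tract_of_voxel = meta$tract_of_voxel,
    subject = if (is.null(meta$subject)) NA else meta$subject,
    session = if (is.null(meta$session)) NA else meta$session)
}

#' Write a voxel volume as NIfTI
#'
#' Background `NA`s are written as 0; pass `background` to use another
#' sentinel.
#'
#' @param vol a numeric 3-D array, or a `projection_image`
#' @param path output file (`.nii` suffix recommended; uncompressed)
#' @param background value replacing `NA`
#' @return invisibly, `path`
#' @export
write_volume <- function(vol, path, background = 0) {
  if (inherits(vol, "projection_image")) vol <- vol$values
  vol[is.na(vol)] <- background
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file
#' @return numeric array
#' @export
read_volume <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim = dim(v))
}

#' Write/read a term-map library as a directory of NIfTI maps + terms.tsv
#'
#' `terms.tsv` has columns `term`, `path`, `is_anatomical`,
#' `synonym_group`; each map is one NIfTI volume.
#'
#' @param lib a [term_library()]
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest path
#' @export
write_term_library <- function(lib, dir) {
  stopifnot(inherits(lib, "term_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(lib$terms, ".nii"))
  for (i in seq_along(lib$terms))
    write_volume(lib$maps[[i]], paths[i])
  manifest <- data.frame(term = lib$terms, path = basename(paths),
                         is_anatomical = lib$is_anatomical,
                         synonym_group = lib$synonym_group)
  write_tsv(manifest, file.path(dir, "terms.tsv"))
  invisible(file.path(dir, "terms.tsv"))
}

#' @rdname write_term_library
#' @export
read_term_library <- function(dir) {
  manifest <- read_tsv(file.path(dir, "terms.tsv"))
  maps <- lapply(file.path(dir, manifest$path), read_volume)
  names(maps) <- manifest$term
  term_library(terms = manifest$term, maps = maps,
               is_anatomical = as.logical(manifest$is_anatomical),
               synonym_group = as.character(manifest$synonym_group),
               grid_shape = dim(maps[[1]]))
}

#' Write/read a tract atlas as a directory of binary NIfTI masks
#'
#' @param atlas a [tract_atlas()]
#' @param dir output directory
#' @return invisibly, `dir`
#' @export
write_tract_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "tract_atlas"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in atlas$names)
    write_volume(atlas$masks[[t]], file.path(dir, paste0(t, ".nii")))
  invisible(dir)
}

#' @rdname write_tract_atlas
#' @export
read_tract_atlas <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.nii$", full.names = TRUE))
  if (length(files) == 0) stop("no .nii masks in ", dir, call. = FALSE)
  masks <- lapply(files, function(f) {
    v <- read_volume(f)
    array(as.integer(v != 0), dim = dim(v))
  })
  names(masks) <- sub("\\.nii$", "", basename(files))
  tract_atlas(masks, dim(masks[[1]]))
}

# plain TSV helpers used for all tabular artefacts
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
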