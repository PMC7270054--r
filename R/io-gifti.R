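# Minimal GIFTI surface I/O (ASCII encoding).
#
# GIFTI is the standard XML container for surface meshes and per-vertex
# scalar maps. Only the subset this package writes is supported on read:
# ASCII-encoded DataArrays with intents NIFTI_INTENT_POINTSET,
# NIFTI_INTENT_TRIANGLE and NIFTI_INTENT_NONE (functional scalars).

gifti_data_array <- function(intent, datatype, data, dims) {
  fmt <- if (datatype == "NIFTI_TYPE_INT32") "%d" else "%.10g"
  body <- paste(apply(data, 1L, function(row)
    paste(sprintf(fmt, row), collapse = " ")), collapse = "\n")
  dim_attrs <- paste(sprintf('Dim%d="%d"', seq_along(dims) - 1L, dims),
                     collapse = " ")
  sprintf(paste0(
    '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" ',
    'Dimensionality="%d" %s Encoding="ASCII" Endian="LittleEndian" ',
    'ExternalFileName="" ExternalFileOffset="">\n',
    '<Data>%s</Data>\n</DataArray>'),
    intent, datatype, length(dims), dim_attrs, body)
}

gifti_document <- function(arrays) {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         sprintf('<GIFTI Version="1.0" NumberOfDataArrays="%d">\n',
                 length(arrays)),
         paste(arrays, collapse = "\n"), "\n</GIFTI>\n")
}

#' Write a seed mesh as a GIFTI surface file
#'
#' @param mesh a [make_seed_mesh()] mesh
#' @param path output file (`.surf.gii` suffix by convention)
#' @return invisibly, `path`
#' @export
write_gifti_surface <- function(mesh, path) {
  stopifnot(inherits(mesh, "seed_mesh"))
  arrays <- c(
    gifti_data_array("NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                     mesh$vertex_coords, dim(mesh$vertex_coords)),
    gifti_data_array("NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                     mesh$triangles - 1L, dim(mesh$triangles)))
  writeLines(gifti_document(arrays), path)
  invisible(path)
}

#' Write per-vertex scalar maps as a GIFTI functional file
#'
#' Each column of `values` becomes one DataArray (one map per gradient
#' mode).
#'
#' @param values numeric vector or n_vertices x m matrix
#' @param path output file (`.func.gii` suffix by convention)
#' @return invisibly, `path`
#' @export
write_gifti_metric <- function(values, path) {
  values <- as.matrix(values)
  arrays <- vapply(seq_len(ncol(values)), function(j)
    gifti_data_array("NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32",
                     values[, j, drop = FALSE], nrow(values)),
    character(1))
  writeLines(gifti_document(arrays), path)
  invisible(path)
}

#' Read a GIFTI file written by this package
#'
#' @param path a `.gii` file with ASCII-encoded data arrays
#' @return for a surface file, a list with `vertex_coords` and
#'   `triangles` (1-based); for a functional file, a numeric matrix with
#'   one column per map
#' @export
read_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  parsed <- lapply(arrays, function(a) {
    if (xml2::xml_attr(a, "Encoding") != "ASCII")
      stop("only ASCII-encoded GIFTI data arrays are supported", call. = FALSE)
    dims <- as.integer(vapply(seq_len(
      as.integer(xml2::xml_attr(a, "Dimensionality"))) - 1L,
      function(d) xml2::xml_attr(a, paste0("Dim", d)), character(1)))
    vals <- scan(text = xml2::xml_text(xml2::xml_find_first(a, ".//Data")),
                 quiet = TRUE)
    if (length(dims) == 1) dims <- c(dims, 1L)
    list(intent = xml2::xml_attr(a, "Intent"),
         data = matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE))
  })
  intents <- vapply(parsed, `[[`, character(1), "intent")
  if ("NIFTI_INTENT_POINTSET" %in% intents) {
    list(vertex_coords = parsed[[which(intents == "NIFTI_INTENT_POINTSET")]]$data,
         triangles = parsed[[which(intents == "NIFTI_INTENT_TRIANGLE")]]$data + 1L)
  } else {
    do.call(cbind, lapply(parsed, `[[`, "data"))
  }
}
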