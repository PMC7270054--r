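# Decile-based functional decoding: split a group gradient into ten
# equal-population vertex bins and rank term maps by spatial Pearson
# correlation with each binarised decile volume.

#' Partition a connectopic map mode into ten rank deciles
#'
#' Vertices are ranked by gradient value (ties broken by ascending vertex
#' index) and split into 10 contiguous rank bins of size `n %/% 10`, the
#' remainder going one-each to the lowest bins. The masks partition all
#' vertices and their sizes differ by at most one. Because only ranks are
#' used, the partition is invariant to strictly monotone transforms of
#' the gradient.
#'
#' @param map a [connectopic_map()] (or a plain numeric vector)
#' @param mode which gradient mode to partition
#' @return list of 10 logical vertex masks, lowest decile first
#' @export
decile_partition <- function(map, mode = 1L) {
  values <- if (inherits(map, "connectopic_map")) map$values[, mode] else map
  n <- length(values)
  if (n < 10) stop("need at least 10 vertices for deciles", call. = FALSE)
  if (length(unique(values)) == 1)
    stop("constant map cannot be partitioned", call. = FALSE)
  decile_partition_values(values)
}

#' Rasterise a vertex mask into a binary voxel volume
#'
#' @param mask logical vertex mask
#' @param vertex_to_voxel n_vertices x 3 matrix of 1-based voxel indices
#' @param grid_shape integer triple
#' @return a binary 3-D array; a voxel is 1 iff at least one masked
#'   vertex maps to it
#' @export
mask_to_volume <- function(mask, vertex_to_voxel, grid_shape) {
  if (length(mask) != nrow(vertex_to_voxel))
    stop("mask and vertex_to_voxel are inconsistent", call. = FALSE)
  if (any(vertex_to_voxel < 1L) || any(t(vertex_to_voxel) > grid_shape))
    stop("vertex mapped outside the grid", call. = FALSE)
  vol <- array(0L, dim = grid_shape)
  vol[vertex_to_voxel[mask, , drop = FALSE]] <- 1L
  vol
}

#' Decode one binarised decile volume against a term-map library
#'
#' Computes the Pearson correlation between the binary decile vector and
#' every term map over the analysis-mask voxels, then applies the
#' decoding filters: anatomical terms are dropped, each synonym group
#' contributes only its highest-correlating member, only positive
#' correlations are kept, and the top three terms are returned in
#' descending order.
#'
#' @param vol_mask binary decile volume from [mask_to_volume()]
#' @param lib a [term_library()]
#' @param analysis_mask optional binary volume restricting the
#'   correlation domain (default: the whole grid)
#' @param top_n how many terms to return
#' @return data.frame with columns `term`, `r`, at most `top_n` rows
#' @export
decode_decile <- function(vol_mask, lib, analysis_mask = NULL, top_n = 3L) {
  stopifnot(inherits(lib, "term_library"))
  if (!all(dim(vol_mask) == lib$grid_shape))
    stop("decile volume and library grids differ", call. = FALSE)
  if (is.null(analysis_mask)) {
    keep <- rep(TRUE, prod(lib$grid_shape))
  } else {
    if (!all(dim(analysis_mask) == lib$grid_shape))
      stop("analysis mask and library grids differ", call. = FALSE)
    keep <- as.logical(analysis_mask != 0)
    if (!any(keep)) stop("analysis mask is empty", call. = FALSE)
  }
  x <- as.numeric(vol_mask)[keep]
  if (stats::sd(x) == 0)
    stop("decile volume constant over the analysis mask", call. = FALSE)
  r <- vapply(seq_along(lib$terms), function(i) {
    y <- as.numeric(lib$maps[[i]])[keep]
    if (stats::sd(y) == 0) {
      warning("term '", lib$terms[i], "' constant over the analysis mask; skipped")
      return(NA_real_)
    }
    stats::cor(x, y)
  }, numeric(1))
  cand <- data.frame(term = lib$terms, r = r,
                     synonym_group = lib$synonym_group,
                     stringsAsFactors = FALSE)
  cand <- cand[!lib$is_anatomical & !is.na(cand$r), , drop = FALSE]
  # keep the best member of each synonym group
  cand <- cand[order(-cand$r, cand$term), , drop = FALSE]
  cand <- cand[!duplicated(cand$synonym_group), , drop = FALSE]
  cand <- cand[cand$r > 0, , drop = FALSE]
  utils::head(cand[, c("term", "r")], top_n)
}

#' Assemble the full decile-by-term decoding table for one gradient mode
#'
#' Runs [decode_decile()] on all ten deciles; the table's rows are the
#' union of per-decile top terms, its entries the positive correlations
#' (absent, `NA`, where a term's correlation with a decile is not
#' positive).
#'
#' @param group_map the group [connectopic_map()]
#' @param mode gradient mode
#' @param lib a [term_library()]
#' @param vertex_to_voxel vertex-to-voxel index map
#' @param analysis_mask optional binary correlation-domain volume
#' @param top_n per-decile top terms retained
#' @return a `decoding_table`: matrix `r` (terms x 10, positive entries
#'   or NA), list `top3` per decile, `mode`
#' @export
decoding_table <- function(group_map, mode, lib, vertex_to_voxel,
                           analysis_mask = NULL, top_n = 3L) {
  masks <- decile_partition(group_map, mode)
  tops <- vector("list", 10L)
  all_r <- vector("list", 10L)
  for (d in 1:10) {
    vol <- mask_to_volume(masks[[d]], vertex_to_voxel,
                          lib$grid_shape)
    tops[[d]] <- decode_decile(vol, lib, analysis_mask, top_n = top_n)
    # full correlation vector for table assembly (same filters re-applied)
    all_r[[d]] <- suppressWarnings(
      decode_decile(vol, lib, analysis_mask, top_n = length(lib$terms)))
  }
  terms <- unique(unlist(lapply(tops, `[[`, "term")))
  r_mat <- matrix(NA_real_, nrow = length(terms), ncol = 10,
                  dimnames = list(terms, paste0("decile", 1:10)))
  for (d in 1:10) {
    rd <- all_r[[d]]
    hit <- intersect(terms, rd$term)
    r_mat[hit, d] <- rd$r[match(hit, rd$term)]
  }
  structure(list(r = r_mat, top3 = tops, mode = as.integer(mode)),
            class = "decoding_table")
}

#' @export
print.decoding_table <- function(x, ...) {
  cat(sprintf("decoding_table: mode g%d, %d retained terms x 10 deciles\n",
              x$mode, nrow(x$r)))
  for (d in 1:10) {
    t3 <- x$top3[[d]]
    cat(sprintf("  decile %2d: %s\n", d,
                if (nrow(t3) == 0) "(no positive terms)"
                else paste(sprintf("%s (r=%.2f)", t3$term, t3$r),
                           collapse = ", ")))
  }
  invisible(x)
}
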