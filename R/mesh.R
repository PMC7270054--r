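# Synthetic seed surface and planted latent gradients.
#
# The generator works on a regular triangulated rectangular sheet rather
# than a folded cortical surface: the sheet's two coordinates give latent
# fields whose orthogonality is exact by construction, which makes planted
# ground truth trivially verifiable downstream.

#' Default tract names used by the synthetic cohort
#'
#' The six association tracts the temporal-lobe connectivity literature
#' works with: inferior longitudinal fasciculus, arcuate fasciculus,
#' acoustic radiation, inferior fronto-occipital fasciculus, middle
#' longitudinal fasciculus and uncinate fasciculus.
#' @export
DEFAULT_TRACTS <- c("ILF", "AF", "AR", "IFOF", "MdLF", "UF")

#' Build a regular triangulated sheet to act as the seed surface
#'
#' Vertices sit on an `n_u` x `n_v` grid with 1 mm spacing in the x-y
#' plane; each grid quad is split into two triangles, so the sheet has
#' `2 * (n_u - 1) * (n_v - 1)` triangles and is a single connected
#' component.
#'
#' @param n_u,n_v grid extent in the two sheet directions (each >= 2)
#' @return an object of class `seed_mesh` with elements `vertex_coords`
#'   (n x 3 matrix, mm), `triangles` (t x 3 integer matrix, 1-based),
#'   `n_vertices`, and the generating grid coordinates `u`, `v`
#'   (0-based integers, one per vertex).
#' @export
make_seed_mesh <- function(n_u, n_v) {
  stop_if_not_scalar_int(n_u, "n_u", min = 2)
  stop_if_not_scalar_int(n_v, "n_v", min = 2)
  if (n_u * n_v < 4) stop("mesh needs at least 4 vertices", call. = FALSE)
  # vertex (i, j), 0-based, at linear index i + j * n_u + 1 (u fastest)
  u <- rep(seq_len(n_u) - 1L, times = n_v)
  v <- rep(seq_len(n_v) - 1L, each = n_u)
  coords <- cbind(x = as.numeric(u), y = as.numeric(v), z = 0)
  idx <- function(i, j) i + j * n_u + 1L
  tri <- vector("list", 2L * (n_u - 1L) * (n_v - 1L))
  t <- 0L
  for (j in 0:(n_v - 2L)) {
    for (i in 0:(n_u - 2L)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
      tri[[t <- t + 1L]] <- c(a, b, d)
      tri[[t <- t + 1L]] <- c(a, d, c)
    }
  }
  structure(
    list(vertex_coords = coords,
         triangles = do.call(rbind, tri),
         n_vertices = n_u * n_v,
         n_u = as.integer(n_u), n_v = as.integer(n_v),
         u = u, v = v),
    class = "seed_mesh")
}

#' @export
print.seed_mesh <- function(x, ...) {
  cat(sprintf("seed_mesh: %d vertices (%d x %d sheet), %d triangles\n",
              x$n_vertices, x$n_u, x$n_v, nrow(x$triangles)))
  invisible(x)
}

#' Plant smooth, quasi-orthogonal latent gradients on a seed mesh
#'
#' The latent fields are the ground truth the embedding pipeline is meant
#' to recover: field 1 is the normalised u-coordinate, field 2 the
#' normalised v-coordinate, field 3 the radial distance from the (0,0)
#' corner orthogonalised against the first two (the raw radial field is
#' strongly collinear with u + v, so its projection onto the earlier
#' fields is removed before rescaling). Each field is rescaled to [0,1]
#' and pairwise centred cosines stay below 0.05.
#'
#' Tract centres are laid out deterministically along the first latent
#' axis (tracts are ordered along the dominant gradient, the structure
#' the tract-projection analysis recovers); along higher axes every
#' tract fans out across the full range.
#'
#' Each planted gradient also carries a finite spatial resolution
#' (`axis_levels`: 16, 11 and 9 resolvable levels for axes 1-3): the
#' connectivity model sees the latent fields coarse-grained to that many
#' levels. Decreasing resolution makes the first mode dominant and
#' orders the eigenvalue spectrum strictly, emulating the falling
#' variance explained of successive connectivity modes.
#'
#' @param mesh a [make_seed_mesh()] sheet
#' @param m_true number of planted gradients (1 to 3)
#' @param rng_seed integer seed (reserved for future stochastic layouts;
#'   the default fields and centres are deterministic)
#' @param tract_names names for the synthetic tracts
#' @return an object of class `latent_truth`: `m_true`, `latent_fields`
#'   (n_vertices x m_true, each column in [0,1]), `tract_centres`
#'   (n_tracts x m_true), `tract_names`, `axis_levels`, and `rng_seed`.
#' @export
plant_gradients <- function(mesh, m_true, rng_seed = 1L,
                            tract_names = DEFAULT_TRACTS) {
  stopifnot(inherits(mesh, "seed_mesh"))
  stop_if_not_scalar_int(m_true, "m_true", min = 1)
  if (m_true > 3)
    stop("m_true > 3 is not supported: a rectangular sheet carries at most ",
         "3 quasi-orthogonal smooth fields", call. = FALSE)
  u <- as.numeric(mesh$u); v <- as.numeric(mesh$v)
  f1 <- rescale01(u)
  fields <- matrix(f1, ncol = 1)
  if (m_true >= 2) fields <- cbind(fields, rescale01(v))
  if (m_true >= 3) {
    r <- sqrt(u^2 + v^2)
    # remove the components of r lying along the centred earlier fields
    rc <- r - mean(r)
    for (j in 1:2) {
      fc <- fields[, j] - mean(fields[, j])
      rc <- rc - sum(rc * fc) / sum(fc * fc) * fc
    }
    fields <- cbind(fields, rescale01(rc))
  }
  colnames(fields) <- paste0("field", seq_len(m_true))

  centres <- tract_centre_layout(length(tract_names), m_true)
  rownames(centres) <- tract_names

  structure(
    list(m_true = as.integer(m_true),
         latent_fields = fields,
         tract_centres = centres,
         tract_names = tract_names,
         axis_levels = c(16L, 11L, 9L)[seq_len(m_true)],
         rng_seed = as.integer(rng_seed)),
    class = "latent_truth")
}

# Deterministic tract-centre positions: tracts are spread along latent
# axis 1 (so their ordering along the dominant gradient is a testable
# ground truth) and sit at mid-range on every higher axis, across which
# their target voxels fan out (see make_target_layout).
tract_centre_layout <- function(n_tracts, m_true) {
  centres <- matrix(seq(0.05, 0.95, length.out = n_tracts), ncol = 1)
  if (m_true >= 2)
    centres <- cbind(centres,
                     matrix(0.5, nrow = n_tracts, ncol = m_true - 1L))
  colnames(centres) <- paste0("axis", seq_len(m_true))
  centres
}

# coarse-grain a [0,1] field to m resolvable levels (bin midpoints)
quantize_field <- function(x, m) {
  (pmin(floor(x * m), m - 1L) + 0.5) / m
}

#' @export
print.latent_truth <- function(x, ...) {
  cat(sprintf("latent_truth: %d planted gradient(s), %d tracts (%s)\n",
              x$m_true, length(x$tract_names),
              paste(x$tract_names, collapse = ", ")))
  invisible(x)
}
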