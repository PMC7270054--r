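# Maximum-likelihood intrinsic dimensionality (nearest-neighbour
# distance-ratio estimator) and the cross-subject common dimension.

#' Levina-Bickel maximum-likelihood intrinsic dimensionality
#'
#' For each point x, with `T_j(x)` the Euclidean distance to its j-th
#' nearest neighbour, the local estimate at neighbourhood size k is
#' `m_k(x) = [ (1/(k-1)) * sum_{j=1}^{k-1} ln(T_k(x)/T_j(x)) ]^-1`.
#' Local estimates are averaged over points, and those per-k averages
#' over `k = k_min..k_max`. The estimate depends only on distance ratios,
#' so it is scale-invariant.
#'
#' Duplicate points produce zero distances; the affected log terms are
#' skipped with a warning, and fully duplicated input is rejected.
#'
#' @param x a points-by-features numeric matrix (rows are observations;
#'   a [similarity_matrix()] may be passed directly, its rows being the
#'   points), or a `dist` object
#' @param k_min,k_max neighbourhood range, `2 <= k_min <= k_max < n`
#' @return a positive scalar estimate
#' @export
estimate_intrinsic_dimension <- function(x, k_min = 8L, k_max = 20L) {
  D <- if (inherits(x, "dist")) as.matrix(x) else as.matrix(stats::dist(x))
  n <- nrow(D)
  stop_if_not_scalar_int(k_min, "k_min", min = 2)
  stop_if_not_scalar_int(k_max, "k_max", min = k_min)
  if (k_max >= n) stop("k_max must be < number of points", call. = FALSE)
  # sorted neighbour distances per point, self excluded
  Tmat <- apply(D, 1L, function(row) sort(row)[-1])  # (n-1) x n, column = point
  if (all(Tmat[seq_len(k_max), ] == 0))
    stop("all points duplicated; intrinsic dimension undefined", call. = FALSE)
  skipped <- FALSE
  per_k <- vapply(k_min:k_max, function(k) {
    Tk <- Tmat[k, ]
    local <- vapply(seq_len(n), function(i) {
      Tj <- Tmat[seq_len(k - 1L), i]
      ok <- Tj > 0 & Tk[i] > 0
      if (!any(ok)) return(NA_real_)
      if (!all(ok)) skipped <<- TRUE
      s <- mean(log(Tk[i] / Tj[ok]))
      if (s <= 0) return(NA_real_)   # all k nearest neighbours coincident
      1 / s
    }, numeric(1))
    mean(local, na.rm = TRUE)
  }, numeric(1))
  if (skipped)
    warning("zero nearest-neighbour distances (duplicate points); ",
            "affected log terms skipped")
  est <- mean(per_k)
  if (!is.finite(est) || est <= 0)
    stop("intrinsic dimension estimate degenerate ",
         "(too many duplicate points)", call. = FALSE)
  est
}

#' Common dimensionality across subjects
#'
#' The number of modes every subject's data supports: the floor of the
#' minimum per-subject estimate, clipped below at 1.
#'
#' @param estimates non-empty numeric vector of per-subject estimates
#' @return a positive integer
#' @export
common_dimension <- function(estimates) {
  if (length(estimates) == 0) stop("empty estimate list", call. = FALSE)
  if (any(!is.finite(estimates) | estimates <= 0))
    stop("estimates must be positive finite reals", call. = FALSE)
  max(1L, as.integer(floor(min(estimates))))
}
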