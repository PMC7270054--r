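# Laplacian eigenmaps and connectopic maps.

#' Laplacian eigenmaps of a similarity graph
#'
#' Solves the generalised eigenproblem `L v = lambda D v` and returns the
#' `m` eigenvectors of smallest non-zero eigenvalue; the trivial constant
#' eigenvector (eigenvalue 0 on a connected graph) is discarded. The
#' problem is reduced to an ordinary symmetric one via
#' `D^{-1/2} L D^{-1/2}`, so the returned vectors are D-orthonormal.
#' Each vector's sign is fixed so its largest-magnitude entry is positive,
#' making the output deterministic.
#'
#' @param L,D Laplacian and degree matrices from [graph_laplacian()]
#' @param m number of non-trivial eigenvectors to retain (`1 <= m <= n-1`)
#' @return list with `vectors` (n x m), `eigenvalues` (length m,
#'   ascending, positive)
#' @export
laplacian_eigenmaps <- function(L, D, m) {
  n <- nrow(L)
  stop_if_not_scalar_int(m, "m", min = 1)
  if (m > n - 1) stop("m must be <= n - 1", call. = FALSE)
  d <- diag(D)
  if (any(d <= 0)) stop("degree matrix must be positive", call. = FALSE)
  s <- 1 / sqrt(d)
  A <- t(L * s) * s          # D^{-1/2} L D^{-1/2}, stays symmetric
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  if (any(!is.finite(e$values)))
    stop("eigendecomposition failed; graph: n = ", n,
         ", min degree = ", signif(min(d), 4), call. = FALSE)
  # eigen() returns descending; take the m+1 smallest, drop the trivial one
  sel <- seq(n, n - m, by = -1L)
  vals <- e$values[sel]
  vecs <- e$vectors[, sel, drop = FALSE] * s   # back-transform to v
  if (abs(vals[1]) > 1e-8 * max(abs(e$values)))
    warning("smallest generalised eigenvalue is not ~0; graph may be ",
            "disconnected or weights degenerate")
  vals <- vals[-1]
  vecs <- vecs[, -1, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(vectors = vecs, eigenvalues = pmax(vals, 0))
}

#' Normalise a gradient to the [1, 10] connectopic scale
#'
#' Affine rescaling sending the minimum to 1 and the maximum to 10;
#' idempotent, rejects constant input.
#'
#' @param v numeric vector, non-constant
#' @return vector of the same length with `min = 1`, `max = 10`
#' @export
normalize_map <- function(v) {
  rescale01(v, lo = 1, hi = 10)
}

#' Align a connectopic map to a reference by the flip-about-5.5 rule
#'
#' An eigenvector's sign is arbitrary, and after [1,10] normalisation a
#' sign flip becomes the reflection `11 - g` about the midpoint 5.5. The
#' target map is returned unchanged when its Pearson correlation with the
#' reference is at least 0.75, and reflected otherwise.
#'
#' @param ref,target equal-length maps on the [1,10] scale
#' @param threshold correlation below which the target is flipped
#' @return the aligned target map
#' @export
align_to_reference <- function(ref, target, threshold = 0.75) {
  if (length(ref) != length(target))
    stop("maps must have equal length", call. = FALSE)
  if (stats::sd(ref) == 0 || stats::sd(target) == 0)
    stop("zero-variance map cannot be aligned", call. = FALSE)
  r <- stats::cor(ref, target)
  if (r >= threshold) target else 11 - target
}

#' Construct a connectopic map object
#'
#' @param values n_vertices x m matrix, each column on the [1,10] scale
#' @param eigenvalues length-m positive non-decreasing eigenvalues
#' @param subject,session labels
#' @return a `connectopic_map` object
#' @export
connectopic_map <- function(values, eigenvalues, subject = NA, session = NA) {
  values <- as.matrix(values)
  m <- ncol(values)
  if (length(eigenvalues) != m)
    stop("eigenvalues length must equal number of modes", call. = FALSE)
  if (any(diff(eigenvalues) < 0))
    stop("eigenvalues must be non-decreasing", call. = FALSE)
  for (j in seq_len(m)) {
    rng <- range(values[, j])
    if (abs(rng[1] - 1) > 1e-9 || abs(rng[2] - 10) > 1e-9)
      stop("mode ", j, " is not normalised to [1, 10]", call. = FALSE)
  }
  colnames(values) <- paste0("g", seq_len(m))
  structure(list(values = values, eigenvalues = as.numeric(eigenvalues),
                 m = m, subject = subject, session = session),
            class = "connectopic_map")
}

#' @export
print.connectopic_map <- function(x, ...) {
  cat(sprintf("connectopic_map: %d vertices x %d mode(s)%s\n",
              nrow(x$values), x$m,
              if (!is.na(x$subject))
                sprintf(" (subject %s, session %s)", x$subject, x$session)
              else ""))
  invisible(x)
}

#' Fit a subject-level connectopic map from a connectivity matrix
#'
#' Chains the pipeline's embedding stages: eta-squared similarity,
#' minimally connected kNN graph, graph Laplacian, Laplacian eigenmaps,
#' and [1,10] normalisation per mode.
#'
#' @param cm a [connectivity_matrix()]
#' @param m number of modes to retain
#' @param transform profile transform passed to [similarity_matrix()]
#' @return a [connectopic_map()] (with the similarity matrix attached as
#'   attribute `"similarity"` for reuse, e.g. dimensionality estimation)
#' @export
fit_connectopic_map <- function(cm, m, transform = "raw") {
  sim <- similarity_matrix(cm, transform = transform)
  g <- minimal_k_graph(sim)
  ld <- graph_laplacian(g)
  em <- laplacian_eigenmaps(ld$L, ld$D, m)
  vals <- apply(em$vectors, 2L, normalize_map)
  out <- connectopic_map(vals, em$eigenvalues,
                         subject = cm$subject, session = cm$session)
  attr(out, "similarity") <- sim
  attr(out, "k_used") <- g$k_used
  out
}

#' Align a list of connectopic maps to a reference subject
#'
#' The reference is the map whose subject label sorts first
#' (lexicographically). Each reference mode is first put into a
#' canonical orientation (the vertex deviating most from the 5.5
#' midpoint lies above it), so that the aligned cohort -- and hence any
#' group average -- does not depend on the arbitrary sign of any
#' subject's eigenvectors, the reference's included. Every mode of every
#' map is then flipped about 5.5 when its correlation with the
#' canonical reference mode falls below the threshold.
#'
#' @param maps list of [connectopic_map()]s with equal n and m
#' @param threshold flip threshold passed to [align_to_reference()]
#' @return the list with aligned `values`
#' @export
align_cohort <- function(maps, threshold = 0.75) {
  stopifnot(length(maps) >= 1)
  subj <- vapply(maps, function(x) as.character(x$subject), character(1))
  ref <- maps[[order(subj)[1]]]
  for (j in seq_len(ref$m)) {
    v <- ref$values[, j]
    if (v[which.max(abs(v - 5.5))] < 5.5) ref$values[, j] <- 11 - v
  }
  lapply(maps, function(x) {
    for (j in seq_len(x$m))
      x$values[, j] <- align_to_reference(ref$values[, j], x$values[, j],
                                          threshold = threshold)
    x
  })
}

#' Group-average aligned connectopic maps
#'
#' Vertex-wise arithmetic mean per mode across subjects, re-normalised to
#' [1, 10]. All maps must share dimensions and be aligned to a common
#' reference first (see [align_cohort()]).
#'
#' @param maps list of aligned [connectopic_map()]s
#' @return a group-level [connectopic_map()] (eigenvalues averaged)
#' @export
group_average <- function(maps) {
  stopifnot(length(maps) >= 1)
  n <- nrow(maps[[1]]$values); m <- maps[[1]]$m
  for (x in maps)
    if (nrow(x$values) != n || x$m != m)
      stop("maps have mixed dimensions", call. = FALSE)
  mean_vals <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  vals <- apply(mean_vals, 2L, normalize_map)
  eig <- Reduce(`+`, lapply(maps, `[[`, "eigenvalues")) / length(maps)
  connectopic_map(vals, eig, subject = "group", session = NA)
}
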