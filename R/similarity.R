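# eta-squared profile similarity and the minimally connected kNN graph.

#' eta-squared similarity between two connectivity profiles
#'
#' With `m_i = (a_i + b_i)/2` and `M` the grand mean of the `m_i`,
#' `eta2 = 1 - [sum_i (a_i - m_i)^2 + (b_i - m_i)^2] /
#'             [sum_i (a_i - M)^2 + (b_i - M)^2]`:
#' the fraction of the pair's total variance not attributable to
#' within-pair disagreement. It is 1 for identical non-constant profiles,
#' 0 when all variance is disagreement, and symmetric in its arguments.
#'
#' Two equal constant profiles make the denominator zero; they are
#' perfectly similar, so 1 is returned with a warning.
#'
#' @param a,b equal-length numeric profiles
#' @return a scalar in [0, 1]
#' @export
eta2_similarity <- function(a, b) {
  if (length(a) != length(b))
    stop("profiles must have equal length", call. = FALSE)
  m <- (a + b) / 2
  M <- mean(m)
  num <- sum((a - m)^2 + (b - m)^2)
  den <- sum((a - M)^2 + (b - M)^2)
  if (den == 0) {
    warning("both profiles constant and equal; eta2 = 1 by convention")
    return(1)
  }
  1 - num / den
}

#' All-pairs eta-squared similarity matrix
#'
#' Computes every pairwise [eta2_similarity()] value between the seed rows
#' of a connectivity matrix, vectorised through the identity
#' `sum_i (a_i - m_i)^2 + (b_i - m_i)^2 = ||a - b||^2 / 2`.
#'
#' @param cm a [connectivity_matrix()], or a plain numeric matrix of
#'   profiles (rows = seeds)
#' @param transform optional profile transform applied before comparison:
#'   `"raw"` (default), `"log1p"`, or `"row-norm"` (rows scaled to sum 1)
#' @return an n x n symmetric matrix with unit diagonal, class
#'   `similarity_matrix`
#' @export
similarity_matrix <- function(cm, transform = c("raw", "log1p", "row-norm")) {
  transform <- match.arg(transform)
  A <- if (inherits(cm, "connectivity_matrix")) cm$counts else as.matrix(cm)
  A <- switch(transform,
              raw = A,
              log1p = log1p(A),
              `row-norm` = A / rowSums(A))
  n <- nrow(A); p <- ncol(A)
  S2 <- rowSums(A^2)          # sum of squares per profile
  Tm <- rowSums(A)            # profile totals; grand mean M_ij = (T_i+T_j)/(2p)
  G <- tcrossprod(A)
  num <- (outer(S2, S2, "+") - 2 * G) / 2
  M <- outer(Tm, Tm, "+") / (2 * p)
  den <- outer(S2, S2, "+") - 2 * M * outer(Tm, Tm, "+") + 2 * p * M^2
  bad <- den == 0
  if (any(bad & num > 1e-12 * pmax(1, outer(S2, S2, "+"))))
    stop("zero denominator for non-identical profiles (numerical breakdown)",
         call. = FALSE)
  if (any(bad[upper.tri(bad)]))
    warning("constant-equal profile pairs; eta2 = 1 by convention at: ",
            paste(utils::head(which(bad & upper.tri(bad))), collapse = ", "))
  sim <- ifelse(bad, 1, 1 - num / den)
  sim <- (sim + t(sim)) / 2   # remove last-bit asymmetry
  diag(sim) <- 1
  sim <- pmin(pmax(sim, 0), 1)
  structure(sim, class = c("similarity_matrix", "matrix", "array"))
}

# number of connected components of a symmetric logical/numeric adjacency
n_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  cid
}

# union-symmetrised kNN adjacency at a given k (logical matrix);
# neighbours ranked by descending similarity, ties by ascending index,
# self excluded, zero-similarity neighbours never linked
knn_adjacency <- function(sim, k) {
  n <- nrow(sim)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    s <- sim[i, ]
    s[i] <- -Inf
    ord <- order(-s, seq_len(n))[seq_len(k)]
    ord <- ord[s[ord] > 0]          # drop would-be weight-0 edges
    adj[i, ord] <- TRUE
  }
  adj | t(adj)
}

#' Minimally connected k-nearest-neighbour similarity graph
#'
#' Links every node to its k most-similar neighbours (union
#' symmetrisation, ties broken by ascending node index, self excluded),
#' with k the minimum value at which the graph has exactly one connected
#' component. Edge weights are the similarity values; zero-similarity
#' edges are never created, and if dropping them leaves the graph
#' disconnected at every k an error is raised.
#'
#' @param sim a [similarity_matrix()] (any symmetric non-negative matrix
#'   with unit diagonal works)
#' @return a `neighbour_graph`: `weights` (sparse symmetric
#'   [Matrix::dsCMatrix]), `k_used`, `degree`
#' @export
minimal_k_graph <- function(sim) {
  n <- nrow(sim)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  k_used <- NA_integer_
  adj <- NULL
  # connectivity is monotone in k (adjacency only gains edges), so binary
  # search over k = 1..n-1 finds the threshold
  lo <- 1L; hi <- n - 1L
  if (n_components(knn_adjacency(sim, hi)) != 1L)
    stop("graph disconnected even at k = n-1 ",
         "(zero-similarity blocks are unreachable)", call. = FALSE)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (n_components(knn_adjacency(sim, mid)) == 1L) hi <- mid else lo <- mid + 1L
  }
  k_used <- lo
  adj <- knn_adjacency(sim, k_used)
  W <- matrix(0, n, n)
  W[adj] <- sim[adj]
  diag(W) <- 0
  Wsp <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
  Wsp <- Matrix::forceSymmetric(Wsp)
  structure(
    list(weights = Wsp, k_used = k_used, degree = Matrix::rowSums(Wsp)),
    class = "neighbour_graph")
}

#' @export
print.neighbour_graph <- function(x, ...) {
  cat(sprintf("neighbour_graph: %d nodes, k_used = %d, %d edges\n",
              nrow(x$weights), x$k_used,
              Matrix::nnzero(x$weights) / 2))
  invisible(x)
}

#' Graph Laplacian and degree matrix of a neighbour graph
#'
#' @param g a [minimal_k_graph()] result (or any symmetric non-negative
#'   weight matrix wrapped in a list with element `weights`)
#' @return list with dense symmetric `L = D - W` and diagonal `D` matrices
#' @export
graph_laplacian <- function(g) {
  W <- as.matrix(g$weights)
  d <- rowSums(W)
  if (any(d <= 0))
    stop("isolated node(s) with zero degree: ",
         paste(utils::head(which(d <= 0), 5), collapse = ", "), call. = FALSE)
  list(L = diag(d) - W, D = diag(d))
}
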