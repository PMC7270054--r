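# Independent oracles and shared fixtures for the test suite.
# Oracles are deliberately written as literal, unoptimised translations of
# the defining formulas, independent of the package's vectorised paths.

# literal double-loop evaluation of the eta-squared sums
eta2_oracle <- function(a, b) {
  num <- 0; den <- 0
  M <- mean((a + b) / 2)
  for (i in seq_along(a)) {
    m_i <- (a[i] + b[i]) / 2
    num <- num + (a[i] - m_i)^2 + (b[i] - m_i)^2
    den <- den + (a[i] - M)^2 + (b[i] - M)^2
  }
  1 - num / den
}

# ICC(2,1) via stats::aov mean squares (independent ANOVA route)
icc21_oracle <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   target = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ target + rater, data = df))[[1]]
  msr <- tab["target", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# brute-force minimal-k search using igraph for component counting
minimal_k_oracle <- function(sim) {
  n <- nrow(sim)
  for (k in 1:(n - 1)) {
    adj <- matrix(FALSE, n, n)
    for (i in 1:n) {
      s <- sim[i, ]; s[i] <- -Inf
      nb <- order(-s, seq_len(n))[1:k]
      nb <- nb[s[nb] > 0]
      adj[i, nb] <- TRUE
    }
    adj <- adj | t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::components(g)$no == 1) return(k)
  }
  NA_integer_
}

# generalised eigenproblem L v = lambda D v via the non-symmetric
# standard problem D^-1 L (independent of the package's symmetric route)
geigen_oracle <- function(L, D) {
  e <- eigen(solve(D) %*% L)
  ord <- order(Re(e$values))
  list(values = Re(e$values)[ord],
       vectors = Re(e$vectors)[, ord, drop = FALSE])
}

# similarity matrix with block structure plus a weak bridge, for
# minimal-k stress tests
random_block_sim <- function(n, seed) {
  set.seed(seed)
  half <- n %/% 2
  blocks <- c(rep(1, half), rep(2, n - half))
  sim <- matrix(stats::runif(n * n, 0.01, 0.2), n, n)
  within <- outer(blocks, blocks, "==")
  sim[within] <- stats::runif(sum(within), 0.5, 1)
  sim <- (sim + t(sim)) / 2
  diag(sim) <- 1
  sim
}

# small noiseless cohort fixtures (cached per test run)
.fixtures <- new.env()

noiseless_cohort <- function(m_true, n_subjects = 2, n_uv = 20, seed = 7) {
  key <- paste0("cohort_m", m_true, "_s", n_subjects, "_n", n_uv, "_", seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  mesh <- make_seed_mesh(n_uv, n_uv)
  truth <- plant_gradients(mesh, m_true)
  spec <- cohort_spec(n_subjects, 2, depth = 1e4,
                      sigma_subject = 0, sigma_session = 0, rng_seed = seed)
  cms <- list()
  for (s in seq_len(n_subjects))
    cms[[s]] <- simulate_connectivity(truth, 50, spec, s, 1, mesh = mesh)
  out <- list(mesh = mesh, truth = truth, spec = spec, cms = cms)
  .fixtures[[key]] <- out
  out
}

# tiny hand-built connectivity matrix on a 3x3x2 grid (up to 9 targets,
# each at a distinct voxel of slice 1)
toy_connectivity <- function(counts, per_seed_total = 1e4) {
  p <- ncol(counts)
  stopifnot(p <= 9)
  idx <- seq_len(p) - 1L
  connectivity_matrix(
    counts = counts,
    seed_ids = seq_len(nrow(counts)),
    target_ijk = cbind(idx %% 3L + 1L, idx %/% 3L + 1L, rep(1L, p)),
    grid_shape = c(3L, 3L, 2L),
    per_seed_total = per_seed_total)
}
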