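test_that("eigenmaps match a dense generalised-eigenproblem oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(8:30, 1)
    sim <- random_block_sim(n, seed = 300 + rep)
    g <- minimal_k_graph(sim)
    ld <- graph_laplacian(g)
    m <- min(4, n - 1)
    em <- laplacian_eigenmaps(ld$L, ld$D, m)

    oracle <- geigen_oracle(ld$L, ld$D)
    # discarded first eigenvector is constant with ~0 eigenvalue
    expect_lt(abs(oracle$values[1]), 1e-8)
    v0 <- oracle$vectors[, 1]
    expect_lt(diff(range(v0 / v0[1])), 1e-6)
    # retained eigenvalues match
    expect_equal(em$eigenvalues, oracle$values[2:(m + 1)], tolerance = 1e-8)
    # retained vectors match up to sign after D-normalisation
    for (j in seq_len(m)) {
      v <- em$vectors[, j]
      w <- oracle$vectors[, j + 1]
      w <- w / sqrt(sum(diag(ld$D) * w^2))
      err <- min(max(abs(v - w)), max(abs(v + w)))
      expect_lt(err, 1e-6)
    }
    # D-orthonormality
    G <- t(em$vectors) %*% ld$D %*% em$vectors
    expect_equal(G, diag(m), tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("the first retained eigenvector of a path graph is monotone", {
  W <- matrix(0, 5, 5)
  for (i in 1:4) W[i, i + 1] <- W[i + 1, i] <- 1
  ld <- graph_laplacian(list(weights = W))
  em <- laplacian_eigenmaps(ld$L, ld$D, 1)
  expect_true(all(diff(em$vectors[, 1]) > 0) || all(diff(em$vectors[, 1]) < 0))
})

test_that("map normalisation is an affine map onto [1,10] and idempotent", {
  expect_equal(normalize_map(c(0.2, 0.5, 0.8)), c(1, 5.5, 10))
  expect_equal(normalize_map(c(-1, 1)), c(1, 10))
  v <- rnorm(50)
  expect_equal(normalize_map(normalize_map(v)), normalize_map(v))
  expect_error(normalize_map(rep(3, 10)), "constant")
})

test_that("alignment flips anti-correlated maps and passes correlated ones", {
  set.seed(3)
  ref <- normalize_map(rnorm(100))
  expect_equal(align_to_reference(ref, 11 - ref), ref)
  expect_equal(align_to_reference(ref, ref), ref)
  # a map correlated at ~0.8 passes through unchanged
  target <- normalize_map(ref + rnorm(100, sd = 2))
  while (stats::cor(ref, target) < 0.76 || stats::cor(ref, target) > 0.95) {
    target <- normalize_map(ref + rnorm(100, sd = 2))
  }
  expect_identical(align_to_reference(ref, target), target)
  expect_error(align_to_reference(ref, rep(5, 100)), "variance")
})

test_that("group averaging restores [1,10], rejects mixed sizes, averages noise down", {
  set.seed(14)
  truth <- normalize_map(sin(seq(0, pi, length.out = 120)) +
                           seq(0, 1, length.out = 120))
  mk <- function(noise_sd, s) {
    connectopic_map(matrix(normalize_map(truth + rnorm(120, sd = noise_sd))),
                    eigenvalues = 0.01, subject = s, session = 1)
  }
  maps <- lapply(1:10, function(s) mk(0.5, s))
  gm <- group_average(align_cohort(maps))
  rho_group <- abs(stats::cor(gm$values[, 1], truth, method = "spearman"))
  rho_ind <- vapply(maps, function(m)
    abs(stats::cor(m$values[, 1], truth, method = "spearman")), numeric(1))
  expect_gt(rho_group, stats::median(rho_ind))
  expect_equal(range(gm$values[, 1]), c(1, 10))

  identical_maps <- lapply(1:3, function(s) mk(0, s))
  gm_id <- group_average(identical_maps)
  expect_equal(gm_id$values[, 1], identical_maps[[1]]$values[, 1])

  short <- connectopic_map(matrix(normalize_map(rnorm(50))), 0.01)
  expect_error(group_average(list(maps[[1]], short)), "mixed")
})

test_that("group maps are invariant to per-subject eigenvector sign flips", {
  set.seed(31)
  truth <- seq(0, 1, length.out = 80)
  maps <- lapply(1:5, function(s)
    connectopic_map(matrix(normalize_map(truth + rnorm(80, sd = 0.05))),
                    eigenvalues = 0.01, subject = s, session = 1))
  flipped <- maps
  # flipping an eigenvector's sign turns its normalised map into 11 - g
  for (s in c(2, 4)) flipped[[s]]$values <- 11 - flipped[[s]]$values
  g1 <- group_average(align_cohort(maps))
  g2 <- group_average(align_cohort(flipped))
  expect_equal(g1$values, g2$values, tolerance = 1e-10)
})

test_that("end-to-end recovery of planted gradients on noiseless cohorts", {
  fx1 <- noiseless_cohort(1, n_subjects = 2)
  for (cm in fx1$cms) {
    map <- fit_connectopic_map(cm, 1)
    rho <- stats::cor(map$values[, 1], fx1$truth$latent_fields[, 1],
                      method = "spearman")
    expect_gte(abs(rho), 0.95)
  }

  fx2 <- noiseless_cohort(2, n_subjects = 1)
  map <- fit_connectopic_map(fx2$cms[[1]], 2)
  R <- abs(stats::cor(map$values, fx2$truth$latent_fields,
                      method = "spearman"))
  paired <- max(min(R[1, 1], R[2, 2]), min(R[1, 2], R[2, 1]))
  expect_gte(paired, 0.9)
  # eigenvalues strictly increasing for the generic synthetic graph
  expect_true(all(diff(map$eigenvalues) > 0))
})

test_that("connectopic map construction validates its invariants", {
  ok <- connectopic_map(matrix(normalize_map(1:10)), 0.1)
  expect_equal(ok$m, 1)
  expect_error(connectopic_map(matrix(2:11), 0.1), "normalised")
  expect_error(
    connectopic_map(cbind(normalize_map(1:10), normalize_map(10:1)),
                    c(0.2, 0.1)),
    "non-decreasing")
})
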