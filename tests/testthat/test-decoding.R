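test_that("decile partition sizes follow the remainder rule and partition all vertices", {
  m100 <- decile_partition(seq_len(100) / 100)
  expect_true(all(vapply(m100, sum, integer(1)) == 10))

  m10 <- decile_partition(rnorm(10))
  expect_true(all(vapply(m10, sum, integer(1)) == 1))

  m105 <- decile_partition(rnorm(105))
  expect_equal(vapply(m105, sum, integer(1)),
               c(11, 11, 11, 11, 11, 10, 10, 10, 10, 10))
  # masks partition: every vertex in exactly one mask
  total <- Reduce(`+`, lapply(m105, as.integer))
  expect_true(all(total == 1))

  # lowest decile holds the smallest values
  v <- c(5, 1, 3, 2, 4, 10, 9, 8, 7, 6)
  m <- decile_partition(v)
  expect_equal(which(m[[1]]), 2)
  expect_equal(which(m[[10]]), 6)

  expect_error(decile_partition(rnorm(9)), "at least 10")
  expect_error(decile_partition(rep(1, 20)), "constant")
})

test_that("decile partition is invariant to strictly monotone transforms", {
  set.seed(2)
  v <- rnorm(73)
  m1 <- decile_partition(v)
  m2 <- decile_partition(exp(2 * v) + 5)
  expect_identical(m1, m2)
})

test_that("vertex masks rasterise to binary volumes", {
  v2v <- cbind(c(1, 1, 2), c(1, 1, 2), c(1, 1, 1))
  empty <- mask_to_volume(c(FALSE, FALSE, FALSE), v2v, c(2, 2, 2))
  expect_true(all(empty == 0))
  # two vertices sharing a voxel produce a single 1
  two <- mask_to_volume(c(TRUE, TRUE, FALSE), v2v, c(2, 2, 2))
  expect_equal(sum(two), 1)
  expect_equal(two[1, 1, 1], 1L)
  expect_error(mask_to_volume(c(TRUE, TRUE, TRUE), v2v, c(1, 1, 1)),
               "outside")
})

test_that("OR of all decile volumes equals the seed footprint", {
  mesh <- make_seed_mesh(10, 10)
  truth <- plant_gradients(mesh, 1)
  v2v <- vertex_to_voxel_map(mesh, c(10, 10, 3))
  masks <- decile_partition(truth$latent_fields[, 1])
  vols <- lapply(masks, mask_to_volume, vertex_to_voxel = v2v,
                 grid_shape = c(10, 10, 3))
  any_vol <- Reduce(`+`, vols) > 0
  foot <- array(FALSE, c(10, 10, 3)); foot[v2v] <- TRUE
  expect_equal(any_vol, foot)
})

test_that("decoding ranks, filters and collapses terms as specified", {
  grid <- c(6, 6, 3)
  set.seed(33)
  mask <- array(0L, grid); mask[1:3, , 1] <- 1L
  lib <- term_library(
    terms = c("self", "anat_hit", "syn_a", "syn_b", "negative", "flat"),
    maps = list(self = array(as.numeric(mask), grid),
                anat_hit = array(as.numeric(mask), grid),
                syn_a = array(as.numeric(mask) + rnorm(prod(grid), sd = 0.4), grid),
                syn_b = array(as.numeric(mask) + rnorm(prod(grid), sd = 0.1), grid),
                negative = array(1 - as.numeric(mask), grid),
                flat = array(2, grid)),
    is_anatomical = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    synonym_group = c("self", "anat_hit", "syn", "syn", "neg", "flat"),
    grid_shape = grid)
  expect_warning(decode_decile(mask, lib), "flat")
  res <- suppressWarnings(decode_decile(mask, lib))
  # exact-match term first with r = 1
  expect_equal(res$term[1], "self")
  expect_equal(res$r[1], 1.0)
  # anatomical term excluded despite r = 1; synonyms collapsed to best member
  expect_false("anat_hit" %in% res$term)
  expect_true(sum(res$term %in% c("syn_a", "syn_b")) <= 1)
  expect_equal(res$term[2], "syn_b")
  # negative correlations never shown
  expect_false("negative" %in% res$term)
  expect_true(all(res$r > 0))
  expect_lte(nrow(res), 3)
})

test_that("planted signal terms are recovered as top-1 across deciles", {
  mesh <- make_seed_mesh(20, 20)
  truth <- plant_gradients(mesh, 2)
  v2v <- vertex_to_voxel_map(mesh)
  lib <- simulate_term_library(c(20, 20, 8), truth, v2v,
                               n_noise_terms = 10, rng_seed = 5,
                               noise_sd = 0.3)
  gmap <- connectopic_map(apply(truth$latent_fields, 2, normalize_map),
                          c(0.001, 0.002))
  for (mode in 1:2) {
    tab <- decoding_table(gmap, mode, lib, v2v)
    top1 <- vapply(tab$top3, function(t) t$term[1], character(1))
    hits <- sum(top1 == sprintf("g%d_decile%02d", mode, 1:10))
    expect_gte(hits, 9)
    # diagonal structure: the planted term for decile d peaks at decile d
    for (d in c(1, 5, 10)) {
      term <- sprintf("g%d_decile%02d", mode, d)
      if (term %in% rownames(tab$r)) {
        rr <- tab$r[term, ]
        expect_equal(unname(which.max(replace(rr, is.na(rr), -1))), d)
      }
    }
  }
})

test_that("an all-noise library yields only small positive correlations", {
  set.seed(12)
  grid <- c(10, 10, 10)
  lib <- term_library(
    terms = sprintf("noise%02d", 1:8),
    maps = lapply(1:8, function(i) array(rnorm(1000), grid)),
    is_anatomical = rep(FALSE, 8),
    grid_shape = grid)
  mask <- array(0L, grid); mask[sample(1000, 100)] <- 1L
  res <- decode_decile(mask, lib)
  expect_lte(nrow(res), 3)
  expect_true(all(res$r < 0.2))
})

test_that("decoding tables are deterministic", {
  mesh <- make_seed_mesh(10, 10)
  truth <- plant_gradients(mesh, 1)
  v2v <- vertex_to_voxel_map(mesh, c(10, 10, 4))
  lib <- simulate_term_library(c(10, 10, 4), truth, v2v,
                               n_noise_terms = 4, rng_seed = 9,
                               noise_sd = 0.2)
  gmap <- connectopic_map(cbind(normalize_map(truth$latent_fields[, 1])), 0.01)
  t1 <- decoding_table(gmap, 1, lib, v2v)
  t2 <- decoding_table(gmap, 1, lib, v2v)
  expect_identical(t1, t2)
})
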