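blob_map <- function(n_blobs, per_blob, spread = 0.05, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(runif(n_blobs * 2, -10, 10), n_blobs, 2)
    coords <- centers[rep(seq_len(n_blobs), each = per_blob), ] +
      matrix(rnorm(n_blobs * per_blob * 2, 0, spread), ncol = 2)
    list(map = make_map_obj(coords),
         truth = rep(seq_len(n_blobs), each = per_blob))
  })
}

test_that("k = N puts every item in its own cluster", {
  bm <- blob_map(3, 2, seed = 5)
  lad <- cluster_ladder(bm$map, k_max = 6, k_min = 2)
  sol <- ladder_solution(lad, 6)
  expect_equal(dplyr::n_distinct(sol$cluster), 6)
})

test_that("each ladder solution refines the next coarser one, for every k", {
  sim_data <- simulate_sorting(n_items = 20, n_sorters = 8,
                               n_true_clusters = 5, noise = 0.3, seed = 17)
  map <- embed_map(build_similarity(sim_data$sorts), seed = 3, n_starts = 3)
  lad <- cluster_ladder(map, k_max = 12, k_min = 2)
  for (k in 12:3) {
    fine <- ladder_solution(lad, k)$cluster
    coarse <- ladder_solution(lad, k - 1)$cluster
    # within a fine cluster, the coarse label must be constant
    expect_true(all(tapply(coarse, fine,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("well-separated blobs are recovered and match the brute-force Ward oracle", {
  bm <- blob_map(3, 3, spread = 0.05, seed = 7)
  lad <- cluster_ladder(bm$map, k_max = 9, k_min = 2)
  sol3 <- ladder_solution(lad, 3)
  expect_true(same_partition(sol3$cluster, bm$truth))
  for (k in c(2, 4, 5)) {
    ours <- ladder_solution(lad, k)$cluster
    theirs <- oracle_ward(bm$map$coords, k)
    expect_true(same_partition(ours, theirs))
  }
})

test_that("cluster ladder validates its k range", {
  bm <- blob_map(2, 2, seed = 1)
  expect_error(cluster_ladder(bm$map, k_max = 2, k_min = 3),
               class = "dtpd_input_error")
  expect_error(cluster_ladder(bm$map, k_max = 10, k_min = 2),
               class = "dtpd_input_error")
})

test_that("hand-set counts and coordinates reproduce the bridging double loop", {
  coords <- rbind(c(0, 0), c(1, 0), c(0, 1), c(4, 4), c(5, 5))
  items <- paste0("it", 1:5)
  rownames(coords) <- items
  counts <- matrix(0L, 5, 5, dimnames = list(items, items))
  counts[1, 2] <- counts[2, 1] <- 7L
  counts[1, 3] <- counts[3, 1] <- 5L
  counts[2, 3] <- counts[3, 2] <- 6L
  counts[4, 5] <- counts[5, 4] <- 8L
  counts[1, 4] <- counts[4, 1] <- 2L
  diag(counts) <- 9L
  b <- bridging_values(make_map_obj(coords), make_sim_obj(counts, 9L))
  expect_equal(b$bridging, oracle_bridging(counts, coords), tolerance = 1e-12)
  expect_true(all(b$defined))
  # min-max endpoints
  expect_equal(min(b$bridging), 0)
  expect_equal(max(b$bridging), 1)
  expect_equal(b$item_id[which.max(b$bridging)], items[which.max(b$raw)])
})

test_that("fully symmetric designs collapse to all-zero bridging", {
  # equilateral triangle, equal counts everywhere: every raw value equal
  coords <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  items <- paste0("it", 1:3)
  rownames(coords) <- items
  counts <- matrix(4L, 3, 3, dimnames = list(items, items))
  diag(counts) <- 8L
  b <- bridging_values(make_map_obj(coords), make_sim_obj(counts, 8L))
  expect_equal(b$bridging, rep(0, 3))
})

test_that("an item never co-piled is flagged undefined, not zero", {
  coords <- rbind(c(0, 0), c(1, 0), c(2, 2))
  items <- paste0("it", 1:3)
  rownames(coords) <- items
  counts <- matrix(0L, 3, 3, dimnames = list(items, items))
  counts[1, 2] <- counts[2, 1] <- 3L
  diag(counts) <- 5L
  expect_warning(b <- bridging_values(make_map_obj(coords),
                                      make_sim_obj(counts, 5L)),
                 "undefined")
  expect_true(is.na(b$bridging[3]))
  expect_false(b$defined[3])
})

test_that("normalised bridging is invariant under rigid motions of the map", {
  sim_data <- simulate_sorting(n_items = 12, n_sorters = 6,
                               n_true_clusters = 4, noise = 0.3, seed = 19)
  sim <- build_similarity(sim_data$sorts)
  map <- embed_map(sim, seed = 4, n_starts = 3)
  b0 <- bridging_values(map, sim)
  theta <- 0.83
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  rotated <- map
  rotated$coords <- map$coords %*% R + matrix(c(5, -2), nrow(map$coords), 2,
                                              byrow = TRUE)
  b1 <- bridging_values(rotated, sim)
  expect_equal(b1$bridging, b0$bridging, tolerance = 1e-8)
})
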