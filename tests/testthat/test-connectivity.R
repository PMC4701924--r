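test_that("standardize centers, scales, and zeroes constant columns", {
  tab <- voxelgraph:::voxel_table(
    cbind(c(1, 2, 3), c(5, 5, 5), c(2, 4, 9)),
    index_map = 0:2, grid_dims = c(3L, 1L, 1L))
  z <- standardize(tab)
  expect_equal(z$data[, 1], c(-1, 0, 1))
  expect_equal(z$data[, 2], c(0, 0, 0))
  expect_identical(attr(z, "zero_variance"), 2L)

  z2 <- standardize(random_table(30, 12, seed = 5))
  expect_true(all(abs(colMeans(z2$data)) < 1e-12))
  expect_true(all(abs(apply(z2$data, 2, sd) - 1) < 1e-12))
})

test_that("plan_tiles arithmetic matches the block-height formula", {
  p <- plan_tiles(1000, 8, 160000)
  expect_equal(p$blocks$end[1] - p$blocks$start[1], 20)
  expect_equal(nrow(p$blocks), 50)

  p2 <- plan_tiles(1000, 8, 8e6)
  expect_equal(nrow(p2$blocks), 1)
  expect_equal(unlist(p2$blocks[1, ], use.names = FALSE), c(0, 1000))

  # whole-brain voxel count at a 4.2 GiB tile budget
  p3 <- plan_tiles(228200, 8, 4.2 * 2^30)
  expect_gte(nrow(p3$blocks), 91)
  expect_lte(nrow(p3$blocks), 93)
  expect_equal(nrow(p3$blocks), 93)   # exact value under this accounting

  # blocks partition [0, n) and every tile respects the budget
  for (p in list(plan_tiles(17, 8, 200), plan_tiles(64, 8, 4096))) {
    expect_equal(p$blocks$start, c(0, head(p$blocks$end, -1)))
    expect_equal(tail(p$blocks$end, 1), p$n_voxels)
    expect_true(all((p$blocks$end - p$blocks$start) * p$n_voxels * 8
                    <= p$tile_budget_bytes))
  }
  expect_error(plan_tiles(1000, 8, 100), "cannot hold one")
})

test_that("memory_footprint is n^2 * bytes (dense, symmetry unexploited)", {
  expect_identical(memory_footprint(228200, 8), 416601920000)
  expect_identical(memory_footprint(1000, 8), 8e6)
  expect_identical(memory_footprint(1, 8), 8)
})

test_that("correlation_tile matches per-pair Pearson and handles edge cases", {
  x <- cbind(c(1, 2, 3, 5), c(2, 4, 6, 10), c(-1, -2, -3, -5))
  z <- standardize(voxelgraph:::voxel_table(x, 0:2, c(3L, 1L, 1L)))
  r <- correlation_tile(z, c(0, 3))
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
  expect_true(all(abs(r) <= 1))

  tab <- random_table(5, 20, seed = 17)
  z2 <- standardize(tab)
  full <- correlation_tile(z2, c(0, 5))
  expect_equal(full, pearson_pair_oracle(tab$data), tolerance = 1e-12)
  expect_equal(full, t(full))
  expect_equal(diag(full), rep(1, 5))

  # zero-variance voxels: exact zero rows/columns
  tab$data[, 3] <- 4
  zc <- standardize(tab)
  rc <- correlation_tile(zc, c(0, 5))
  expect_identical(rc[3, -3], rep(0, 4))
  expect_identical(rc[-3, 3], rep(0, 4))

  expect_error(correlation_tile(z2, c(3, 9)), "out of bounds")
  expect_error(correlation_tile(tab, c(0, 2)), "standardized")
})

test_that("cosine tile agrees with Pearson on standardized data", {
  expect_equal(column_cosine_tile(
    voxelgraph:::voxel_table(cbind(c(1, 0), c(0, 1)), 0:1, c(2L, 1L, 1L)),
    c(0, 2)), rbind(c(1, 0), c(0, 1)))

  tab <- random_table(8, 25, seed = 23)
  z <- standardize(tab)
  expect_equal(column_cosine_tile(z, c(0, 8)),
               correlation_tile(z, c(0, 8)), tolerance = 1e-12)
})

test_that("threshold_stream equals dense thresholding and is plan-invariant", {
  # three identical columns form a clique at any threshold
  x <- matrix(rnorm(10), 10, 1)[, c(1, 1, 1)]
  z <- standardize(voxelgraph:::voxel_table(x, 0:2, c(3L, 1L, 1L)))
  e <- threshold_stream(z, NULL, 0.6)
  expect_equal(e$i, c(0, 0, 1))
  expect_equal(e$j, c(1, 2, 2))
  expect_equal(e$r, rep(1, 3))

  tab <- random_table(50, 30, seed = 31)
  z2 <- standardize(tab)
  dense <- pearson_pair_oracle(tab$data)
  for (thr in c(0.2, 0.4, 0.6)) {
    want <- which(abs(dense) >= thr & upper.tri(dense), arr.ind = TRUE)
    want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
    got <- threshold_stream(z2, NULL, thr)
    expect_equal(got$i, want[, 1] - 1L)
    expect_equal(got$j, want[, 2] - 1L)
    expect_equal(got$r, dense[want], tolerance = 1e-12)
  }

  plans <- list(NULL, plan_tiles(50, 8, 50 * 8),      # 1-row tiles
                plan_tiles(50, 8, 7 * 50 * 8),        # 7-row tiles
                plan_tiles(50, 8, 1e9))
  ref <- threshold_stream(z2, plans[[1]], 0.4)
  for (p in plans[-1]) {
    out <- threshold_stream(z2, p, 0.4)
    expect_identical(out$i, ref$i)
    expect_identical(out$j, ref$j)
    expect_identical(out$r, ref$r)    # bit-exact across plans
  }

  # near-1 threshold on independent noise: (almost surely) empty
  noise <- standardize(random_table(20, 50, seed = 41))
  expect_equal(nrow(threshold_stream(noise, NULL, 0.999999)), 0)
  expect_error(threshold_stream(z2, NULL, 1.5), "in \\(0, 1\\)")
})

test_that("edge count is non-increasing along a descending threshold grid", {
  z <- standardize(random_table(40, 25, seed = 53))
  grid <- seq(0.9, 0.1, by = -0.1)
  counts <- voxelgraph:::edge_counts_over_grid(z, NULL, grid)
  expect_true(all(diff(counts) >= 0))  # descending grid -> growing E
  # binned counts agree with direct streaming at each grid point
  direct <- vapply(grid, function(t) nrow(threshold_stream(z, NULL, t)), 1L)
  expect_equal(counts, direct)
})
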