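test_that("edge-list loader dedupes, drops self-loops, parses headers", {
  p <- tempfile(fileext = ".txt")
  writeLines(c("# comment", "0 1", "1 0", "1 1"), p)
  g <- suppressMessages(load_edge_list(p))
  expect_equal(length(g$i), 1L)
  expect_equal(c(g$i, g$j), c(0L, 1L))
  expect_message(load_edge_list(p), "self-loop")

  empty <- tempfile(); writeLines(character(0), empty)
  g0 <- load_edge_list(empty, n_vertices = 5)
  expect_equal(g0$n_vertices, 5L)
  expect_equal(length(g0$i), 0L)

  bad <- tempfile(); writeLines(c("0 1", "2 x"), bad)
  expect_error(load_edge_list(bad), "line 2.*non-integer")
  neg <- tempfile(); writeLines("-1 2", neg)
  expect_error(load_edge_list(neg), "negative")
})

test_that("edge-list write/load round-trips, including weights and gzip", {
  z <- standardize(random_table(20, 15, seed = 61))
  e <- threshold_stream(z, NULL, 0.3)
  p <- tempfile(fileext = ".edges.gz")
  write_edge_list(e, p, source = "unit-test")
  g <- load_edge_list(p)                      # n_vertices from header
  expect_equal(g$n_vertices, 20L)
  expect_identical(g$i, as.integer(e$i))
  expect_identical(g$j, as.integer(e$j))

  # two-column compatibility dialect loads identically
  p2 <- tempfile(fileext = ".edges")
  write_edge_list(e, p2, graphx_compat = TRUE)
  g2 <- load_edge_list(p2)
  expect_identical(g2$i, g$i)
  expect_identical(g2$j, g$j)
})

test_that("degrees satisfy closed forms and the handshake lemma", {
  tri <- sparse_graph(c(0, 1, 2), c(1, 2, 0))
  expect_equal(degrees(tri), c(2L, 2L, 2L))
  star <- sparse_graph(c(0, 0, 0), c(1, 2, 3))
  expect_equal(degrees(star), c(3L, 1L, 1L, 1L))
  g <- random_graph(20, 0.3, seed = 71)
  expect_equal(sum(degrees(g)), 2L * length(g$i))
})

test_that("connected components carry min-member labels", {
  g <- sparse_graph(c(1, 2, 5), c(2, 3, 6), n_vertices = 7)
  expect_equal(connected_components(g), c(0L, 1L, 1L, 1L, 4L, 5L, 5L))
  k5 <- random_graph(5, 1, seed = 1)
  expect_equal(connected_components(k5), rep(0L, 5))

  for (s in 1:5) {
    g <- random_graph(60, 0.03, seed = 100 + s)
    expect_equal(connected_components(g), bfs_components_oracle(g))
  }
})

test_that("triangle counts match brute-force triple enumeration", {
  k4 <- sparse_graph(c(0, 0, 0, 1, 1, 2), c(1, 2, 3, 2, 3, 3))
  expect_equal(triangle_counts(k4), rep(3L, 4))
  path <- sparse_graph(c(0, 1), c(1, 2))
  expect_equal(triangle_counts(path), rep(0L, 3))

  for (s in 1:5) {
    g <- random_graph(15, 0.4, seed = 200 + s)
    tc <- triangle_counts(g)
    expect_identical(tc, triangle_triples_oracle(g))
    expect_equal(sum(tc) %% 3, 0)
  }
})

test_that("local clustering follows tc / (d(d-1)/2) with d<2 -> 0", {
  k4 <- sparse_graph(c(0, 0, 0, 1, 1, 2), c(1, 2, 3, 2, 3, 3))
  expect_equal(local_clustering(degrees(k4), triangle_counts(k4)),
               rep(1, 4))
  path <- sparse_graph(c(0, 1), c(1, 2))
  expect_equal(local_clustering(degrees(path), triangle_counts(path)),
               rep(0, 3))   # middle vertex d=2 tc=0 -> 0; leaves d<2 -> 0

  g <- random_graph(40, 0.2, seed = 77)
  cc <- local_clustering(degrees(g), triangle_counts(g))
  expect_true(all(cc >= 0 & cc <= 1))
  skip_if_not_installed("igraph")
  ig <- igraph::graph_from_edgelist(cbind(g$i, g$j) + 1L, directed = FALSE)
  ig <- igraph::add_vertices(ig, g$n_vertices - igraph::vcount(ig))
  ref <- igraph::transitivity(ig, type = "local", isolates = "zero")
  ref[degrees(g) < 2] <- 0
  expect_equal(cc, ref)
})

test_that("pagerank matches symmetry cases and a dense oracle", {
  pair <- sparse_graph(0, 1)
  expect_equal(pagerank(pair), c(0.5, 0.5))
  c6 <- sparse_graph(0:5, c(1:5, 0))
  expect_equal(pagerank(c6), rep(1 / 6, 6), tolerance = 1e-9)

  star <- sparse_graph(c(0, 0, 0), c(1, 2, 3))
  expect_equal(pagerank(star, damping = 0.85, tol = 1e-12),
               pagerank_dense_oracle(star), tolerance = 1e-8)

  # isolated vertices get the dangling treatment, sum stays 1
  g <- sparse_graph(c(0, 1), c(1, 2), n_vertices = 5)
  pr <- pagerank(g)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  expect_equal(pr, pagerank_dense_oracle(g), tolerance = 1e-7)

  expect_error(pagerank(c6, tol = 0, max_iter = 3L), "did not converge")
})

test_that("vertex_metrics bundles consistent per-vertex columns", {
  g <- random_graph(25, 0.25, seed = 88)
  vm <- vertex_metrics(g)
  expect_equal(vm$degree, degrees(g))
  expect_equal(vm$tc, triangle_counts(g))
  expect_equal(vm$cc, local_clustering(vm$degree, vm$tc))
  expect_equal(vm$component, connected_components(g))
  expect_equal(sum(vm$pagerank), 1, tolerance = 1e-9)
})

test_that("edge-density statistic S = log E / log K, base-invariant", {
  s <- edge_density_statistic(100, 40)
  expect_equal(s$K, 5)
  expect_equal(s$S, log(100) / log(5))
  expect_equal(s$S, log10(100) / log10(5))   # base cancels
  expect_equal(edge_density_statistic(64, 16)$S, 2)
  expect_error(edge_density_statistic(0, 10), "undefined")
  expect_error(edge_density_statistic(3, 100), "K = ")
})

test_that("select_threshold picks the largest threshold meeting target S", {
  spec <- community_spec(grid_dims = c(5, 5, 4), n_volumes = 200,
                         communities = rep(25L, 4), seed = 5)
  sim <- generate_bold(spec, tempfile("sel_"))
  z <- standardize(read_masked(sim$image_path, sim$mask_path))
  grid <- seq(0.95, 0.05, by = -0.05)
  sel <- select_threshold(z, target_S = 1.5, grid = grid)
  expect_gt(sel$threshold, 0.1)
  expect_lt(sel$threshold, 0.9)
  expect_gte(sel$summary$S, 1.5)
  # the next larger grid threshold must fail the target
  above <- grid[grid > sel$threshold]
  if (length(above)) {
    nxt <- min(above)
    e_nxt <- nrow(threshold_stream(z, NULL, nxt))
    s_nxt <- if (e_nxt >= 1 && 2 * e_nxt / ncol(z$data) > 1)
      log(e_nxt) / log(2 * e_nxt / ncol(z$data)) else -Inf
    expect_lt(s_nxt, 1.5)
  }
  # count at the selected threshold agrees with direct streaming
  expect_equal(sel$summary$E, nrow(threshold_stream(z, NULL, sel$threshold)))

  expect_error(select_threshold(z, target_S = 100, grid = grid),
               "unattainable")
  one <- grid[abs(grid - sel$threshold) < 1e-9]
  expect_equal(select_threshold(z, 1.5, grid = one)$threshold,
               sel$threshold)
})
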