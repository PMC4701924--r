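# Independent oracles and fixture builders shared across the test files.
# Every oracle here deliberately avoids the code path it checks: dense base-R
# linear algebra vs the package's tiled/sparse routines, BFS vs union-find,
# explicit per-pair formulas vs crossprod.

random_table <- function(v, t, seed) {
  set.seed(seed)
  voxelgraph:::voxel_table(matrix(rnorm(t * v), t, v),
                           index_map = seq_len(v) - 1L,
                           grid_dims = c(v, 1L, 1L))
}

# per-pair Pearson from the textbook formula, no shared code with the package
pearson_pair_oracle <- function(x) {
  v <- ncol(x)
  out <- diag(1, v)
  for (a in seq_len(v - 1)) for (b in (a + 1):v) {
    xa <- x[, a] - mean(x[, a]); xb <- x[, b] - mean(x[, b])
    den <- sqrt(sum(xa^2) * sum(xb^2))
    out[a, b] <- out[b, a] <- if (den == 0) 0 else sum(xa * xb) / den
  }
  out
}

assemble_full <- function(z, plan) {
  parts <- lapply(seq_len(nrow(plan$blocks)), function(b)
    correlation_tile(z, c(plan$blocks$start[b], plan$blocks$end[b])))
  do.call(rbind, parts)
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  sparse_graph(pairs[keep, 1L] - 1L, pairs[keep, 2L] - 1L, n_vertices = n)
}

# breadth-first search components with min-id labels
bfs_components_oracle <- function(g) {
  n <- g$n_vertices
  adj <- vector("list", n)
  for (e in seq_along(g$i)) {
    a <- g$i[e] + 1L; b <- g$j[e] + 1L
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  label <- rep(NA_integer_, n)
  for (s in seq_len(n)) {
    if (!is.na(label[s])) next
    queue <- s; label[s] <- s - 1L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(label[w])) {
        label[w] <- s - 1L; queue <- c(queue, w)
      }
    }
  }
  label
}

# O(n^3) enumeration of all vertex triples (small n only)
triangle_triples_oracle <- function(g) {
  n <- g$n_vertices
  a <- matrix(FALSE, n, n)
  a[cbind(g$i + 1L, g$j + 1L)] <- TRUE
  a <- a | t(a)
  tc <- integer(n)
  if (n >= 3) for (u in 1:(n - 2)) for (v in (u + 1):(n - 1)) for (w in (v + 1):n)
    if (a[u, v] && a[v, w] && a[u, w]) {
      tc[u] <- tc[u] + 1L; tc[v] <- tc[v] + 1L; tc[w] <- tc[w] + 1L
    }
  tc
}

# dense-matrix triangle oracle (base %*%, independent of the sparse path)
triangle_dense_oracle <- function(g) {
  n <- g$n_vertices
  a <- matrix(0, n, n)
  a[cbind(g$i + 1L, g$j + 1L)] <- 1
  a <- a + t(a)
  as.integer(round(diag(a %*% a %*% a) / 2))
}

# dense power-iteration PageRank with uniform dangling redistribution
pagerank_dense_oracle <- function(g, damping = 0.85, tol = 1e-12,
                                  max_iter = 10000L) {
  n <- g$n_vertices
  a <- matrix(0, n, n)
  if (length(g$i)) {
    a[cbind(g$i + 1L, g$j + 1L)] <- 1
    a <- a + t(a)
  }
  d <- rowSums(a)
  m <- matrix(1 / n, n, n)                 # dangling rows: uniform
  live <- d > 0
  m[live, ] <- a[live, ] / d[live]
  p <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    p_new <- (1 - damping) / n + damping * as.vector(t(m) %*% p)
    if (sum(abs(p_new - p)) < tol) return(p_new / sum(p_new))
    p <- p_new
  }
  p / sum(p)
}

make_mask_file <- function(grid_dims, in_mask = NULL,
                           path = tempfile(fileext = ".nii.gz")) {
  arr <- if (is.null(in_mask)) array(1, dim = grid_dims)
         else array(as.double(in_mask), dim = grid_dims)
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "uint8")
  path
}
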