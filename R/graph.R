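#' Construct an undirected simple graph from vertex pairs
#'
#' Canonicalizes to i < j, drops self-loops and duplicate edges (both
#' orientations of a pair collapse to one edge). Isolated vertices are
#' allowed: `n_vertices` may exceed the largest id seen.
#'
#' @param i,j 0-based vertex id vectors of equal length.
#' @param n_vertices Total vertex count; defaults to max id + 1.
#' @return A `sparse_graph`: list with `n_vertices` and integer vectors
#'   `i`, `j` (each undirected edge once, i < j, sorted).
#' @export
sparse_graph <- function(i, j, n_vertices = NULL) {
  stopifnot(length(i) == length(j))
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) && (anyNA(i) || anyNA(j) || min(i, j) < 0))
    stop("vertex ids must be non-negative integers")
  loops <- i == j
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    i <- i[!loops]; j <- j[!loops]
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (is.null(n_vertices))
    n_vertices <- if (length(lo)) max(hi) + 1L else 0L
  if (length(lo) && max(hi) >= n_vertices)
    stop("vertex id exceeds n_vertices")
  key <- as.double(lo) * n_vertices + hi
  keep <- !duplicated(key)
  ord <- order(key[keep])
  structure(list(n_vertices = as.integer(n_vertices),
                 i = lo[keep][ord], j = hi[keep][ord]),
            class = "sparse_graph")
}

#' @export
print.sparse_graph <- function(x, ...) {
  cat(sprintf("<sparse_graph> %d vertices, %d edges\n",
              x$n_vertices, length(x$i)))
  invisible(x)
}

n_edges <- function(g) length(g$i)

#' Load a whitespace-separated edge-list file
#'
#' Reads lines of integer pairs `i j` (an optional third weight column is
#' ignored for graph construction); lines starting with `#` are skipped.
#' The graph is undirected and simple: duplicates and both orientations
#' collapse, self-loops are dropped with a message.
#'
#' @param path Edge-list text file, optionally gzipped.
#' @param n_vertices Optional total vertex count (isolated vertices beyond
#'   the largest id); defaults to max id + 1. If the file carries a
#'   `# n_vertices` header it is used when `n_vertices` is NULL.
#' @return A `sparse_graph`.
#' @export
load_edge_list <- function(path, n_vertices = NULL) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  hdr <- grep("^\\s*#", lines)
  if (is.null(n_vertices) && length(hdr)) {
    m <- regmatches(lines[hdr], regexpr("n_vertices\\s+\\d+", lines[hdr]))
    if (length(m <- unlist(m)))
      n_vertices <- as.integer(sub("n_vertices\\s+", "", m[1]))
  }
  body <- setdiff(seq_along(lines), hdr)
  body <- body[nzchar(trimws(lines[body]))]
  if (!length(body)) {
    if (is.null(n_vertices))
      stop("empty edge list and no n_vertices given")
    return(sparse_graph(integer(0), integer(0), n_vertices))
  }
  toks <- strsplit(trimws(lines[body]), "\\s+")
  nf <- lengths(toks)
  if (any(nf < 2L))
    stop("line ", body[which(nf < 2L)[1]], ": expected at least 2 fields")
  ii <- suppressWarnings(as.integer(vapply(toks, `[`, "", 1L)))
  jj <- suppressWarnings(as.integer(vapply(toks, `[`, "", 2L)))
  bad <- which(is.na(ii) | is.na(jj))
  if (length(bad))
    stop("line ", body[bad[1]], ": non-integer vertex id '",
         lines[body[bad[1]]], "'")
  neg <- which(ii < 0 | jj < 0)
  if (length(neg))
    stop("line ", body[neg[1]], ": negative vertex id")
  sparse_graph(ii, jj, n_vertices)
}

#' Per-vertex degree
#'
#' @param g A `sparse_graph`.
#' @return Integer vector of length `n_vertices`; sums to 2E.
#' @export
degrees <- function(g) {
  tabulate(c(g$i, g$j) + 1L, nbins = g$n_vertices)
}

#' Connected components with min-id labels
#'
#' Union-find with path halving. Two vertices share a label iff they are
#' connected; the label is the smallest vertex id in the component (so
#' isolated vertices label themselves), matching the convention of
#' distributed graph libraries whose saved component files identify each
#' component by its minimum member.
#'
#' @param g A `sparse_graph`.
#' @return Integer vector of 0-based component labels per vertex.
#' @export
connected_components <- function(g) {
  n <- g$n_vertices
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]   # path halving
      x <- parent[x]
    }
    x
  }
  ii <- g$i + 1L; jj <- g$j + 1L
  for (e in seq_along(ii)) {
    ra <- find(ii[e]); rb <- find(jj[e])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, 1L)
  # min member id per root; roots were always merged toward the smaller id,
  # so the root already is the minimum of its component
  root - 1L
}

#' Adjacency matrix of a sparse graph
#' @param g A `sparse_graph`.
#' @return Symmetric sparse 0/1 `Matrix::sparseMatrix`.
#' @keywords internal
adjacency <- function(g) {
  Matrix::sparseMatrix(i = c(g$i, g$j) + 1L, j = c(g$j, g$i) + 1L,
                       x = 1, dims = c(g$n_vertices, g$n_vertices))
}

#' Per-vertex triangle count
#'
#' Number of distinct 3-cliques through each vertex, computed from closed
#' walks of length 3 on the adjacency matrix: `diag(A^3) = 2 * tc`. The
#' total over vertices is three times the number of triangles in the graph.
#'
#' @param g A `sparse_graph` (simple; guaranteed by the constructors).
#' @return Integer vector of length `n_vertices`.
#' @export
triangle_counts <- function(g) {
  if (!n_edges(g)) return(integer(g$n_vertices))
  a <- adjacency(g)
  a2 <- a %*% a
  walks3 <- Matrix::rowSums(a2 * a)     # diag(A %*% A %*% A), elementwise
  as.integer(round(walks3 / 2))
}

#' Local clustering coefficient
#'
#' `cc[v] = tc[v] / (d[v] * (d[v] - 1) / 2)`: the fraction of a vertex's
#' neighbor pairs that are themselves connected. Vertices with degree < 2
#' have no neighbor pair; their coefficient is defined as 0.
#'
#' @param d Per-vertex degrees (from [degrees()]).
#' @param tc Per-vertex triangle counts (from [triangle_counts()]) of the
#'   same graph.
#' @return Numeric vector in \[0, 1\].
#' @export
local_clustering <- function(d, tc) {
  stopifnot(length(d) == length(tc))
  cc <- numeric(length(d))
  ok <- d >= 2L
  cc[ok] <- tc[ok] / (d[ok] * (d[ok] - 1) / 2)
  cc
}

#' PageRank by power iteration
#'
#' Each undirected edge is treated as two directed edges; dangling
#' (degree-0) vertices redistribute their mass uniformly. Iterates
#' `p' = (1 - damping)/N + damping * (A (p/d) + dangling_mass/N)` until the
#' L1 change drops below `tol`. Scores are normalized to sum to 1 (the
#' probability convention; some graph libraries leave scores summing to N).
#'
#' @param g A `sparse_graph`.
#' @param damping Damping factor in (0, 1), default 0.85.
#' @param tol L1 convergence tolerance, default 1e-8.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   last residual.
#' @return Numeric vector of PageRank scores summing to 1.
#' @export
pagerank <- function(g, damping = 0.85, tol = 1e-8, max_iter = 200L) {
  n <- g$n_vertices
  if (n == 0L) return(numeric(0))
  d <- degrees(g)
  a <- adjacency(g)
  dangling <- d == 0L
  dsafe <- pmax(d, 1L)
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    spread <- as.vector(a %*% (p / dsafe)) + sum(p[dangling]) / n
    p_new <- (1 - damping) / n + damping * spread
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      return(p / sum(p))
    }
  }
  stop(sprintf("PageRank did not converge in %d iterations (L1 residual %.3g)",
               max_iter, delta))
}

#' All per-vertex graph metrics in one table
#'
#' Degree, triangle count, local clustering coefficient, PageRank, and
#' connected-component label for every vertex.
#'
#' @param g A `sparse_graph`.
#' @param damping,tol,max_iter Passed to [pagerank()].
#' @return data.frame with columns `vertex`, `degree`, `tc`, `cc`,
#'   `pagerank`, `component` (vertex and component ids 0-based).
#' @export
vertex_metrics <- function(g, damping = 0.85, tol = 1e-8, max_iter = 200L) {
  d <- degrees(g)
  tc <- triangle_counts(g)
  data.frame(vertex = seq_len(g$n_vertices) - 1L,
             degree = d, tc = tc,
             cc = local_clustering(d, tc),
             pagerank = pagerank(g, damping, tol, max_iter),
             component = connected_components(g))
}

#' Edge-density statistic S and graph summary
#'
#' `S = log(E) / log(K)` with E the edge count and K = 2E/N the average
#' degree. S is invariant to the log base and is used to pick comparable
#' correlation thresholds across heterogeneous datasets; it is defined only
#' for E >= 1 and K > 1.
#'
#' @param E Edge count.
#' @param N Vertex count.
#' @return A `graph_summary`: list with `N`, `E`, `K`, `S`.
#' @export
edge_density_statistic <- function(E, N) {
  stopifnot(N >= 1)
  if (E < 1) stop("S is undefined for an empty graph (E = 0)")
  K <- 2 * E / N
  if (K <= 1)
    stop(sprintf("S is undefined for average degree K = %.4g <= 1", K))
  structure(list(N = N, E = E, K = K, S = log(E) / log(K)),
            class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat(sprintf("<graph_summary> N = %d, E = %d, K = %.4g, S = %.4g\n",
              as.integer(x$N), as.integer(x$E), x$K, x$S))
  invisible(x)
}

#' Automatic threshold selection for a target edge density
#'
#' Scans a descending grid of absolute-correlation thresholds and returns
#' the largest one whose edge-density statistic S meets `target_S`
#' (heterogeneous datasets thresholded at a fixed r produce graphs of very
#' different density; fixing S instead makes them comparable). Edge count
#' is non-increasing in the threshold, so the scan needs a single tile
#' pass: correlations are binned against the grid once.
#'
#' @param z A standardized `voxel_table`.
#' @param target_S Desired minimum S.
#' @param grid Descending thresholds in (0, 1).
#' @param plan Optional `tile_plan` for the scan.
#' @return List with `threshold` (selected grid value) and `summary` (the
#'   `graph_summary` at that threshold).
#' @export
select_threshold <- function(z, target_S,
                             grid = seq(0.95, 0.05, by = -0.05),
                             plan = NULL) {
  stopifnot(inherits(z, "voxel_table"))
  counts <- edge_counts_over_grid(z, plan, grid)
  n <- ncol(z$data)
  s_vals <- rep(NA_real_, length(grid))
  for (k in seq_along(grid)) {
    K <- 2 * counts[k] / n
    if (counts[k] >= 1 && K > 1) s_vals[k] <- log(counts[k]) / log(K)
  }
  ok <- which(!is.na(s_vals) & s_vals >= target_S)
  if (!length(ok)) {
    if (all(is.na(s_vals)))
      stop(sprintf("target S = %.4g unattainable: S undefined at every grid threshold",
                   target_S))
    stop(sprintf(
      "target S = %.4g unattainable on grid (attainable S in [%.4g, %.4g])",
      target_S, min(s_vals, na.rm = TRUE), max(s_vals, na.rm = TRUE)))
  }
  k <- ok[1]   # grid is descending: first hit is the largest threshold
  list(threshold = grid[k],
       summary = edge_density_statistic(counts[k], n))
}
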