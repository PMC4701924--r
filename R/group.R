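#' Stack multiple subjects into one group matrix
#'
#' Concatenates subjects' time points (rows) over a shared voxel set, the
#' union-of-rows reduction used for group-level decompositions. All tables
#' must share the same voxel index map (same mask); column v keeps meaning
#' voxel `index_map[v]` in every subject.
#'
#' @param tables List of `voxel_table`s with identical index maps.
#' @return A `group_matrix`: list with `data` ((sum of T_s) x V matrix),
#'   `subject_boundaries` (0-based row offsets, length subjects + 1),
#'   `index_map`, `grid_dims`.
#' @export
group_stack <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, TRUE, "voxel_table")))
  ref <- tables[[1]]$index_map
  for (s in seq_along(tables)) {
    im <- tables[[s]]$index_map
    if (!identical(im, ref)) {
      bad <- which(!(seq_along(ref) <= length(im) & im[seq_along(ref)] == ref))
      first <- if (length(im) != length(ref)) min(length(im), length(ref)) + 1L
               else which(im != ref)[1]
      stop(sprintf(
        "subject %d voxel map differs from subject 1 (first discrepancy at voxel position %d)",
        s, first))
    }
  }
  rows <- vapply(tables, function(t) nrow(t$data), 1L)
  structure(
    list(data = do.call(rbind, lapply(tables, `[[`, "data")),
         subject_boundaries = c(0L, cumsum(rows)),
         index_map = ref,
         grid_dims = tables[[1]]$grid_dims),
    class = "group_matrix")
}

#' @export
print.group_matrix <- function(x, ...) {
  cat(sprintf("<group_matrix> %d rows (%d subjects) x %d voxels\n",
              nrow(x$data), length(x$subject_boundaries) - 1L,
              ncol(x$data)))
  invisible(x)
}

#' Randomized truncated SVD of a group matrix
#'
#' Computes the top `k` singular triplets by randomized subspace iteration:
#' a Gaussian sketch of the row space is refined by alternating
#' multiplications with the matrix and its transpose (re-orthonormalized
#' each round), and the small projected problem is solved densely. Iteration
#' stops when the top-k Ritz values are stable to `tol` (relative, L-inf).
#' Only matrix products against the data are used, so the cost is
#' O(rows x V x (k + oversample)) per round and no V x V or rows x rows
#' dense matrix is ever formed.
#'
#' @param m A `group_matrix`, `voxel_table`, or plain numeric matrix.
#' @param k Number of singular triplets, `1 <= k <= min(dim)`.
#' @param center Subtract column means first (turning the decomposition
#'   into a PCA of the voxel time series); default FALSE.
#' @param oversample Extra sketch columns beyond k (default `max(10, k)`,
#'   capped by the small dimension).
#' @param tol Relative convergence tolerance on singular values (default 1e-12).
#' @param max_iter Subspace iteration cap.
#' @param seed Integer seed for the Gaussian sketch (local RNG state only).
#' @return List with `d` (k singular values, non-increasing), `u`
#'   (rows x k, orthonormal columns), `v` (V x k, orthonormal columns),
#'   and `iterations`.
#' @export
truncated_svd <- function(m, k, center = FALSE, oversample = NULL,
                          tol = 1e-12, max_iter = 500L, seed = 1L) {
  x <- if (is.matrix(m)) m
       else if (inherits(m, c("group_matrix", "voxel_table"))) m$data
       else stop("m must be a matrix, voxel_table or group_matrix")
  if (center) x <- sweep(x, 2L, colMeans(x), "-")
  nr <- nrow(x); nc <- ncol(x)
  if (k < 1 || k > min(nr, nc))
    stop(sprintf("k = %d out of range [1, %d]", k, min(nr, nc)))
  if (is.null(oversample)) oversample <- max(10L, k)
  p <- min(k + oversample, min(nr, nc))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  omega <- matrix(stats::rnorm(nc * p), nc, p)
  q <- qr.Q(qr(x %*% omega))
  d_prev <- rep(Inf, k)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    q <- qr.Q(qr(crossprod(x, q)))      # V x p
    q <- qr.Q(qr(x %*% q))              # rows x p
    b <- crossprod(q, x)                # p x V, small first dimension
    d_now <- svd(b, nu = 0, nv = 0)$d[seq_len(k)]
    if (max(abs(d_now - d_prev) / pmax(d_now, .Machine$double.eps)) < tol ||
        iterations >= max_iter)
      break
    d_prev <- d_now
  }
  sb <- svd(b, nu = p, nv = p)
  u <- q %*% sb$u[, seq_len(k), drop = FALSE]
  v <- sb$v[, seq_len(k), drop = FALSE]
  d <- sb$d[seq_len(k)]
  # deterministic sign: largest-magnitude loading of each right vector >= 0
  for (c in seq_len(k)) {
    piv <- which.max(abs(v[, c]))
    if (v[piv, c] < 0) { v[, c] <- -v[, c]; u[, c] <- -u[, c] }
  }
  list(d = d, u = u, v = v, iterations = iterations)
}
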