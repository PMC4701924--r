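#' Standardize voxel time series
#'
#' Centers each column to mean 0 and scales non-constant columns to sample
#' standard deviation 1 (denominator T-1). After this step the Pearson
#' correlation between two voxels is the plain dot product of their columns
#' divided by T-1, which is what lets the tiled correlation run as dense
#' matrix products. Zero-variance (constant) columns are set to all-zero and
#' their positions recorded: their correlation with everything is defined as
#' 0, never NaN.
#'
#' @param table A `voxel_table` with at least 2 time points.
#' @return The standardized `voxel_table`; attribute `zero_variance` holds
#'   the 1-based column positions of constant voxels (integer(0) if none),
#'   attribute `standardized` is TRUE.
#' @export
standardize <- function(table) {
  stopifnot(inherits(table, "voxel_table"))
  x <- table$data
  if (nrow(x) < 2L) stop("need at least 2 time points to standardize")
  mu <- colMeans(x)
  x <- sweep(x, 2L, mu, "-")
  sd <- sqrt(colSums(x^2) / (nrow(x) - 1))
  zv <- which(sd == 0)
  sd[zv] <- 1
  x <- sweep(x, 2L, sd, "/")
  if (length(zv)) x[, zv] <- 0
  table$data <- x
  attr(table, "zero_variance") <- as.integer(zv)
  attr(table, "standardized") <- TRUE
  table
}

#' Dense memory footprint of the full correlation matrix
#'
#' Bytes needed to hold the dense V x V voxelwise correlation matrix
#' (symmetry not exploited). At the native resolution of a typical
#' whole-brain mask (~228,200 voxels) this is ~388 GiB in double precision —
#' the quantity that motivates tiling instead of materializing the matrix.
#'
#' @param n_voxels Number of in-mask voxels.
#' @param bytes_per_element Storage bytes per value (8 for double).
#' @return Footprint in bytes (double, exact for realistic sizes).
#' @export
memory_footprint <- function(n_voxels, bytes_per_element = 8) {
  stopifnot(n_voxels >= 1)
  as.double(n_voxels)^2 * bytes_per_element
}

#' Plan row-block tiles of the correlation matrix under a byte budget
#'
#' Partitions the V x V correlation matrix into contiguous row blocks, each
#' a (height x V) dense tile no larger than `tile_budget_bytes`. Block
#' height is `floor(budget / (V * bytes))`; the last block may be shorter.
#'
#' @param n_voxels Number of voxels V.
#' @param bytes_per_element Bytes per matrix element (8 for double).
#' @param tile_budget_bytes Maximum bytes one tile may occupy; must fit at
#'   least one row.
#' @return A `tile_plan`: list with `n_voxels`, `bytes_per_element`,
#'   `tile_budget_bytes`, and `blocks`, a data.frame of 0-based half-open
#'   row ranges `[start, end)`.
#' @export
plan_tiles <- function(n_voxels, bytes_per_element = 8,
                       tile_budget_bytes) {
  n_voxels <- as.double(n_voxels)
  row_bytes <- n_voxels * bytes_per_element
  if (tile_budget_bytes < row_bytes)
    stop(sprintf(
      "tile budget %.0f bytes cannot hold one matrix row (%.0f bytes)",
      tile_budget_bytes, row_bytes))
  height <- floor(tile_budget_bytes / row_bytes)
  starts <- seq(0, n_voxels - 1, by = height)
  ends <- pmin(starts + height, n_voxels)
  structure(
    list(n_voxels = n_voxels, bytes_per_element = bytes_per_element,
         tile_budget_bytes = tile_budget_bytes,
         blocks = data.frame(start = starts, end = ends)),
    class = "tile_plan")
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf(
    "<tile_plan> %d blocks over %.0f voxels (budget %.3g bytes, height %d)\n",
    nrow(x$blocks), x$n_voxels, x$tile_budget_bytes,
    as.integer(x$blocks$end[1] - x$blocks$start[1])))
  invisible(x)
}

check_block <- function(block, n_voxels) {
  if (block[1] < 0 || block[2] > n_voxels || block[1] >= block[2])
    stop("block row range out of bounds")
}

#' One row-block tile of the Pearson correlation matrix
#'
#' Computes rows `[start, end)` of the full correlation matrix from a
#' standardized table: `out[a, b] = sum_t z[t, start+a] * z[t, b] / (T-1)`,
#' clipped to [-1, 1]. Rows/columns of zero-variance voxels are exactly 0.
#'
#' Each row is computed as one matrix-vector product against the full
#' table, never as a blocked matrix-matrix product: row i's floating-point
#' result then depends only on i, so assembled matrices and streamed edge
#' lists are bit-identical across tile plans (blocked BLAS kernels change
#' summation order with the tile height, which would break that contract).
#'
#' @param z A standardized `voxel_table` (see [standardize()]).
#' @param block Length-2 vector, 0-based half-open row range `c(start, end)`.
#' @return Dense (end-start) x V matrix of correlations.
#' @export
correlation_tile <- function(z, block) {
  stopifnot(inherits(z, "voxel_table"))
  if (!isTRUE(attr(z, "standardized")))
    stop("correlation_tile requires a standardized table")
  check_block(block, ncol(z$data))
  cols <- (block[1] + 1L):block[2]
  r <- matrix(0, length(cols), ncol(z$data))
  for (a in seq_along(cols))
    r[a, ] <- crossprod(z$data[, cols[a]], z$data)
  r <- r / (nrow(z$data) - 1)
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' One row-block tile of the column cosine-similarity matrix
#'
#' `out[a, b] = <col_a, col_b> / (||col_a|| * ||col_b||)`; entries involving
#' an all-zero column are 0 by convention. On a standardized table this
#' equals the Pearson correlation.
#'
#' @param table A `voxel_table` (standardization not required).
#' @param block 0-based half-open row range `c(start, end)`.
#' @return Dense (end-start) x V matrix of cosine similarities.
#' @export
column_cosine_tile <- function(table, block) {
  stopifnot(inherits(table, "voxel_table"))
  check_block(block, ncol(table$data))
  x <- table$data
  nrm <- sqrt(colSums(x^2))
  safe <- ifelse(nrm == 0, 1, nrm)
  cols <- (block[1] + 1L):block[2]
  out <- crossprod(x[, cols, drop = FALSE], x) / outer(safe[cols], safe)
  if (any(nrm == 0)) {
    out[, nrm == 0] <- 0
    out[nrm[cols] == 0, ] <- 0
  }
  out
}

#' Stream threshold-surviving correlations to a sparse edge list
#'
#' Runs the tile loop over a `tile_plan`, keeping exactly the voxel pairs
#' i < j with `|r| >= threshold`. Only one tile is dense in memory at a
#' time, so the full V x V matrix is never materialized. The output is
#' independent of the tile plan (same pairs, same floating-point values).
#' The signed correlation is stored even though thresholding uses |r|;
#' downstream graph metrics use the unweighted graph.
#'
#' @param z A standardized `voxel_table`.
#' @param plan A `tile_plan` from [plan_tiles()], or NULL for a single tile.
#' @param threshold Absolute-correlation threshold in (0, 1); comparison is
#'   closed (`>=`).
#' @return A `weighted_edge_list`: data.frame with columns `i`, `j` (0-based
#'   vertex ids, i < j) and `r`, ordered by (i, j); attributes `n_vertices`
#'   and `threshold`.
#' @export
threshold_stream <- function(z, plan = NULL, threshold) {
  stopifnot(inherits(z, "voxel_table"))
  if (!isTRUE(attr(z, "standardized")))
    stop("threshold_stream requires a standardized table")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  v <- ncol(z$data)
  if (is.null(plan))
    plan <- plan_tiles(v, 8, v * v * 8 + 8)
  if (plan$n_voxels != v)
    stop("tile plan voxel count does not match table")
  parts <- vector("list", nrow(plan$blocks))
  for (b in seq_len(nrow(plan$blocks))) {
    blk <- c(plan$blocks$start[b], plan$blocks$end[b])
    tile <- correlation_tile(z, blk)
    hit <- which(abs(tile) >= threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      gi <- blk[1] + hit[, 1L] - 1L   # global 0-based row id
      gj <- hit[, 2L] - 1L
      keep <- gi < gj                 # upper triangle once, no diagonal
      if (any(keep))
        parts[[b]] <- data.frame(i = gi[keep], j = gj[keep],
                                 r = tile[hit[keep, , drop = FALSE]])
    }
  }
  edges <- do.call(rbind, parts)
  if (is.null(edges))
    edges <- data.frame(i = integer(0), j = integer(0), r = double(0))
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, n_vertices = v, threshold = threshold,
            class = c("weighted_edge_list", "data.frame"))
}

#' Write an edge list as plain text
#'
#' One edge per line, `i j r` separated by single spaces, 0-based vertex
#' ids; `#` header lines record the vertex count, threshold and source.
#' `graphx_compat = TRUE` drops the weight column, producing the two-column
#' dialect accepted by standard graph edge-list loaders.
#'
#' @param edges A `weighted_edge_list` (or data.frame with i, j and
#'   optionally r).
#' @param path Output path; a `.gz` suffix gzip-compresses.
#' @param graphx_compat Write `i j` only.
#' @param source Provenance string for the header.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path, graphx_compat = FALSE,
                            source = NA_character_) {
  n_vertices <- attr(edges, "n_vertices")
  threshold <- attr(edges, "threshold")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  hdr <- c(sprintf("# n_vertices %d", as.integer(n_vertices)),
           if (!is.null(threshold)) sprintf("# threshold %.17g", threshold),
           if (!is.na(source)) paste("# source", source),
           "# vertex ids: 0-based x-fastest linear indices of the mask grid")
  writeLines(hdr, con)
  if (nrow(edges)) {
    lines <- if (graphx_compat || is.null(edges$r))
      paste(edges$i, edges$j)
    else
      paste(edges$i, edges$j, formatC(edges$r, format = "g", digits = 17))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Count edges over a descending threshold grid with one tile pass
#'
#' For each grid value t, the number of pairs i < j with |r| >= t. Shared by
#' [select_threshold()]; runs the tile loop once and bins |r| against the
#' grid, so the cost is one pass regardless of grid length.
#'
#' @param z Standardized `voxel_table`.
#' @param plan `tile_plan` or NULL (single tile).
#' @param grid Descending vector of thresholds in (0, 1).
#' @return Integer vector of edge counts aligned with `grid`.
#' @keywords internal
edge_counts_over_grid <- function(z, plan = NULL, grid) {
  stopifnot(all(diff(grid) < 0), all(grid > 0), all(grid < 1))
  v <- ncol(z$data)
  if (is.null(plan)) plan <- plan_tiles(v, 8, v * v * 8 + 8)
  asc <- rev(grid)                       # ascending for findInterval
  counts <- integer(length(grid))
  for (b in seq_len(nrow(plan$blocks))) {
    blk <- c(plan$blocks$start[b], plan$blocks$end[b])
    tile <- abs(correlation_tile(z, blk))
    rows <- (blk[1] + 1L):blk[2]
    ut <- tile[outer(blk[1] + seq_along(rows) - 1L, 0:(v - 1L), "<")]
    # bin k means |r| >= asc[k] but < asc[k+1]
    bins <- findInterval(ut, asc)
    tab <- tabulate(bins, nbins = length(asc))
    counts <- counts + rev(cumsum(rev(tab)))
  }
  rev(counts)  # back to descending-grid order? counts computed ascending
}
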