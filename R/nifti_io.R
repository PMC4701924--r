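#' Linearize 3D voxel coordinates
#'
#' Maps 0-based grid coordinates to a 0-based linear index with the first
#' axis varying fastest: `x + dx * (y + dy * z)`. This is the voxel/vertex
#' identity used throughout the package: the vertex ids of the connectivity
#' graph are exactly these linear indices restricted to the mask.
#'
#' @param x,y,z Integer coordinates, 0-based, vectorized.
#' @param grid_dims Integer vector of length 3 (grid extents).
#' @return 0-based integer linear index (double to avoid overflow on
#'   large grids).
#' @seealso [unravel_index()] for the inverse.
#' @export
linear_index <- function(x, y, z, grid_dims) {
  grid_dims <- as.double(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 1))
    stop("grid_dims must be 3 positive integers")
  if (any(x < 0 | x >= grid_dims[1]) || any(y < 0 | y >= grid_dims[2]) ||
      any(z < 0 | z >= grid_dims[3]))
    stop("coordinate out of range for grid_dims")
  x + grid_dims[1] * (y + grid_dims[2] * z)
}

#' Invert a linear voxel index to 3D coordinates
#'
#' @param idx 0-based linear index (vectorized).
#' @param grid_dims Integer vector of length 3.
#' @return Matrix with columns x, y, z (0-based).
#' @export
unravel_index <- function(idx, grid_dims) {
  grid_dims <- as.double(grid_dims)
  if (any(idx < 0 | idx >= prod(grid_dims)))
    stop("linear index out of range for grid_dims")
  x <- idx %% grid_dims[1]
  y <- (idx %/% grid_dims[1]) %% grid_dims[2]
  z <- idx %/% (grid_dims[1] * grid_dims[2])
  cbind(x = x, y = y, z = z)
}

#' Load a 3D binary brain mask
#'
#' Reads a 3D NIfTI image and binarizes it as `value > 0` (standard binary
#' masks store 1.0 in-brain; any nonzero voxel counts as in-mask). An empty
#' mask is an error: downstream stages need at least one voxel.
#'
#' @param mask_path Path to a 3D NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return A `brain_mask` object: list with `grid_dims`, `affine` (4x4 xform
#'   matrix, qform preferred), `in_mask` (logical array), `n_voxels`, and
#'   `index_map` (0-based x-fastest linear indices of in-mask voxels,
#'   strictly increasing).
#' @export
read_brain_mask <- function(mask_path) {
  img <- RNifti::readNifti(mask_path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(img[, , , 1L], dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) < 3L)
    d <- c(d, rep(1L, 3L - length(d)))   # trailing singleton dims elided
  if (length(d) != 3L)
    stop("mask must be a 3D NIfTI image, got ", length(d), " dimensions")
  in_mask <- array(as.array(img) > 0, dim = d)
  n <- sum(in_mask)
  if (n < 1L) stop("mask is empty: no voxel has a positive value")
  structure(
    list(grid_dims = as.integer(d),
         affine = unclass(RNifti::xform(img, useQuaternionFirst = TRUE)),
         in_mask = in_mask,
         n_voxels = as.integer(n),
         # which() walks the array first-axis-fastest, so these 0-based
         # positions are exactly linear_index() of the in-mask voxels.
         index_map = which(in_mask) - 1L),
    class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> grid %s, %d in-mask voxels (%.1f%%)\n",
              paste(x$grid_dims, collapse = "x"), x$n_voxels,
              100 * x$n_voxels / prod(x$grid_dims)))
  invisible(x)
}

#' Construct a voxel table
#'
#' Internal constructor for the time-by-voxel matrix container. Rows are
#' time points (volumes), columns are in-mask voxel time series; `index_map`
#' carries the 0-based linear grid index of each column.
#'
#' @param data T x V numeric matrix.
#' @param index_map 0-based linear voxel indices, strictly increasing.
#' @param grid_dims Grid extents of the source image.
#' @param tr_seconds Optional repetition time.
#' @param source_path Provenance string.
#' @return A `voxel_table` object.
#' @keywords internal
voxel_table <- function(data, index_map, grid_dims, tr_seconds = NA_real_,
                        source_path = NA_character_) {
  stopifnot(is.matrix(data), ncol(data) == length(index_map))
  if (is.unsorted(index_map, strictly = TRUE) && length(index_map) > 1L)
    stop("index_map must be strictly increasing")
  structure(
    list(data = data, index_map = as.integer(index_map),
         grid_dims = as.integer(grid_dims),
         tr_seconds = tr_seconds, source_path = source_path),
    class = "voxel_table")
}

#' @export
print.voxel_table <- function(x, ...) {
  cat(sprintf("<voxel_table> %d time points x %d voxels (grid %s)\n",
              nrow(x$data), ncol(x$data), paste(x$grid_dims, collapse = "x")))
  invisible(x)
}

#' Read masked 4D BOLD data in bounded-memory volume chunks
#'
#' Extracts the in-mask voxel time series of a 4D NIfTI image into a
#' time-by-voxel matrix. Volumes are read in chunks of at most
#' `chunk_volumes` at a time so the high-water memory mark is bounded by
#' one chunk plus the output matrix; the result is bit-identical for every
#' chunk size. Intensities are promoted to 64-bit doubles, with NIfTI
#' scl_slope/scl_inter scaling applied by the reader.
#'
#' @param image_path Path to a 4D NIfTI-1 file (optionally gzipped).
#' @param mask_path Path to a 3D binary mask on the same grid, or a
#'   `brain_mask` object.
#' @param chunk_volumes Positive integer, number of volumes per read.
#' @return A `voxel_table` (see [voxel_table()]); `tr_seconds` is taken from
#'   the image pixdim when available.
#' @examples
#' \dontrun{
#' tab <- read_masked("bold.nii.gz", "mask.nii.gz", chunk_volumes = 32)
#' }
#' @export
read_masked <- function(image_path, mask_path, chunk_volumes = 32L) {
  chunk_volumes <- as.integer(chunk_volumes)
  if (is.na(chunk_volumes) || chunk_volumes < 1L)
    stop("chunk_volumes must be a positive integer")
  mask <- if (inherits(mask_path, "brain_mask")) mask_path
          else read_brain_mask(mask_path)

  hdr <- RNifti::niftiHeader(image_path)
  nd <- hdr$dim[1L]
  if (nd != 4L)
    stop("image must be 4D NIfTI-1, got ", nd, " dimensions")
  d <- hdr$dim[2:5]
  if (!identical(as.integer(d[1:3]), mask$grid_dims))
    stop(sprintf("grid mismatch: image %s vs mask %s",
                 paste(d[1:3], collapse = "x"),
                 paste(mask$grid_dims, collapse = "x")))
  n_t <- as.integer(d[4])
  keep <- mask$index_map + 1L   # 1-based linear offsets within one volume

  out <- matrix(NA_real_, nrow = n_t, ncol = mask$n_voxels)
  vol_len <- prod(mask$grid_dims)
  for (start in seq(1L, n_t, by = chunk_volumes)) {
    vols <- start:min(start + chunk_volumes - 1L, n_t)
    chunk <- RNifti::readNifti(image_path, volumes = vols)
    chunk <- matrix(as.double(chunk), nrow = vol_len)
    out[vols, ] <- t(chunk[keep, , drop = FALSE])
  }
  tr <- suppressWarnings(as.double(hdr$pixdim[5L]))
  voxel_table(out, mask$index_map, mask$grid_dims,
              tr_seconds = if (is.finite(tr) && tr > 0) tr else NA_real_,
              source_path = as.character(image_path))
}

#' Write a per-voxel metric vector as a 3D NIfTI map
#'
#' Places one value per in-mask voxel into the mask geometry (affine
#' preserved) and `fill_value` elsewhere, then writes a 3D NIfTI-1 file.
#' With `datatype = "float"` values are stored in 32-bit floats (the
#' default, sufficient for metric maps); `"double"` keeps full precision.
#'
#' @param values Numeric vector, one value per in-mask voxel.
#' @param mask A `brain_mask`.
#' @param out_path Output path (`.nii` or `.nii.gz`).
#' @param fill_value Value written outside the mask (default 0).
#' @param datatype `"float"` or `"double"` storage.
#' @param reference Optional NIfTI image or path whose header supplies the
#'   affine; defaults to the mask's affine.
#' @return `out_path`, invisibly.
#' @export
write_metric_map <- function(values, mask, out_path, fill_value = 0,
                             datatype = c("float", "double"),
                             reference = NULL) {
  datatype <- match.arg(datatype)
  if (length(values) != mask$n_voxels)
    stop(sprintf("metric length %d does not match mask voxel count %d",
                 length(values), mask$n_voxels))
  vol <- array(as.double(fill_value), dim = mask$grid_dims)
  vol[mask$index_map + 1L] <- as.double(values)
  img <- RNifti::asNifti(vol, reference = reference)
  img <- RNifti::`sform<-`(img, structure(mask$affine, code = 2L))
  RNifti::writeNifti(img, out_path, datatype = datatype)
  invisible(out_path)
}

#' Extract in-mask values from a 3D metric map
#'
#' Inverse of [write_metric_map()]: reads a 3D NIfTI file and returns the
#' values at in-mask voxels in index_map order.
#'
#' @param map_path Path to a 3D NIfTI file.
#' @param mask A `brain_mask` on the same grid.
#' @return Numeric vector of length `mask$n_voxels`.
#' @export
read_metric_map <- function(map_path, mask) {
  img <- RNifti::readNifti(map_path)
  d <- dim(img)
  if (length(d) != 3L || !identical(as.integer(d), mask$grid_dims))
    stop("metric map grid does not match mask grid")
  as.double(img)[mask$index_map + 1L]
}
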