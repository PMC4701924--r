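#' Specify a planted-community BOLD simulation
#'
#' Latent-factor model for synthetic resting-state data: every voxel of
#' community c follows `a * L_c(t) + sigma * eps(t)` with independent
#' standard-normal community signal L_c and voxel noise eps, so the expected
#' correlation is `a^2 / (a^2 + sigma^2)` within a community and 0 between
#' communities and for pure-noise voxels. The closed form makes every
#' pipeline stage checkable against ground truth, and generation is
#' O(V x T) rather than requiring a V x V covariance factorization.
#'
#' @param grid_dims Grid extents (3 integers). Default `c(10, 5, 5)`.
#' @param n_volumes Number of time points T. Default 400.
#' @param communities Either an integer vector of community sizes (voxels
#'   assigned as contiguous blocks in linear-index order, so metric maps
#'   are visually checkable) or a list of disjoint 0-based voxel index
#'   vectors. Default `rep(50, 5)`.
#' @param amplitude Community signal amplitude a >= 0. Default 3.
#' @param noise_sd Noise standard deviation sigma > 0. Default 1.
#' @param seed RNG seed.
#' @return A `community_spec` list; `$rho_within` and `$rho_between` hold
#'   the expected correlations.
#' @export
community_spec <- function(grid_dims = c(10L, 5L, 5L), n_volumes = 400L,
                           communities = rep(50L, 5L), amplitude = 3,
                           noise_sd = 1, seed = 42L) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 1L),
            n_volumes >= 2L, amplitude >= 0, noise_sd > 0)
  n_vox <- prod(grid_dims)
  if (!is.list(communities)) {
    sizes <- as.integer(communities)
    stopifnot(all(sizes >= 1L), sum(sizes) <= n_vox)
    ends <- cumsum(sizes)
    communities <- lapply(seq_along(sizes), function(c)
      (c(0L, ends)[c]):(ends[c] - 1L))
  } else {
    communities <- lapply(communities, as.integer)
    all_idx <- unlist(communities)
    if (anyDuplicated(all_idx))
      stop("communities must be disjoint voxel sets")
    if (length(all_idx) && (min(all_idx) < 0 || max(all_idx) >= n_vox))
      stop("community voxel index out of grid range")
  }
  structure(
    list(grid_dims = grid_dims, n_volumes = as.integer(n_volumes),
         communities = communities, amplitude = amplitude,
         noise_sd = noise_sd, seed = as.integer(seed),
         rho_within = amplitude^2 / (amplitude^2 + noise_sd^2),
         rho_between = 0),
    class = "community_spec")
}

#' Generate a 4D BOLD image + mask with planted community structure
#'
#' Writes a NIfTI-1 image/mask pair realizing a [community_spec()]: voxels
#' in a community share a latent signal (scaled by `amplitude`) plus
#' independent Gaussian noise; voxels outside every community are pure
#' noise. The mask covers the whole grid. Output is reproducible: the same
#' spec (including seed) yields bit-identical files.
#'
#' @param spec A `community_spec`.
#' @param out_prefix Path prefix; writes `<prefix>bold.nii.gz` and
#'   `<prefix>mask.nii.gz`.
#' @return List with `image_path`, `mask_path`, and `truth` (the expected
#'   within/between correlations and the community voxel sets).
#' @export
generate_bold <- function(spec, out_prefix = tempfile("sim_")) {
  stopifnot(inherits(spec, "community_spec"))
  n_vox <- prod(spec$grid_dims)
  t_len <- spec$n_volumes

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  data <- matrix(stats::rnorm(t_len * n_vox, sd = spec$noise_sd),
                 nrow = t_len, ncol = n_vox)
  for (c in seq_along(spec$communities)) {
    latent <- stats::rnorm(t_len)
    cols <- spec$communities[[c]] + 1L
    data[, cols] <- data[, cols] + spec$amplitude * latent
  }

  arr <- array(t(data), dim = c(spec$grid_dims, t_len))
  image_path <- paste0(out_prefix, "bold.nii.gz")
  mask_path <- paste0(out_prefix, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), image_path, datatype = "double")
  RNifti::writeNifti(RNifti::asNifti(array(1, dim = spec$grid_dims)),
                     mask_path, datatype = "uint8")
  list(image_path = image_path, mask_path = mask_path,
       truth = list(rho_within = spec$rho_within,
                    rho_between = spec$rho_between,
                    communities = spec$communities))
}

#' Generate the linear-index test-pattern image
#'
#' 4D image whose intensity encodes position and time:
#' `value(x, y, z, t) = linear_index(x, y, z) * 1000 + t` (t 0-based).
#' Reading it back through any masked/chunked path must reproduce
#' `index_map[v] * 1000 + t` exactly, which pins down voxel ordering,
#' chunk assembly and index bookkeeping in one shot.
#'
#' @param grid_dims Grid extents (keep small; values grow as 1000 x voxels).
#' @param n_volumes Number of volumes T.
#' @param out_path Output NIfTI path.
#' @return `out_path`, invisibly.
#' @export
generate_index_image <- function(grid_dims, n_volumes,
                                 out_path = tempfile(fileext = ".nii.gz")) {
  grid_dims <- as.integer(grid_dims)
  n_vox <- prod(grid_dims)
  idx <- seq_len(n_vox) - 1                 # x-fastest == R array order
  arr <- array(0, dim = c(grid_dims, n_volumes))
  for (t in seq_len(n_volumes))
    arr[, , , t] <- idx * 1000 + (t - 1)
  RNifti::writeNifti(RNifti::asNifti(arr), out_path, datatype = "double")
  invisible(out_path)
}
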