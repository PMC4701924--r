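#' Run the full single-subject connectivity pipeline
#'
#' read -> standardize -> tiled threshold stream -> graph metrics -> maps:
#' extracts the masked BOLD time series, builds the thresholded
#' correlation graph under the tile budget, computes all voxelwise graph
#' metrics, and writes the edge list, a per-vertex metrics CSV, and one
#' NIfTI map per metric. Exactly one of `threshold` / `target_S` selects
#' the graph construction rule.
#'
#' @param image_path 4D BOLD NIfTI path.
#' @param mask_path 3D mask NIfTI path (or `brain_mask`).
#' @param out_prefix Prefix for all outputs (may include a directory).
#' @param threshold Absolute-correlation threshold in (0, 1), or NULL.
#' @param target_S Target edge-density statistic, or NULL; selected via
#'   [select_threshold()] on `s_grid`.
#' @param s_grid Descending threshold grid for target_S mode.
#' @param tile_budget_bytes Byte budget per correlation tile.
#' @param chunk_volumes Volumes per read chunk.
#' @param damping,pr_tol,pr_max_iter PageRank settings.
#' @param write_maps Write per-metric NIfTI maps (degree, cc, pagerank,
#'   component).
#' @return The run manifest (list): paths and md5 checksums of every
#'   artifact, the `graph_summary` (N, E, K, S when defined), the applied
#'   threshold, and zero-variance voxel count. Also written as
#'   `<prefix>manifest.json`.
#' @export
run_subject_pipeline <- function(image_path, mask_path, out_prefix,
                                 threshold = NULL, target_S = NULL,
                                 s_grid = seq(0.95, 0.05, by = -0.05),
                                 tile_budget_bytes = 512 * 1024^2,
                                 chunk_volumes = 32L,
                                 damping = 0.85, pr_tol = 1e-8,
                                 pr_max_iter = 200L,
                                 write_maps = TRUE) {
  if (is.null(threshold) == is.null(target_S))
    stop("set exactly one of threshold / target_S")
  mask <- if (inherits(mask_path, "brain_mask")) mask_path
          else read_brain_mask(mask_path)
  tab <- read_masked(image_path, mask, chunk_volumes = chunk_volumes)
  z <- standardize(tab)
  plan <- plan_tiles(ncol(z$data), 8, max(tile_budget_bytes,
                                          ncol(z$data) * 8))
  if (is.null(threshold)) {
    sel <- select_threshold(z, target_S, grid = s_grid, plan = plan)
    threshold <- sel$threshold
  }
  edges <- threshold_stream(z, plan, threshold)

  g <- sparse_graph(edges$i, edges$j, n_vertices = ncol(z$data))
  metrics <- vertex_metrics(g, damping, pr_tol, pr_max_iter)
  metrics$voxel_index <- z$index_map

  edge_path <- paste0(out_prefix, "edges.txt.gz")
  write_edge_list(edges, edge_path, source = basename(image_path))
  csv_path <- paste0(out_prefix, "metrics.csv")
  utils::write.csv(metrics, csv_path, row.names = FALSE)
  artifacts <- c(edges = edge_path, metrics = csv_path)

  if (write_maps) {
    for (col in c("degree", "cc", "pagerank", "component")) {
      p <- paste0(out_prefix, col, ".nii.gz")
      write_metric_map(metrics[[col]], mask, p,
                       datatype = if (col %in% c("cc", "pagerank"))
                         "double" else "float")
      artifacts[[paste0("map_", col)]] <- p
    }
  }

  E <- nrow(edges)
  summary <- tryCatch(edge_density_statistic(E, ncol(z$data)),
                      error = function(e)
                        list(N = ncol(z$data), E = E,
                             K = 2 * E / ncol(z$data), S = NA_real_))
  manifest <- list(
    image = as.character(image_path),
    threshold = threshold,
    n_vertices = ncol(z$data),
    n_edges = E,
    avg_degree = summary$K,
    S = summary$S,
    n_zero_variance = length(attr(z, "zero_variance")),
    n_nonsingleton_components =
      length(unique(metrics$component[metrics$degree > 0])),
    artifacts = as.list(artifacts),
    checksums = as.list(tools::md5sum(unname(unlist(artifacts)))))
  jsonlite::write_json(manifest, paste0(out_prefix, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the pipeline for several subjects, with optional group SVD
#'
#' Each subject is processed independently with [run_subject_pipeline()]
#' (identical outputs to a single-subject run), then the subjects' voxel
#' tables are stacked over the shared mask and a truncated SVD of the group
#' matrix is computed. Right singular vectors can be written as NIfTI maps,
#' one per component.
#'
#' @param image_paths Character vector of 4D BOLD paths.
#' @param mask_path Shared mask path or `brain_mask` (all subjects must
#'   share one grid/mask).
#' @param out_prefix Output prefix; subject outputs get `sub<k>_` inserted.
#' @param svd_k Components for the group SVD; 0 skips it.
#' @param center Column-center before the SVD (PCA).
#' @param seed Seed for the randomized SVD sketch.
#' @param ... Passed to [run_subject_pipeline()] (threshold/target_S etc.).
#' @return List with `subjects` (per-subject manifests) and `svd`
#'   (singular values + artifact paths, or NULL).
#' @export
run_group_pipeline <- function(image_paths, mask_path, out_prefix,
                               svd_k = 0L, center = FALSE, seed = 1L, ...) {
  for (p in image_paths)
    if (!file.exists(p)) stop("missing subject input: ", p)
  mask <- if (inherits(mask_path, "brain_mask")) mask_path
          else read_brain_mask(mask_path)
  manifests <- vector("list", length(image_paths))
  for (s in seq_along(image_paths))
    manifests[[s]] <- run_subject_pipeline(
      image_paths[s], mask, paste0(out_prefix, "sub", s, "_"), ...)

  svd_out <- NULL
  if (svd_k >= 1L) {
    tables <- lapply(image_paths, read_masked, mask_path = mask)
    gm <- group_stack(tables)
    dec <- truncated_svd(gm, k = svd_k, center = center, seed = seed)
    sv_path <- paste0(out_prefix, "singular_values.csv")
    utils::write.csv(
      data.frame(component = seq_len(svd_k), singular_value = dec$d),
      sv_path, row.names = FALSE)
    map_paths <- character(0)
    for (c in seq_len(svd_k)) {
      p <- paste0(out_prefix, sprintf("component%02d.nii.gz", c))
      write_metric_map(dec$v[, c], mask, p, datatype = "double")
      map_paths <- c(map_paths, p)
    }
    svd_out <- list(d = dec$d, singular_values_csv = sv_path,
                    component_maps = map_paths)
  }
  list(subjects = manifests, svd = svd_out)
}
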