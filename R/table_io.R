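#' Write a voxel table as plain text
#'
#' Tab-separated values, one volume per row, voxels in columns; `#` header
#' lines carry a JSON metadata record (grid dims, index map, TR, source).
#' Values are printed with 17 significant digits so doubles round-trip
#' exactly. Open and diffable; use a `.gz` suffix for compression.
#'
#' @param table A `voxel_table`.
#' @param path Output path (`.tsv` or `.tsv.gz`).
#' @return `path`, invisibly.
#' @export
write_voxel_table <- function(table, path) {
  stopifnot(inherits(table, "voxel_table"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  meta <- list(grid_dims = table$grid_dims, index_map = table$index_map,
               tr_seconds = table$tr_seconds,
               source_path = table$source_path)
  writeLines(paste("# voxel_table",
                   jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
             con)
  utils::write.table(
    format(table$data, digits = 17, scientific = TRUE, trim = TRUE),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a voxel table written by [write_voxel_table()]
#'
#' @param path Path to the `.tsv`/`.tsv.gz` file.
#' @return A `voxel_table`.
#' @export
read_voxel_table <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  hdr <- lines[startsWith(lines, "# voxel_table")]
  if (!length(hdr)) stop("not a voxel_table file: missing header")
  meta <- jsonlite::fromJSON(sub("^# voxel_table ", "", hdr[1]))
  body <- lines[!startsWith(lines, "#")]
  data <- matrix(scan(text = body, quiet = TRUE),
                 nrow = length(body), byrow = TRUE)
  voxel_table(data, meta$index_map, meta$grid_dims,
              tr_seconds = if (is.null(meta$tr_seconds)) NA_real_
                           else meta$tr_seconds,
              source_path = if (is.null(meta$source_path)) NA_character_
                            else meta$source_path)
}
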