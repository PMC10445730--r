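#' Write and read 3-channel stacks as multi-page TIFF
#'
#' Stacks are stored as 16-bit multi-page TIFF with pages ordered z within
#' channel (channel order dna, probe, lamin) plus a JSON sidecar
#' (`<file>.json`) carrying the channel roles, shape and per-axis voxel sizes
#' in micrometres. Counts above 65535 are clipped; fractional counts are
#' quantized to the 16-bit grid.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path; the sidecar is written next to it.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- list()
  for (ch in names(stack$channels)) {
    vol <- stack$channels[[ch]]
    for (z in seq_len(dim(vol)[1])) {
      pages[[length(pages) + 1L]] <- pmin(vol[z, , ], 65535) / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate",
                  reduce = FALSE)
  meta <- list(channels = names(stack$channels),
               shape_zyx = dim(stack$channels[[1]]),
               voxel_size_zyx = stack$voxel_size_zyx)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    abort(paste0("missing stack sidecar `", meta_path, "`"))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  shp <- as.integer(meta$shape_zyx)
  n_per <- shp[1]
  if (length(pages) != n_per * length(meta$channels))
    abort("page count does not match sidecar shape")
  vols <- list()
  for (i in seq_along(meta$channels)) {
    vol <- array(0, shp)
    for (z in seq_len(n_per)) {
      vol[z, , ] <- pages[[(i - 1L) * n_per + z]] * 65535
    }
    vols[[meta$channels[i]]] <- vol
  }
  image_stack(vols$dna, vols$probe, vols$lamin, as.numeric(meta$voxel_size_zyx))
}

#' Write the scene ground truth as CSV
#'
#' One row per spot: nucleus id, exact position in micrometres, requested
#' normalized radial position and exact shell distance.
#'
#' @param truth the `truth` tibble from [generate_scene()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
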