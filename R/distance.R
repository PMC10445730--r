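#' Shortest 3D distance from a point to a point cloud
#'
#' Euclidean minimum over all cloud points, in micrometres. Coordinates must
#' already be rescaled per axis by the physical voxel size, so the anisotropic
#' z step is accounted for.
#'
#' @param spot_um numeric (z, y, x) position in micrometres.
#' @param cloud_um numeric matrix (n x 3) of cloud positions in micrometres.
#' @return The minimum Euclidean distance, a single number.
#' @export
min_distance_3d <- function(spot_um, cloud_um) {
  spot_um <- check_len3(spot_um, "spot_um", positive = FALSE)
  cloud_um <- as.matrix(cloud_um)
  if (nrow(cloud_um) == 0) abort("lamin point cloud is empty")
  if (ncol(cloud_um) != 3) abort("`cloud_um` must have 3 columns (z, y, x)")
  d2 <- (cloud_um[, 1] - spot_um[1])^2 + (cloud_um[, 2] - spot_um[2])^2 +
    (cloud_um[, 3] - spot_um[3])^2
  sqrt(min(d2))
}

#' Distance of every probe spot to its nucleus's lamin point cloud
#'
#' For each assigned spot, reports the shortest 3D distance (micrometres) to
#' any lamin point of the same nucleus. Spots without a nucleus label and
#' spots in nuclei without lamin points are dropped (and counted in the
#' `n_excluded` attribute).
#'
#' @param spots spot tibble from [localize_spots()] (probe channel).
#' @param cloud lamin point tibble from [lamin_point_cloud()].
#' @param condition optional condition label attached to every record.
#' @return Tibble of distance records: `nucleus`, `spot` (row index into
#'   `spots`), `distance_3d_um`, and `condition` if given.
#' @export
spot_lamin_distances <- function(spots, cloud, condition = NULL) {
  spots$spot <- seq_len(nrow(spots))
  assigned <- dplyr::filter(spots, !is.na(.data$nucleus))
  cloud_by_nuc <- split(as.data.frame(cloud[, c("z_um", "y_um", "x_um")]),
                        cloud$nucleus)
  rows <- purrr::map_dfr(seq_len(nrow(assigned)), function(i) {
    k <- as.character(assigned$nucleus[i])
    cl <- cloud_by_nuc[[k]]
    if (is.null(cl)) return(tibble())
    tibble(nucleus = assigned$nucleus[i], spot = assigned$spot[i],
           distance_3d_um = min_distance_3d(
             c(assigned$z_um[i], assigned$y_um[i], assigned$x_um[i]),
             as.matrix(cl)))
  })
  if (!is.null(condition) && nrow(rows) > 0) rows$condition <- condition
  attr(rows, "n_excluded") <- nrow(spots) - nrow(rows)
  rows
}

#' Maximum projection over z
#'
#' Per-channel maximum-intensity projection, plus an RGB composite for display
#' and 2D annotation (lamin mapped to red, probe to green, DNA to blue; each
#' channel scaled to its own maximum).
#'
#' @param stack an [image_stack()].
#' @return A list with `channels` (named list of 2D matrices, y by x) and
#'   `composite` (H x W x 3 array in \[0, 1\]).
#' @export
max_project_composite <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  proj <- lapply(stack$channels, function(vol) apply(vol, c(2, 3), max))
  norm <- lapply(proj, function(m) if (max(m) > 0) m / max(m) else m)
  comp <- array(0, c(dim(proj[[1]]), 3))
  comp[, , 1] <- norm$lamin
  comp[, , 2] <- norm$probe
  comp[, , 3] <- norm$dna
  list(channels = proj, composite = comp)
}
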