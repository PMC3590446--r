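#' Candidate search space
#'
#' The matching stage does not scan the whole volume: a prior tissue
#' segmentation (vessels, bronchi, abnormalities) restricts the GA's
#' location genes to a set of candidate voxels.  The segmentation itself
#' is outside this package; a search space is built either from a
#' user-supplied binary mask or from a simple gray-level threshold
#' stand-in.  Either way, small connected components (26-connectivity)
#' are discarded, and holes enclosed within a component's slice are
#' filled by default: region-based segmentations return filled objects,
#' and a cavity nodule's center -- which the hollow template must be
#' placed on -- lies in its enclosed interior.
#'
#' @param mask a binary [nod_volume()] congruent with the image volume.
#' @param min_component minimum connected-component size in voxels.
#' @param fill_holes fill background enclosed in-plane by foreground.
#' @return object of class `search_space`: list with `voxels` (0-based
#'   n x 3 integer matrix) and `source`.
#' @export
space_from_mask <- function(mask, min_component = 1, fill_holes = TRUE) {
  stopifnot(inherits(mask, "nod_volume"))
  m <- mask$data > 0
  new_search_space(component_filter(m, min_component, fill_holes),
                   "mask_file")
}

#' @rdname space_from_mask
#' @param vol gray-level [nod_volume()].
#' @param q_low gray threshold; voxels with gray `>= q_low` are candidates.
#' @export
space_from_threshold <- function(vol, q_low, min_component = 1,
                                 fill_holes = TRUE) {
  stopifnot(inherits(vol, "nod_volume"))
  m <- vol$data >= q_low
  new_search_space(component_filter(m, min_component, fill_holes),
                   "threshold_standin")
}

component_filter <- function(m, min_component, fill_holes = TRUE) {
  if (!any(m)) return(matrix(integer(), 0, 3))
  lab <- label_components_26(m, dim(m))
  if (min_component > 1) {
    sz <- tabulate(lab[lab > 0])
    keep <- which(sz >= min_component)
    m <- array(lab %in% keep & lab > 0, dim(m))
  }
  if (fill_holes) for (k in seq_len(dim(m)[3])) m[, , k] <- fill_slice(m[, , k])
  idx <- which(m, arr.ind = TRUE)
  cbind(idx[, 1], idx[, 2], idx[, 3]) - 1L
}

# Fill background regions not connected to the slice border (2D).
fill_slice <- function(sl) {
  bg <- !sl
  dim(bg) <- c(dim(sl), 1L)
  lab <- label_components_26(bg, dim(bg))[, , 1]
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  hole <- !(lab %in% c(0L, border))
  dim(hole) <- dim(sl)
  sl | hole
}

new_search_space <- function(voxels, source) {
  storage.mode(voxels) <- "integer"
  colnames(voxels) <- c("x", "y", "z")
  structure(list(voxels = voxels, source = source), class = "search_space")
}

#' Binary mask volume spanned by a search space
#'
#' @param space a `search_space`.
#' @param dims volume dimensions.
#' @return binary [nod_volume()] with 1 at the space's voxels.
#' @export
space_to_mask <- function(space, dims) {
  m <- array(0, dims)
  if (nrow(space$voxels)) m[space$voxels + 1L] <- 1
  nod_volume(m)
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("<search_space> %d voxels (%s)\n", nrow(x$voxels), x$source))
  invisible(x)
}
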