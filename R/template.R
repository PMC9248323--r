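#' Build a hypervoxel template from tractograms
#'
#' A hypervoxel template records the bidirectional incidence between grid
#' voxels and streamline identities: a streamline is linked to every voxel
#' any of its segments passes through (segments are traversed with
#' half-voxel steps, so voxels crossed between sparse vertices are not
#' missed), and a voxel revisited by the same streamline is linked once.
#' The template is the connectivity structure of tract-based cluster
#' analysis: two suprathreshold voxels belong to the same cluster when
#' they are spatially adjacent or share a common streamline.
#'
#' @param tracts a [tractogram()] or a list of tractograms (all in the
#'   template grid's world frame).
#' @param grid_shape integer vector of 3 voxel counts.
#' @param affine 4x4 voxel-to-world matrix of the template grid.
#' @param step traversal step length in voxel units (default 0.5).
#' @return an object of class `hypervoxel_template` with elements
#'   `voxel_streamlines` (list keyed by linear voxel index) and
#'   `streamline_voxels` (list keyed by streamline id), plus the grid
#'   geometry and per-streamline bundle labels.
#' @export
build_template <- function(tracts, grid_shape, affine = diag(4), step = 0.5) {
  if (inherits(tracts, "tractogram")) tracts <- list(tracts)
  stopifnot(length(tracts) >= 1L,
            all(vapply(tracts, inherits, logical(1), "tractogram")))
  n_total <- sum(vapply(tracts, function(t) length(t$streamlines), integer(1)))
  if (n_total == 0L) stop("empty tractogram: no streamlines to build a template from")
  grid_shape <- as.integer(rep(grid_shape, length.out = 3L))

  streamline_voxels <- vector("list", n_total)
  labels <- character(n_total)
  sid <- 0L
  for (tr in tracts) {
    for (i in seq_along(tr$streamlines)) {
      sid <- sid + 1L
      vox <- streamline_voxel_indices(tr$streamlines[[i]], affine, grid_shape, step)
      streamline_voxels[[sid]] <- vox
      labels[sid] <- if (is.null(tr$labels)) NA_character_ else tr$labels[i]
    }
  }
  names(streamline_voxels) <- as.character(seq_len(n_total))

  counts <- lengths(streamline_voxels)
  all_vox <- unlist(streamline_voxels, use.names = FALSE)
  all_sid <- rep.int(seq_len(n_total), counts)
  voxel_streamlines <- split(all_sid, all_vox)

  structure(list(grid_shape = grid_shape, affine = as.matrix(affine),
                 voxel_streamlines = voxel_streamlines,
                 streamline_voxels = streamline_voxels,
                 labels = labels),
            class = "hypervoxel_template")
}

#' @export
print.hypervoxel_template <- function(x, ...) {
  cat(sprintf("<hypervoxel_template> %d x %d x %d grid, %d streamlines, %d occupied voxels\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              length(x$streamline_voxels), length(x$voxel_streamlines)))
  invisible(x)
}

# Unique 1-based linear voxel indices crossed by one streamline.
# Walks every inter-vertex segment at `step` voxel-length increments;
# out-of-grid samples are dropped.
streamline_voxel_indices <- function(points, affine, grid_shape, step = 0.5) {
  v <- world_to_voxel(points, affine)
  n <- nrow(v)
  if (n == 1L) {
    samp <- v
  } else {
    seg_len <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-n, , drop = FALSE])^2))
    n_steps <- pmax(1L, ceiling(seg_len / step))
    total <- sum(n_steps) + 1L
    samp <- matrix(0, nrow = total, ncol = 3L)
    row <- 1L
    for (s in seq_len(n - 1L)) {
      f <- seq(0, 1, length.out = n_steps[s] + 1L)[-(n_steps[s] + 1L)]
      samp[row:(row + n_steps[s] - 1L), ] <-
        cbind(v[s, 1] + f * (v[s + 1, 1] - v[s, 1]),
              v[s, 2] + f * (v[s + 1, 2] - v[s, 2]),
              v[s, 3] + f * (v[s + 1, 3] - v[s, 3]))
      row <- row + n_steps[s]
    }
    samp[total, ] <- v[n, ]
  }
  idx <- floor(samp + 0.5) # nearest voxel center, half-open extents
  keep <- idx[, 1] >= 0 & idx[, 1] < grid_shape[1] &
    idx[, 2] >= 0 & idx[, 2] < grid_shape[2] &
    idx[, 3] >= 0 & idx[, 3] < grid_shape[3]
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0L) return(integer(0))
  lin <- 1L + idx[, 1] + grid_shape[1] * (idx[, 2] + grid_shape[2] * idx[, 3])
  unique(as.integer(lin))
}

# logical 3D mask of voxels traversed by streamlines with the given label
template_bundle_mask <- function(template, label) {
  sel <- which(template$labels == label)
  vox <- unique(unlist(template$streamline_voxels[sel], use.names = FALSE))
  mask <- array(FALSE, dim = template$grid_shape)
  mask[vox] <- TRUE
  mask
}
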