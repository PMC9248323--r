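#' Sample a metric map at streamline vertices
#'
#' Trilinear interpolation at each vertex's continuous voxel coordinate
#' (world-to-voxel via the inverse affine, voxel centers at integer
#' 0-based coordinates). Vertices outside the grid of voxel centers yield
#' `NA`.
#'
#' @param volume a [scalar_volume()].
#' @param streamline n x 3 matrix of world-mm points.
#' @return numeric vector of per-vertex values (`NA` outside the grid).
#' @export
sample_streamline <- function(volume, streamline) {
  vals <- interp_trilinear(volume$data, world_to_voxel(streamline, volume$affine))
  if (all(is.na(vals))) stop("all streamline vertices fall outside the volume grid")
  vals
}

# vectorized trilinear interpolation at continuous 0-based voxel coords
interp_trilinear <- function(arr, vc) {
  d <- dim(arr)
  n <- nrow(vc)
  inside <- vc[, 1] >= 0 & vc[, 1] <= d[1] - 1 &
    vc[, 2] >= 0 & vc[, 2] <= d[2] - 1 &
    vc[, 3] >= 0 & vc[, 3] <= d[3] - 1
  out <- rep(NA_real_, n)
  if (!any(inside)) return(out)
  v <- vc[inside, , drop = FALSE]
  f0 <- pmin(floor(v), rep(d, each = nrow(v)) - 2) # upper corner stays in-grid
  fr <- v - f0
  acc <- numeric(nrow(v))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) fr[, 1] else 1 - fr[, 1]) *
      (if (cy) fr[, 2] else 1 - fr[, 2]) *
      (if (cz) fr[, 3] else 1 - fr[, 3])
    idx <- 1 + (f0[, 1] + cx) + d[1] * ((f0[, 2] + cy) + d[2] * (f0[, 3] + cz))
    acc <- acc + w * arr[idx]
  }
  out[inside] <- acc
  out
}

#' Aggregate a metric over one bundle
#'
#' Default aggregation: the median over each streamline's vertex samples,
#' then the mean over streamlines ("vertex-median-streamline-mean").
#' `"pooled-median"` instead pools all vertex samples of the bundle and
#' takes a single median. Missing vertices are excluded from their
#' streamline's median; streamlines with no usable vertex are dropped
#' (with a message giving the count).
#'
#' @param volume a [scalar_volume()].
#' @param bundle list of n x 3 streamline matrices (world mm), non-empty.
#' @param aggregate aggregation rule.
#' @return scalar bundle value.
#' @export
segment_value <- function(volume, bundle,
                          aggregate = c("vertex-median-streamline-mean",
                                        "pooled-median")) {
  aggregate <- match.arg(aggregate)
  if (length(bundle) == 0L) stop("empty bundle")
  samples <- lapply(bundle, function(s)
    interp_trilinear(volume$data, world_to_voxel(s, volume$affine)))
  if (aggregate == "pooled-median") {
    pooled <- unlist(samples, use.names = FALSE)
    if (all(is.na(pooled))) stop("no usable vertex samples in bundle")
    return(stats::median(pooled, na.rm = TRUE))
  }
  med <- vapply(samples, function(v) stats::median(v, na.rm = TRUE), numeric(1))
  n_empty <- sum(is.nan(med) | is.na(med))
  if (n_empty == length(med)) stop("no usable vertex samples in bundle")
  if (n_empty > 0L) {
    message("segment_value: excluded ", n_empty,
            " streamline(s) with no in-grid vertex")
  }
  mean(med, na.rm = TRUE)
}

#' Build the subject x segment x metric tractometry table
#'
#' Samples every metric map along the seven labeled callosal bundles and
#' aggregates with [segment_value()]. Non-callosal bundles (e.g. "CST")
#' are excluded from the table.
#'
#' @param cohort cohort tibble with an `id` column, or an `hd_cohort`.
#' @param tracts labeled [tractogram()] (ignored if `cohort` is an
#'   `hd_cohort`).
#' @param volumes named list: `volumes[[subject_id]][[metric]]` is a
#'   [scalar_volume()] (ignored if `cohort` is an `hd_cohort`).
#' @param metrics metrics to tabulate.
#' @param aggregate passed to [segment_value()].
#' @return tibble with columns `subject_id`, `segment` (integer 1-7),
#'   `metric`, `value`.
#' @export
build_tractometry_table <- function(cohort, tracts = NULL, volumes = NULL,
                                    metrics = c("FA", "AD", "RD", "FR", "MTR"),
                                    aggregate = "vertex-median-streamline-mean") {
  if (inherits(cohort, "hd_cohort")) {
    tracts <- cohort$tractogram
    volumes <- cohort$volumes
    cohort <- cohort$cohort
  }
  stopifnot(inherits(tracts, "tractogram"), !is.null(tracts$labels))
  segs <- as.character(1:7)

  # all volumes share one affine in a registered cohort, so the
  # world-to-voxel conversion of every vertex is precomputed once
  ref <- volumes[[cohort$id[1]]][[metrics[1]]]
  for (sid in cohort$id) {
    if (is.null(volumes[[sid]])) stop("no volumes for subject ", sid)
    for (m in metrics) {
      v <- volumes[[sid]][[m]]
      if (is.null(v)) stop("missing metric volume '", m, "' for subject ", sid)
      check_same_grid(v, ref, paste0("volumes of ", sid))
    }
  }
  seg_coords <- lapply(segs, function(s) {
    sl <- tracts$streamlines[tracts$labels == s]
    if (length(sl) == 0L) stop("no streamlines labeled '", s, "'")
    list(vc = world_to_voxel(do.call(rbind, sl), ref$affine),
         sid = rep.int(seq_along(sl), vapply(sl, nrow, integer(1))))
  })
  names(seg_coords) <- segs

  rows <- list()
  for (sid in cohort$id) {
    for (m in metrics) {
      arr <- volumes[[sid]][[m]]$data
      vals <- vapply(segs, function(s) {
        sc <- seg_coords[[s]]
        v <- interp_trilinear(arr, sc$vc)
        if (aggregate == "pooled-median") {
          stats::median(v, na.rm = TRUE)
        } else {
          mean(grouped_medians(v, sc$sid), na.rm = TRUE)
        }
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sid, segment = as.integer(segs), metric = m, value = vals)
    }
  }
  out <- do.call(rbind, rows)
  if (any(!is.finite(out$value))) stop("non-finite tractometry values produced")
  out
}

# median of v within each group of sid; vectorized via a single order()
# when all groups have equal size and no missing values
grouped_medians <- function(v, sid) {
  nv <- tabulate(sid)
  if (!anyNA(v) && length(unique(nv)) == 1L) {
    n <- nv[1]
    m <- matrix(v, nrow = n)
    ms <- matrix(m[order(col(m), m)], nrow = n)
    if (n %% 2L == 1L) return(ms[(n + 1L) %/% 2L, ])
    return((ms[n %/% 2L, ] + ms[n %/% 2L + 1L, ]) / 2)
  }
  vapply(split(v, sid), stats::median, numeric(1), na.rm = TRUE)
}
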