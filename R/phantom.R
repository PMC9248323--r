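#' Phantom configuration
#'
#' Describes the synthetic voxel grid and bundle geometry used by the
#' generators: seven parasagittal callosal arcs ordered anterior to
#' posterior along the x axis (labels 1-7: rostrum, genu, rostral body,
#' anterior midbody, posterior midbody, isthmus, splenium) plus one
#' vertical corticospinal-tract-like tube ("CST"), spatially disjoint from
#' the callosal arcs.
#'
#' @param grid_shape integer vector of 3 voxel counts (default 48^3).
#' @param voxel_size voxel edge length in mm (default 2).
#' @param n_streamlines_per_bundle streamlines per bundle (default 2000,
#'   matching segment-wise callosal tractography practice; reduce for
#'   tests).
#' @param n_vertices vertices per streamline.
#' @param jitter_mm within-bundle positional jitter (mm).
#' @param noise_sd named list of voxelwise noise standard deviations per
#'   metric (map units).
#' @param subject_sd named list of between-subject global offsets per
#'   metric (map units). The MTR offset is driven by a per-subject latent
#'   myelin factor.
#' @param myelin_rd_cross loading of the latent myelin factor on RD
#'   (mm^2/s per myelin SD; negative: more myelin, lower radial
#'   diffusivity). This mild MTR-RD coupling is what lets the MT
#'   component carry more than one variable's worth of variance.
#' @param smooth_fwhm Gaussian smoothing FWHM applied to generated maps
#'   (mm).
#' @param age_range patient age range in years.
#' @param cag_range integer CAG repeat range for patients.
#' @param seed integer root seed; all generator randomness derives from it
#'   through named substreams.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 48L),
                           voxel_size = 2,
                           n_streamlines_per_bundle = 2000L,
                           n_vertices = 30L,
                           jitter_mm = 1,
                           noise_sd = NULL,
                           subject_sd = NULL,
                           myelin_rd_cross = -1.5e-5,
                           smooth_fwhm = 4,
                           age_range = c(21, 70),
                           cag_range = c(37L, 45L),
                           seed = 1L) {
  grid_shape <- as.integer(rep(grid_shape, length.out = 3L))
  stopifnot(all(grid_shape > 0L), voxel_size > 0,
            n_streamlines_per_bundle >= 1L, n_vertices >= 3L,
            diff(age_range) > 0, cag_range[1] >= 36L)
  default_noise <- list(MTR = 0.8, FA = 0.04, AD = 6e-5, RD = 4e-5,
                        FR = 0.03, FWF = 0.02)
  default_subject <- list(MTR = 0.6, FA = 0.02, AD = 3e-5, RD = 2e-5,
                          FR = 0.015, FWF = 0.01)
  noise_sd <- utils::modifyList(default_noise, as.list(noise_sd %||% list()))
  subject_sd <- utils::modifyList(default_subject, as.list(subject_sd %||% list()))
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 n_streamlines_per_bundle = as.integer(n_streamlines_per_bundle),
                 n_vertices = as.integer(n_vertices), jitter_mm = jitter_mm,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 myelin_rd_cross = myelin_rd_cross,
                 smooth_fwhm = smooth_fwhm, age_range = age_range,
                 cag_range = as.integer(cag_range), seed = as.integer(seed)),
            class = "phantom_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Planted group-level effects for the synthetic cohort
#'
#' Encodes the effects the downstream analyses are expected to recover:
#' a segment-dependent MTR shift in patients (positive anterior, negative
#' posterior), a positive CAG-MTR slope, a negative group-by-age
#' difference in MTR slope (patients' MTR higher when young, lower when
#' old), an additive restricted-fraction offset in the patients' CST, and
#' a posterior-high axon-density baseline gradient. `effect_spec(null =
#' TRUE)` gives the global null (all zeros).
#'
#' Magnitudes are in native map units. The source study reports component
#' scores and test statistics rather than native-unit effect sizes, so the
#' defaults are chosen as plausible premanifest-scale effects (see the
#' methods vignette).
#'
#' @param group_segment_mtr length-7 numeric, additive MTR offset for
#'   patients per callosal segment 1-7.
#' @param cag_mtr_slope MTR units per CAG repeat (applied around the
#'   patients' mean CAG, callosal bundles only).
#' @param age_mtr_slope baseline MTR units per year of age (both groups).
#' @param group_age_interaction patient-minus-control difference in MTR
#'   age slope (units/year).
#' @param cst_fr_offset additive FR in the patients' CST bundle.
#' @param density_gradient named numeric: posterior-minus-anterior span of
#'   the baseline bundle value for FA, FR, AD (positive) and RD (applied
#'   with opposite sign).
#' @param null if TRUE, return the all-zero spec.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(group_segment_mtr = c(2, 1.4, 0.7, 0, -0.7, -1.4, -2),
                        cag_mtr_slope = 0.15,
                        age_mtr_slope = -0.05,
                        group_age_interaction = -0.04,
                        cst_fr_offset = 0.05,
                        density_gradient = c(FA = 0.08, FR = 0.08,
                                             AD = 2e-4, RD = 8e-5),
                        null = FALSE) {
  if (null) {
    group_segment_mtr <- rep(0, 7)
    cag_mtr_slope <- age_mtr_slope <- group_age_interaction <- cst_fr_offset <- 0
    density_gradient <- c(FA = 0, FR = 0, AD = 0, RD = 0)
  }
  stopifnot(length(group_segment_mtr) == 7L,
            all(is.finite(group_segment_mtr)),
            all(is.finite(c(cag_mtr_slope, age_mtr_slope,
                            group_age_interaction, cst_fr_offset))),
            all(c("FA", "FR", "AD", "RD") %in% names(density_gradient)))
  structure(list(group_segment_mtr = group_segment_mtr,
                 cag_mtr_slope = cag_mtr_slope,
                 age_mtr_slope = age_mtr_slope,
                 group_age_interaction = group_age_interaction,
                 cst_fr_offset = cst_fr_offset,
                 density_gradient = density_gradient),
            class = "effect_spec")
}

#' Tractogram container
#'
#' @param streamlines list of n x 3 numeric matrices of world-mm points.
#' @param labels vector of bundle labels, one per streamline (callosal
#'   segments "1".."7" and "CST" in the phantom).
#' @return an object of class `tractogram`.
#' @export
tractogram <- function(streamlines, labels = NULL) {
  stopifnot(is.list(streamlines), length(streamlines) >= 1L)
  if (!is.null(labels) && length(labels) != length(streamlines)) {
    stop("label count (", length(labels), ") does not match streamline count (",
         length(streamlines), ")")
  }
  structure(list(streamlines = streamlines,
                 labels = if (is.null(labels)) NULL else as.character(labels)),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("<tractogram> %d streamlines", length(x$streamlines)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(", bundles: ", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

# default voxel-to-world affine for a phantom grid: voxel centers at
# 0, vs, 2*vs, ... mm
phantom_affine <- function(config) {
  a <- diag(c(rep(config$voxel_size, 3), 1))
  a
}

#' Generate the phantom tractogram
#'
#' Callosal segments are half-ellipse arcs lying in parallel slabs whose
#' midpoint x-position orders bundles 1 to 7 from anterior to posterior;
#' the CST is a straight vertical tube, disjoint from the arcs. All points
#' fall inside the grid's world bounding box; a bundle whose geometry
#' would leave the grid raises an error naming the bundle.
#'
#' @param config a [phantom_config()].
#' @return a labeled [tractogram()].
#' @export
make_phantom_tractogram <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_substream(config$seed, "phantom_tractogram", {
    vs <- config$voxel_size
    span <- (config$grid_shape - 1L) * vs # extent of voxel centers
    nsl <- config$n_streamlines_per_bundle
    nv <- config$n_vertices
    jit <- config$jitter_mm
    bounds_lo <- rep(-vs / 2, 3)
    bounds_hi <- span + vs / 2

    streamlines <- list()
    labels <- character(0)
    tt <- seq(0, pi, length.out = nv)

    for (k in 1:7) {
      cx <- span[1] * (0.15 + 0.7 * (k - 1) / 6)
      sx <- span[1] * 0.7 / 6 * 0.25 # slab half-width: segments stay disjoint
      cy <- span[2] * 0.5
      ry <- span[2] * 0.25
      z0 <- span[3] * 0.35
      rz <- span[3] * 0.35
      pts <- vector("list", nsl)
      for (i in seq_len(nsl)) {
        x <- cx + stats::runif(1, -sx, sx)
        ryi <- ry + stats::runif(1, -jit, jit)
        rzi <- rz + stats::runif(1, -jit, jit)
        p <- cbind(x + stats::rnorm(nv, 0, jit / 4),
                   cy + ryi * cos(tt) + stats::rnorm(nv, 0, jit / 4),
                   z0 + rzi * sin(tt) + stats::rnorm(nv, 0, jit / 4))
        pts[[i]] <- p
      }
      check_bundle_bounds(pts, bounds_lo, bounds_hi, as.character(k))
      streamlines <- c(streamlines, pts)
      labels <- c(labels, rep(as.character(k), nsl))
    }

    # CST-like tube: vertical, anterior-inferior of the arcs in y
    cstx <- span[1] * 0.5
    csty <- span[2] * 0.04
    radius <- max(vs / 2, 0.02 * min(span))
    zlo <- span[3] * 0.1
    zhi <- span[3] * 0.9
    pts <- vector("list", nsl)
    for (i in seq_len(nsl)) {
      th <- stats::runif(1, 0, 2 * pi)
      r <- radius * sqrt(stats::runif(1))
      z <- seq(zlo, zhi, length.out = nv)
      pts[[i]] <- cbind(cstx + r * cos(th) + stats::rnorm(nv, 0, jit / 4),
                        csty + r * sin(th) + stats::rnorm(nv, 0, jit / 4),
                        z + stats::rnorm(nv, 0, jit / 4))
    }
    check_bundle_bounds(pts, bounds_lo, bounds_hi, "CST")
    streamlines <- c(streamlines, pts)
    labels <- c(labels, rep("CST", nsl))

    tractogram(streamlines, labels)
  })
}

check_bundle_bounds <- function(pts, lo, hi, label) {
  all_pts <- do.call(rbind, pts)
  out <- sweep(all_pts, 2, lo, "<") | sweep(all_pts, 2, hi, ">=")
  if (any(out)) {
    stop("bundle ", label, " exceeds the grid's world bounding box (",
         sum(rowSums(out) > 0), " vertices outside)")
  }
  invisible(TRUE)
}
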