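# Shared fixtures, built in code and cached across test files.

tiny_config <- function(seed = 7, n_streamlines = 60, grid = 24) {
  phantom_config(grid_shape = rep(grid, 3), voxel_size = 2,
                 n_streamlines_per_bundle = n_streamlines, seed = seed)
}

.fixture_env <- new.env(parent = emptyenv())

# small default-effect cohort reused by several test files
tiny_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- make_cohort(8, 8, effect_spec(),
                                       tiny_config(seed = 42, n_streamlines = 100))
  }
  .fixture_env$cohort
}

# small multishell protocol for the diffusion-model tests
tiny_protocol <- function() {
  multishell_protocol(n_b0 = 4, shells = c(`500` = 12, `1200` = 12,
                                           `2400` = 20, `4000` = 20,
                                           `6000` = 20))
}

# wrap a per-measurement signal vector into a 1-voxel dwi_series
signal_as_dwi <- function(sig, protocol, reps = 1) {
  arr <- array(rep(sig, each = reps), dim = c(reps, 1, 1, length(sig)))
  dwi_series(arr, diag(4), protocol)
}

# volumes list for one metric, ordered as the cohort rows
metric_volumes <- function(ch, metric) {
  v <- lapply(ch$cohort$id, function(id) ch$volumes[[id]][[metric]])
  names(v) <- ch$cohort$id
  v
}

expect_tractogram_in_grid <- function(tr, config) {
  gs <- config$grid_shape
  aff <- diag(c(rep(config$voxel_size, 3), 1))
  for (s in tr$streamlines) {
    vc <- floor(s / config$voxel_size + 0.5)
    expect_true(all(vc >= 0 & vc <= rep(gs - 1, each = nrow(vc))))
  }
}

# logical mask of voxels traversed by one labeled bundle of a cohort
template_mask <- function(ch, label) {
  tmpl <- ch$template
  vox <- unique(unlist(tmpl$streamline_voxels[tmpl$labels == label],
                       use.names = FALSE))
  arr <- array(FALSE, dim = tmpl$grid_shape)
  arr[vox] <- TRUE
  arr
}
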