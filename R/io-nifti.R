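#' Write a scalar volume to NIfTI
#'
#' Data are stored as float32 with the affine in both qform and sform;
#' a write/read round trip preserves values to float32 precision and the
#' affine bit-exactly.
#'
#' @param volume a [scalar_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "scalar_volume"))
  img <- RNifti::asNifti(volume$data)
  vs <- sqrt(colSums(volume$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- vs
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a scalar volume from NIfTI
#'
#' @param path NIfTI-1/2 file.
#' @param metric label to attach to the volume.
#' @return a [scalar_volume()].
#' @export
read_volume <- function(path, metric = "value") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  scalar_volume(array(as.numeric(img), dim = dim(img)[1:3]), aff, metric)
}

#' Write a diffusion series as NIfTI plus FSL-style bvals/bvecs
#'
#' @param dwi a [dwi_series()].
#' @param path 4D NIfTI output path.
#' @param bvals_path,bvecs_path text sidecar paths (default: `path` with
#'   `.bval` / `.bvec` extensions).
#' @return `path`, invisibly.
#' @export
write_dwi <- function(dwi, path,
                      bvals_path = sub("\\.nii(\\.gz)?$", ".bval", path),
                      bvecs_path = sub("\\.nii(\\.gz)?$", ".bvec", path)) {
  stopifnot(inherits(dwi, "dwi_series"))
  img <- RNifti::asNifti(dwi$data)
  vs <- sqrt(colSums(dwi$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- c(vs, 1)
  RNifti::qform(img) <- structure(dwi$affine, code = 2L)
  RNifti::sform(img) <- structure(dwi$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  writeLines(paste(format(dwi$protocol$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bvals_path)
  writeLines(apply(t(dwi$protocol$bvecs), 1, paste, collapse = " "), bvecs_path)
  invisible(path)
}

#' Read a diffusion series from NIfTI plus FSL-style bvals/bvecs
#'
#' @param path 4D NIfTI file.
#' @param bvals_path,bvecs_path sidecar text files (FSL convention: one
#'   row of b-values; three rows of direction components).
#' @param delta_ms,Delta_ms pulse timings (not stored in the FSL files).
#' @return a [dwi_series()].
#' @export
read_dwi <- function(path,
                     bvals_path = sub("\\.nii(\\.gz)?$", ".bval", path),
                     bvecs_path = sub("\\.nii(\\.gz)?$", ".bvec", path),
                     delta_ms = 7, Delta_ms = 24) {
  for (f in c(path, bvals_path, bvecs_path)) {
    if (!file.exists(f)) stop("no such file: ", f)
  }
  img <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  bvals <- scan(bvals_path, quiet = TRUE)
  bvecs <- t(matrix(scan(bvecs_path, quiet = TRUE), nrow = 3, byrow = TRUE))
  proto <- acquisition_protocol(bvals, bvecs, delta_ms, Delta_ms)
  dwi_series(array(as.numeric(img), dim = dim(img)), aff, proto)
}

# reject grid mismatches across a cohort of volume files
check_cohort_grids <- function(volumes, ids = names(volumes)) {
  ref <- volumes[[1]]
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (!identical(dim(v$data), dim(ref$data)) ||
        max(abs(v$affine - ref$affine)) > 1e-6) {
      stop("grid/affine mismatch for ", ids[i])
    }
  }
  invisible(TRUE)
}
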