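#' Magnetization transfer ratio map
#'
#' `MTR = (S0 - SMT) / S0 x 100`, where S0 is the signal without and SMT
#' the signal with the off-resonance saturation pulse. Voxels outside the
#' mask (which always excludes S0 <= 0) are set to `NA`.
#'
#' @param s0 [scalar_volume()] without MT saturation.
#' @param s_mt [scalar_volume()] with MT saturation; same grid and affine.
#' @param mask optional logical array; combined with the S0 > 0 condition.
#' @return a [scalar_volume()] labeled "MTR".
#' @export
compute_mtr <- function(s0, s_mt, mask = NULL) {
  stopifnot(inherits(s0, "scalar_volume"), inherits(s_mt, "scalar_volume"))
  check_same_grid(s0, s_mt, "S0 and SMT volumes")
  keep <- s0$data > 0
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(s0$data)))
    keep <- keep & mask
  }
  out <- array(NA_real_, dim = dim(s0$data))
  out[keep] <- (s0$data[keep] - s_mt$data[keep]) / s0$data[keep] * 100
  scalar_volume(out, s0$affine, "MTR")
}
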