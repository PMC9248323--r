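# design matrix for the log-linear tensor model:
# log S = log S0 - b g' D g
dti_design <- function(bvals, bvecs) {
  g <- bvecs
  cbind(1,
        -bvals * g[, 1]^2,
        -bvals * g[, 2]^2,
        -bvals * g[, 3]^2,
        -2 * bvals * g[, 1] * g[, 2],
        -2 * bvals * g[, 1] * g[, 3],
        -2 * bvals * g[, 2] * g[, 3])
}

tensor_matrix <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

# eigenvalue-derived scalar metrics; eigenvalues clipped at zero before FA
tensor_metrics <- function(d6) {
  ev <- sort(eigen(tensor_matrix(d6), symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  md <- mean(ev)
  denom <- sum(ev^2)
  fa <- if (denom > 0) sqrt(1.5 * sum((ev - md)^2) / denom) else 0
  c(FA = fa, AD = ev[1], RD = (ev[2] + ev[3]) / 2, MD = md)
}

#' Fit the diffusion tensor with weighted linear least squares
#'
#' Fits `log S = log S0 - b g' D g` by ordinary least squares on the
#' log-signal followed by one reweighting pass with weights equal to the
#' squared predicted signal. Only measurements with b = 0 or b inside
#' `b_range` enter the fit (the restricted range suppresses CSF partial
#' volume in the tensor metrics); both endpoints are included. Eigenvalues
#' are clipped at zero before FA is computed.
#'
#' @param dwi a [dwi_series()].
#' @param b_range inclusive b-value window in s/mm^2 (default 500-1200).
#' @param mask optional logical array of voxels to fit.
#' @return a list of class `tensor_fit`: `tensors` (n_voxel x 6 of unique
#'   tensor elements Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), scalar map volumes
#'   `FA`, `AD`, `RD`, `MD`, the fitted `mask`, and `n_excluded_signals`
#'   (count of non-positive signals dropped voxelwise).
#' @export
fit_dti <- function(dwi, b_range = c(500, 1200), mask = NULL) {
  stopifnot(inherits(dwi, "dwi_series"))
  p <- dwi$protocol
  sel <- p$bvals == 0 | (p$bvals >= b_range[1] & p$bvals <= b_range[2])
  in_shell <- sel & p$bvals > 0
  ndir <- nrow(unique(round(p$bvecs[in_shell, , drop = FALSE], 6)))
  if (ndir < 6L) {
    stop("need at least 6 unique gradient directions within b_range, found ", ndir)
  }
  if (!any(p$bvals[sel] == 0)) stop("need at least one b = 0 volume")

  d <- dim(dwi$data)
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  vox <- which(mask)
  X <- dti_design(p$bvals[sel], p$bvecs[sel, , drop = FALSE])
  M <- matrix(aperm(dwi$data, c(4, 1, 2, 3)), nrow = d[4])
  Y <- M[sel, vox, drop = FALSE]

  tensors <- matrix(NA_real_, length(vox), 6)
  mets <- matrix(NA_real_, length(vox), 4)
  n_excluded <- 0L
  for (i in seq_along(vox)) {
    y <- Y[, i]
    ok <- is.finite(y) & y > 0
    n_excluded <- n_excluded + sum(!ok)
    if (sum(ok) < ncol(X) + 1L) next
    Xi <- X[ok, , drop = FALSE]
    ly <- log(y[ok])
    beta <- stats::lm.fit(Xi, ly)$coefficients
    w <- exp(Xi %*% beta)^2 # reweight by squared predicted signal
    beta <- stats::lm.wfit(Xi, ly, as.vector(w))$coefficients
    tensors[i, ] <- beta[2:7]
    mets[i, ] <- tensor_metrics(beta[2:7])
  }
  if (n_excluded > 0L) {
    message("fit_dti: excluded ", n_excluded, " non-positive signal(s) voxelwise")
  }

  vols <- lapply(1:4, function(j) {
    arr <- array(NA_real_, dim = d[1:3])
    arr[vox] <- mets[, j]
    scalar_volume(arr, dwi$affine, c("FA", "AD", "RD", "MD")[j])
  })
  names(vols) <- c("FA", "AD", "RD", "MD")
  structure(c(list(tensors = tensors, voxels = vox, mask = mask,
                   n_excluded_signals = n_excluded), vols),
            class = "tensor_fit")
}
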