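#' Parameters of the composite hindered and restricted diffusion model
#'
#' The signal is `S = S0 * ((1 - FR) * E_h + FR * E_r)` with a Gaussian
#' hindered compartment `E_h = exp(-b g' D_h g)` and a restricted
#' cylinder compartment whose parallel attenuation is mono-exponential in
#' the intracellular axial diffusivity and whose perpendicular attenuation
#' follows the small-radius Gaussian-phase closed form (see
#' `charmed_restricted_attenuation`). A single cylinder population with a
#' fixed radius is modeled and the intracellular perpendicular diffusivity
#' is tied to the axial one: only the restricted signal fraction is of
#' analytic interest, not radius estimation.
#'
#' @param s0 non-diffusion-weighted signal.
#' @param fr restricted signal fraction in `[0, 1]`.
#' @param d_hindered hindered tensor: length-6 vector
#'   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) or symmetric 3x3 matrix, mm^2/s.
#' @param d_par intracellular axial diffusivity, mm^2/s (> 0).
#' @param radius_um cylinder radius in micrometres (> 0; default 3, the
#'   smallest radius resolvable with ultra-strong gradients).
#' @param axis unit cylinder axis (defaults to the hindered tensor's
#'   principal eigenvector).
#' @return an object of class `charmed_params`.
#' @export
charmed_params <- function(s0 = 1, fr, d_hindered, d_par = 1.5e-3,
                           radius_um = 3, axis = NULL) {
  stopifnot(fr >= 0, fr <= 1, d_par > 0, radius_um > 0, s0 > 0)
  if (is.matrix(d_hindered)) {
    stopifnot(all(dim(d_hindered) == c(3, 3)),
              max(abs(d_hindered - t(d_hindered))) < 1e-12)
    d6 <- c(diag(d_hindered), d_hindered[1, 2], d_hindered[1, 3], d_hindered[2, 3])
  } else {
    stopifnot(length(d_hindered) == 6L)
    d6 <- as.numeric(d_hindered)
  }
  if (is.null(axis)) {
    axis <- eigen(tensor_matrix(d6), symmetric = TRUE)$vectors[, 1]
  }
  axis <- axis / sqrt(sum(axis^2))
  structure(list(s0 = s0, fr = fr, d_hindered = d6, d_par = d_par,
                 radius_um = radius_um, axis = axis),
            class = "charmed_params")
}

# Restricted (intra-cylinder) attenuation.
# Parallel: exp(-4 pi^2 q_par^2 (Delta - delta/3) D_par) = exp(-b cos2 D_par)
# since b = 4 pi^2 q^2 (Delta - delta/3).
# Perpendicular: exp(-(7/96) 4 pi^2 q_perp^2 (a^4 / (D_perp Delta))
#                    (2 - (99/112) a^2 / (D_perp Delta))).
# b in s/mm^2, times in s, radius in mm, diffusivities in mm^2/s.
charmed_restricted_attenuation <- function(bvals, cos2, delta, Delta,
                                           d_par, radius_mm, d_perp = d_par) {
  tdiff <- Delta - delta / 3
  e_par <- exp(-bvals * cos2 * d_par)
  q2_perp_4pi2 <- bvals * (1 - cos2) / tdiff # = 4 pi^2 q_perp^2
  ad <- radius_mm^2 / (d_perp * Delta)
  e_perp <- exp(-(7 / 96) * q2_perp_4pi2 * radius_mm^2 * ad *
                  (2 - (99 / 112) * ad))
  e_par * e_perp
}

# hindered Gaussian attenuation for a 6-element tensor
hindered_attenuation <- function(bvals, bvecs, d6) {
  g <- bvecs
  quad <- d6[1] * g[, 1]^2 + d6[2] * g[, 2]^2 + d6[3] * g[, 3]^2 +
    2 * (d6[4] * g[, 1] * g[, 2] + d6[5] * g[, 1] * g[, 3] +
           d6[6] * g[, 2] * g[, 3])
  exp(-bvals * quad)
}

charmed_forward <- function(params, protocol) {
  cos2 <- as.vector(protocol$bvecs %*% params$axis)^2
  e_h <- hindered_attenuation(protocol$bvals, protocol$bvecs, params$d_hindered)
  e_r <- charmed_restricted_attenuation(protocol$bvals, cos2,
                                        protocol$delta, protocol$Delta,
                                        params$d_par, params$radius_um * 1e-3)
  params$s0 * ((1 - params$fr) * e_h + params$fr * e_r)
}

#' Simulate a diffusion-weighted signal under the two-compartment model
#'
#' Noise-free signal `S = S0 * ((1 - FR) E_h + FR E_r)`; a finite `snr`
#' adds Rician noise built from two independent Gaussian channels with
#' standard deviation `S0 / snr`.
#'
#' @param params a [charmed_params()].
#' @param protocol an [acquisition_protocol()].
#' @param snr positive signal-to-noise ratio at b = 0, or `Inf`.
#' @param seed root seed for the noise draw (substream "charmed_noise").
#' @return numeric signal vector, one value per protocol measurement.
#' @export
simulate_charmed_signal <- function(params, protocol, snr = Inf, seed = 1L) {
  stopifnot(inherits(params, "charmed_params"),
            inherits(protocol, "acquisition_protocol"), snr > 0)
  s <- charmed_forward(params, protocol)
  if (is.finite(snr)) {
    sigma <- params$s0 / snr
    s <- with_substream(seed, "charmed_noise", {
      n1 <- stats::rnorm(length(s), 0, sigma)
      n2 <- stats::rnorm(length(s), 0, sigma)
      sqrt((s + n1)^2 + n2^2)
    })
  }
  s
}

# shared per-voxel box-constrained Levenberg-Marquardt driver for the
# two-compartment fitters; returns NULL on failure
lm_fit_voxel <- function(par0, lower, upper, residual_fn) {
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = residual_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info < 1 || fit$info > 4) return(NULL)
  fit
}

#' Fit the restricted signal fraction (FR) per voxel
#'
#' Per-voxel box-constrained least squares fit of the two-compartment
#' hindered/restricted signal. The hindered tensor is seeded from a
#' low-b diffusion tensor fit; FR starts at 0.3 with one alternate start
#' at 0.7 and the lower-misfit solution is kept (FR has local minima at
#' the box edges). The cylinder axis follows the current hindered tensor's
#' principal eigenvector; the intracellular axial diffusivity and cylinder
#' radius are fixed. Non-converged voxels get `NA` FR and are counted in
#' the returned log.
#'
#' @param dwi a [dwi_series()] with maximum b >= 4000 s/mm^2.
#' @param mask optional logical array.
#' @param d_par fixed intracellular axial diffusivity (mm^2/s).
#' @param radius_um fixed cylinder radius (micrometres).
#' @param init_fr the two FR starting values.
#' @return a list of class `charmed_fit`: `FR` [scalar_volume()], `s0`
#'   and `tensors` per fitted voxel, and `n_failed` voxels.
#' @export
fit_charmed <- function(dwi, mask = NULL, d_par = 1.5e-3, radius_um = 3,
                        init_fr = c(0.3, 0.7)) {
  stopifnot(inherits(dwi, "dwi_series"))
  p <- dwi$protocol
  if (max(p$bvals) < 4000) {
    stop("CHARMED requires multi-shell data with maximum b >= 4000 s/mm^2")
  }
  d <- dim(dwi$data)
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  vox <- which(mask)
  dti <- fit_dti(dwi, b_range = c(1, 1200), mask = mask)
  Y <- matrix(aperm(dwi$data, c(4, 1, 2, 3)), nrow = d[4])[, vox, drop = FALSE]
  radius_mm <- radius_um * 1e-3 # micrometres to millimetres
  b0 <- p$bvals == 0

  fr_hat <- rep(NA_real_, length(vox))
  s0_hat <- rep(NA_real_, length(vox))
  tensors <- matrix(NA_real_, length(vox), 6)
  n_failed <- 0L

  for (i in seq_along(vox)) {
    y <- Y[, i]
    d6_0 <- dti$tensors[i, ]
    if (any(!is.finite(d6_0)) || any(!is.finite(y))) { n_failed <- n_failed + 1L; next }
    s0_0 <- mean(y[b0])
    resid_fn <- function(par) {
      d6 <- par[3:8]
      axis <- eigen(tensor_matrix(d6), symmetric = TRUE)$vectors[, 1]
      cos2 <- as.vector(p$bvecs %*% axis)^2
      e_h <- hindered_attenuation(p$bvals, p$bvecs, d6)
      e_r <- charmed_restricted_attenuation(p$bvals, cos2, p$delta, p$Delta,
                                            d_par, radius_mm)
      par[1] * ((1 - par[2]) * e_h + par[2] * e_r) - y
    }
    best <- NULL
    for (fr0 in init_fr) {
      fit <- lm_fit_voxel(c(s0_0, fr0, d6_0),
                          lower = c(0, 0, rep(-Inf, 6)),
                          upper = c(Inf, 1, rep(Inf, 6)),
                          resid_fn)
      if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) {
        best <- fit
      }
    }
    if (is.null(best)) { n_failed <- n_failed + 1L; next }
    fr_hat[i] <- best$par[2]
    s0_hat[i] <- best$par[1]
    tensors[i, ] <- best$par[3:8]
  }
  if (n_failed > 0L) {
    message("fit_charmed: ", n_failed, " voxel(s) did not converge (FR set to NA)")
  }
  fr_map <- array(NA_real_, dim = d[1:3])
  fr_map[vox] <- fr_hat
  structure(list(FR = scalar_volume(fr_map, dwi$affine, "FR"),
                 s0 = s0_hat, tensors = tensors, voxels = vox,
                 n_failed = n_failed),
            class = "charmed_fit")
}

#' Fit the free-water signal fraction (FWF) per voxel
#'
#' Two-compartment fit `S/S0 = FWF exp(-b D_free) + (1 - FWF)
#' exp(-b g' D_t g)` with the free-water diffusivity fixed at
#' 3.0e-3 mm^2/s, using only shells at or below `b_max`. FWF is box
#' constrained to `[0, 1]` and the tissue tensor elements to
#' `d_tissue_max` (below the free diffusivity), which keeps the two
#' compartments identifiable when the voxel is nearly pure fluid; two FWF
#' starts (0.1 and 0.9) are tried and the lower misfit kept. This is a
#' plain unregularized fixed-D two-compartment estimator; outputs are
#' labeled "FWF" accordingly.
#'
#' @param dwi a [dwi_series()] with at least 2 nonzero shells <= `b_max`.
#' @param mask optional logical array.
#' @param d_free free-water diffusivity (mm^2/s).
#' @param b_max highest shell used (s/mm^2).
#' @param d_tissue_max box bound on the tissue-tensor elements (mm^2/s).
#' @return a list of class `fwf_fit` with `FWF` [scalar_volume()], tissue
#'   `tensors`, and `n_failed`.
#' @export
fit_fwf <- function(dwi, mask = NULL, d_free = 3.0e-3, b_max = 1200,
                    d_tissue_max = 2.5e-3) {
  stopifnot(inherits(dwi, "dwi_series"))
  p <- dwi$protocol
  sel <- p$bvals <= b_max
  shells <- unique(round(p$bvals[sel & p$bvals > 0]))
  if (length(shells) < 2L) {
    stop("free-water fit requires at least 2 nonzero shells <= ", b_max, " s/mm^2")
  }
  d <- dim(dwi$data)
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  vox <- which(mask)
  dti <- fit_dti(dwi, b_range = c(1, b_max), mask = mask)
  bv <- p$bvals[sel]
  gv <- p$bvecs[sel, , drop = FALSE]
  Y <- matrix(aperm(dwi$data, c(4, 1, 2, 3)), nrow = d[4])[sel, vox, drop = FALSE]
  b0 <- bv == 0

  fwf_hat <- rep(NA_real_, length(vox))
  tensors <- matrix(NA_real_, length(vox), 6)
  n_failed <- 0L
  e_free <- exp(-bv * d_free)
  for (i in seq_along(vox)) {
    y <- Y[, i]
    d6_0 <- dti$tensors[i, ]
    if (any(!is.finite(d6_0)) || any(!is.finite(y))) { n_failed <- n_failed + 1L; next }
    s0_0 <- mean(y[b0])
    resid_fn <- function(par) {
      e_t <- hindered_attenuation(bv, gv, par[3:8])
      par[1] * (par[2] * e_free + (1 - par[2]) * e_t) - y
    }
    lo <- c(0, 0, rep(0, 3), rep(-d_tissue_max, 3)) # diagonal non-negative
    hi <- c(Inf, 1, rep(d_tissue_max, 6))
    d6_0 <- pmin(pmax(d6_0, lo[3:8] + 1e-9), hi[3:8] - 1e-9)
    fit <- NULL
    for (f0 in c(0.1, 0.9)) {
      cand <- lm_fit_voxel(c(s0_0, f0, d6_0), lower = lo, upper = hi,
                           resid_fn)
      if (!is.null(cand) && (is.null(fit) || cand$deviance < fit$deviance)) {
        fit <- cand
      }
    }
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    fwf_hat[i] <- min(max(fit$par[2], 0), 1)
    tensors[i, ] <- fit$par[3:8]
  }
  if (n_failed > 0L) {
    message("fit_fwf: ", n_failed, " voxel(s) did not converge (FWF set to NA)")
  }
  fwf_map <- array(NA_real_, dim = d[1:3])
  fwf_map[vox] <- fwf_hat
  structure(list(FWF = scalar_volume(fwf_map, dwi$affine, "FWF"),
                 tensors = tensors, voxels = vox, n_failed = n_failed),
            class = "fwf_fit")
}
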