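#' Diffusion acquisition protocol
#'
#' Stores the b-value/gradient-direction table and the pulse timing
#' (gradient duration delta and separation Delta). Directions for b > 0
#' must be unit vectors; near-unit rows are renormalized with a warning,
#' non-unit rows are an error.
#'
#' @param bvals numeric b-values in s/mm^2 (>= 0).
#' @param bvecs 3 x n or n x 3 matrix of gradient directions.
#' @param delta_ms gradient duration delta in ms (default 7).
#' @param Delta_ms gradient separation Delta in ms (default 24).
#' @return an object of class `acquisition_protocol` with `bvals`, `bvecs`
#'   (n x 3), and timings in seconds (`delta`, `Delta`).
#' @export
acquisition_protocol <- function(bvals, bvecs, delta_ms = 7, Delta_ms = 24) {
  bvals <- as.numeric(bvals)
  if (any(bvals < 0)) stop("negative b-values are not allowed")
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L && nrow(bvecs) == 3L) bvecs <- t(bvecs)
  stopifnot(ncol(bvecs) == 3L, nrow(bvecs) == length(bvals))
  if (delta_ms >= Delta_ms) stop("delta must be smaller than Delta")
  nrm <- sqrt(rowSums(bvecs^2))
  dwi <- bvals > 0
  bad <- dwi & abs(nrm - 1) > 0.2
  if (any(bad)) {
    stop(sum(bad), " gradient direction(s) for b > 0 are not unit vectors")
  }
  off <- dwi & abs(nrm - 1) > 1e-6
  if (any(off)) {
    warning("renormalizing ", sum(off), " near-unit gradient direction(s)")
  }
  bvecs[dwi, ] <- bvecs[dwi, , drop = FALSE] / nrm[dwi]
  bvecs[!dwi, ] <- 0
  structure(list(bvals = bvals, bvecs = bvecs,
                 delta = delta_ms / 1000, Delta = Delta_ms / 1000),
            class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  tab <- table(round(x$bvals))
  cat(sprintf("<acquisition_protocol> %d volumes (%s), delta/Delta = %g/%g ms\n",
              length(x$bvals),
              paste(sprintf("b=%s x%d", names(tab), tab), collapse = ", "),
              x$delta * 1000, x$Delta * 1000))
  invisible(x)
}

# Deterministic quasi-uniform unit directions (Fibonacci sphere)
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Multi-shell ultra-strong-gradient style protocol
#'
#' Builds a deterministic multishell protocol mirroring a Connectom-class
#' acquisition: interleaved b = 0 volumes plus shells at 500, 1200, 2400,
#' 4000 and 6000 s/mm^2, with delta/Delta = 7/24 ms.
#'
#' @param n_b0 number of b = 0 volumes.
#' @param shells named integer vector: directions per shell.
#' @param delta_ms,Delta_ms pulse timings in ms.
#' @return an [acquisition_protocol()].
#' @export
multishell_protocol <- function(n_b0 = 14,
                                shells = c(`500` = 30, `1200` = 30,
                                           `2400` = 60, `4000` = 60,
                                           `6000` = 60),
                                delta_ms = 7, Delta_ms = 24) {
  bvals <- c(rep(0, n_b0),
             rep(as.numeric(names(shells)), shells))
  dirs <- rbind(matrix(0, n_b0, 3),
                do.call(rbind, lapply(shells, fibonacci_directions)))
  acquisition_protocol(bvals, dirs, delta_ms, Delta_ms)
}
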