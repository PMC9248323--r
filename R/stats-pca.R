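#' Sampling adequacy for PCA: KMO and Bartlett's sphericity test
#'
#' The Kaiser-Meyer-Olkin statistic compares zero-order with
#' anti-image (partial) correlations; Bartlett's test is
#' `chi^2 = -(n - 1 - (2p + 5)/6) log det(R)` with `p (p - 1) / 2`
#' degrees of freedom.
#'
#' @param X numeric observation x variable matrix or data frame
#'   (complete cases; more observations than variables).
#' @return list with `kmo`, `bartlett_chisq`, `df`, `p_value`, `n`, `p`.
#' @export
pca_adequacy <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("Bartlett's test needs more observations than variables")
  R <- stats::cor(X)
  detR <- det(R)
  if (detR < .Machine$double.eps) stop("correlation matrix is singular")
  Ri <- solve(R)
  # anti-image (partial) correlations
  A <- -Ri / sqrt(outer(diag(Ri), diag(Ri)))
  off <- upper.tri(R)
  kmo <- sum(R[off]^2) / (sum(R[off]^2) + sum(A[off]^2))
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(kmo = kmo, bartlett_chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
       n = n, p = p)
}

# map a dominant variable to a component label
metric_component_label <- function(var) {
  if (var == "MTR") return("magnetization transfer")
  if (var %in% c("FA", "FR", "AD", "RD")) return("axon density")
  var
}

#' PCA with varimax rotation and regression scores
#'
#' Principal components of the centered, standardized data; components
#' retained by the Kaiser criterion (eigenvalue > 1) or a fixed count;
#' orthogonal varimax rotation (with Kaiser normalization) applied when at
#' least two components are retained; per-observation scores by the
#' regression method on the rotated loadings. Components are sign-aligned
#' so their largest-magnitude loading is positive, and labeled by the
#' dominant variable ("magnetization transfer" when MTR dominates, "axon
#' density" for the diffusion metrics).
#'
#' @param X complete numeric observation x variable table.
#' @param retain `"kaiser"` or `"fixed"`.
#' @param k number of components when `retain = "fixed"`.
#' @param rotate apply varimax when >= 2 components are retained.
#' @param loading_threshold magnitude treated as a salient loading.
#' @return list of class `pca_result`: `eigenvalues`, `loadings`
#'   (rotated), `unrotated`, `rotation` matrix, `variance_pct`, `scores`,
#'   `n_components`, `labels`, `salient` (logical matrix of loadings >=
#'   threshold in magnitude).
#' @export
pca_varimax <- function(X, retain = c("kaiser", "fixed"), k = NULL,
                        rotate = TRUE, loading_threshold = 0.5) {
  retain <- match.arg(retain)
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete (remove incomplete cases first)")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  }
  Z <- scale(X)
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  evals <- eig$values
  m <- switch(retain,
              kaiser = max(1L, sum(evals > 1)),
              fixed = { stopifnot(!is.null(k)); as.integer(k) })
  L <- eig$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(evals[seq_len(m)]), m)
  rownames(L) <- colnames(X)
  rot <- diag(m)
  Lr <- L
  if (rotate && m >= 2L) {
    vm <- stats::varimax(L, normalize = TRUE)
    Lr <- L %*% vm$rotmat
    rot <- vm$rotmat
  }
  # sign convention: dominant loading positive
  flip <- apply(Lr, 2, function(col) sign(col[which.max(abs(col))]))
  Lr <- sweep(Lr, 2, flip, "*")
  rot <- sweep(rot, 2, flip, "*")
  # regression-method scores: Z R^{-1} L; the Moore-Penrose inverse keeps
  # the scores defined when there are fewer observations than variables
  W <- MASS::ginv(R) %*% Lr
  scores <- Z %*% W
  var_pct <- colSums(Lr^2) / ncol(X) * 100
  labels <- vapply(seq_len(m), function(j)
    metric_component_label(rownames(Lr)[which.max(abs(Lr[, j]))]), character(1))
  colnames(Lr) <- colnames(scores) <- names(var_pct) <- paste0("PC", seq_len(m))
  structure(list(eigenvalues = evals, loadings = Lr,
                 unrotated = L, rotation = rot, variance_pct = var_pct,
                 scores = scores, n_components = m, labels = labels,
                 salient = abs(Lr) >= loading_threshold),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d component(s) retained (%s), variance: %s\n",
              x$n_components, paste(x$labels, collapse = ", "),
              paste(sprintf("%.1f%%", x$variance_pct), collapse = " / ")))
  invisible(x)
}
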