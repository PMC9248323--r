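#' Design for the TBCA permutation GLM
#'
#' Per-subject explanatory variables: the group indicator whose effect is
#' tested, plus nuisance covariates (age and sex by default) that are
#' regressed out. `direction = "greater"` tests patient > control,
#' `"less"` tests patient < control; each direction carries its own
#' max-mass null.
#'
#' @param cohort tibble with `group` (factor, control reference) and the
#'   covariate columns.
#' @param covariates character vector of nuisance covariate columns.
#' @param direction one-sided test direction for the group effect.
#' @return an object of class `tbca_design`.
#' @export
tbca_design <- function(cohort, covariates = c("age", "sex"),
                        direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(is.factor(cohort$group), nlevels(cohort$group) == 2L)
  fml <- stats::reformulate(c("group", covariates))
  X <- stats::model.matrix(fml, data = cohort)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  group_col <- grep("^group", colnames(X))
  stopifnot(length(group_col) == 1L)
  contrast <- as.numeric(seq_len(ncol(X)) == group_col)
  structure(list(X = X, contrast = contrast, group_col = group_col,
                 direction = direction, n = nrow(X)),
            class = "tbca_design")
}

# core vectorized GLM t-statistics: Y is n x V, returns list(t, n_degenerate)
glm_t_core <- function(Y, X, contrast) {
  n <- nrow(X)
  p <- ncol(X)
  XtXi <- solve(crossprod(X))
  A <- XtXi %*% t(X)
  cvc <- drop(t(contrast) %*% XtXi %*% contrast)
  B <- A %*% Y
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / (n - p)
  se <- sqrt(sigma2 * cvc)
  tval <- drop(contrast %*% B) / se
  degen <- !is.finite(tval)
  tval[degen] <- 0
  list(t = tval, n_degenerate = sum(degen))
}

# subject x voxel matrix from a list of scalar_volumes at given voxels
subject_matrix <- function(volumes, voxels) {
  stopifnot(length(volumes) >= 1L)
  t(vapply(volumes, function(v) v$data[voxels], numeric(length(voxels))))
}

#' Voxelwise GLM t-map for a group contrast
#'
#' Ordinary least-squares fit of voxel value on the design's explanatory
#' variables; `t = c'beta / SE(c'beta)` with residual degrees of freedom
#' `n - rank(X)`. With no covariates this equals the pooled-variance
#' two-sample t-statistic. Voxels with zero residual variance are emitted
#' as t = 0 and counted in the `n_degenerate` attribute.
#'
#' @param volumes named list of per-subject [scalar_volume()]s for one
#'   metric, in the same order as the design's rows.
#' @param design a [tbca_design()].
#' @param mask optional logical array or integer voxel indices.
#' @return a [scalar_volume()] of t-scores (patient-minus-control sign),
#'   with attribute `n_degenerate`.
#' @export
glm_tmap <- function(volumes, design, mask = NULL) {
  stopifnot(inherits(design, "tbca_design"),
            length(volumes) == design$n)
  first <- volumes[[1]]
  vox <- mask_to_voxels(mask, dim(first$data))
  Y <- subject_matrix(volumes, vox)
  fit <- glm_t_core(Y, design$X, design$contrast)
  arr <- array(NA_real_, dim = dim(first$data))
  arr[vox] <- fit$t
  out <- scalar_volume(arr, first$affine, "t")
  attr(out, "n_degenerate") <- fit$n_degenerate
  out
}

mask_to_voxels <- function(mask, grid_shape) {
  if (is.null(mask)) return(seq_len(prod(grid_shape)))
  if (is.array(mask) || is.logical(mask)) return(which(mask))
  sort(unique(as.integer(mask)))
}

permutation_set <- function(n, n_perm, seed) {
  total <- factorial(n)
  if (n <= 9 && total - 1 <= n_perm) {
    warning("n_perm (", n_perm, ") exceeds the ", total - 1,
            " distinct non-identity permutations; enumerating exhaustively")
    perms <- enumerate_permutations(n)
    # drop the identity: the observed statistic plays that role
    perms <- perms[!vapply(perms, function(p) all(p == seq_len(n)), logical(1))]
    return(perms)
  }
  with_substream(seed, "tbca_permutations",
                 lapply(seq_len(n_perm), function(i) sample.int(n)))
}

enumerate_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- enumerate_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    v <- integer(n)
    v[pos] <- n
    v[-pos] <- s
    out[[k]] <- v
  }
  out
}

#' Permutation p-map under the Freedman-Lane scheme
#'
#' Fits the reduced model (all EVs except group), permutes the residual
#' rows, refits the full model per permutation, and derives voxelwise
#' one-sided p-values `p = (1 + #\{t_perm >= t_obs\}) / (n_perm + 1)` in
#' the design's direction. The full stack of permutation t-maps is
#' returned so the identical permutation set drives the cluster-level
#' inference.
#'
#' @param volumes named list of per-subject [scalar_volume()]s (one metric).
#' @param design a [tbca_design()].
#' @param n_perm number of permutations (>= 100; capped with a warning if
#'   it exceeds the number of distinct permutations).
#' @param seed root seed (substream "tbca_permutations").
#' @param mask optional logical array or integer voxel indices.
#' @return a list of class `tbca_perm`: `p` (voxel p [scalar_volume()]),
#'   `tmap` (observed, direction-signed), `T` (the (n_perm_used + 1) x V
#'   stack, observed row first), `voxels`, `n_perm`, `design`.
#' @export
permutation_p <- function(volumes, design, n_perm = 1000, seed = 1L,
                          mask = NULL) {
  stopifnot(inherits(design, "tbca_design"), n_perm >= 100)
  first <- volumes[[1]]
  vox <- mask_to_voxels(mask, dim(first$data))
  Y <- subject_matrix(volumes, vox)
  X <- design$X
  contrast <- design$contrast
  n <- nrow(X)

  perms <- permutation_set(n, n_perm, seed)
  n_perm <- length(perms)

  # Freedman-Lane: reduced-model fit + permuted reduced-model residuals
  Z <- X[, -design$group_col, drop = FALSE]
  Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
  Fit <- Hz %*% Y
  Res <- Y - Fit

  sign_dir <- if (design$direction == "less") -1 else 1
  T <- matrix(0, n_perm + 1L, ncol(Y))
  T[1L, ] <- sign_dir * glm_t_core(Y, X, contrast)$t
  for (j in seq_len(n_perm)) {
    Yp <- Fit + Res[perms[[j]], , drop = FALSE]
    T[j + 1L, ] <- sign_dir * glm_t_core(Yp, X, contrast)$t
  }

  N <- n_perm + 1L
  # p for every row against the pooled stack (exchangeable with the
  # observed row, which counts itself): p = #\{t >= t_row\} / N
  P <- apply(T, 2, function(col) (N - rank(col, ties.method = "min") + 1) / N)

  parr <- array(NA_real_, dim = dim(first$data))
  parr[vox] <- P[1L, ]
  tarr <- array(NA_real_, dim = dim(first$data))
  tarr[vox] <- T[1L, ]
  structure(list(p = scalar_volume(parr, first$affine, "p"),
                 tmap = scalar_volume(tarr, first$affine, "t"),
                 T = T, P = P, voxels = vox, n_perm = n_perm,
                 design = design),
            class = "tbca_perm")
}

# --- cluster formation ----------------------------------------------------

# Partition suprathreshold voxels (1-based linear indices) into clusters:
# edges are 26-neighborhood spatial adjacency plus shared-streamline pairs
# from the hypervoxel template. Union-find with path halving.
cluster_partition <- function(vox, template) {
  n <- length(vox)
  if (n == 0L) return(integer(0))
  gs <- template$grid_shape
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }

  lin0 <- vox - 1L
  x <- lin0 %% gs[1]
  y <- (lin0 %/% gs[1]) %% gs[2]
  z <- lin0 %/% (gs[1] * gs[2])
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 &
                 (offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
                    (offs[, 2] == 0 & offs[, 1] > 0)))), , drop = FALSE]
  for (r in seq_len(nrow(offs))) {
    nx <- x + offs[r, 1]; ny <- y + offs[r, 2]; nz <- z + offs[r, 3]
    ok <- nx >= 0 & nx < gs[1] & ny >= 0 & ny < gs[2] & nz >= 0 & nz < gs[3]
    nlin <- 1L + nx + gs[1] * (ny + gs[2] * nz)
    j <- match(nlin, vox)
    hit <- which(ok & !is.na(j))
    for (i in hit) union_(i, j[i])
  }

  # shared-streamline edges: all suprathreshold voxels crossed by one
  # streamline collapse into one component (star union)
  vs <- template$voxel_streamlines[as.character(vox)]
  has <- !vapply(vs, is.null, logical(1))
  if (any(has)) {
    pos <- rep.int(which(has), lengths(vs[has]))
    sid <- unlist(vs[has], use.names = FALSE)
    groups <- split(pos, sid)
    for (g in groups) {
      if (length(g) > 1L) for (i in g[-1L]) union_(g[1L], i)
    }
  }

  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Form tract-aware clusters from thresholded statistic maps
#'
#' Suprathreshold voxels (permutation p below `p_thr`) are the nodes;
#' edges join voxels that are 26-neighbors or share a common streamline in
#' the hypervoxel template; clusters are the connected components. Each
#' cluster's mass is the sum of its voxels' (direction-signed) t-scores.
#' FWE-corrected p-values are left to [fwe_correct()].
#'
#' @param tmap t-score [scalar_volume()] (direction-signed).
#' @param pmap voxel p [scalar_volume()] on the same grid.
#' @param template a [hypervoxel_template()][build_template].
#' @param p_thr cluster-forming voxel threshold on the permutation p-map.
#' @return tibble with one row per cluster: `cluster_id`, `n_voxels`,
#'   `mass`, and list-columns `voxels` (linear indices) and `streamlines`
#'   (member streamline ids). Zero rows when nothing is suprathreshold.
#' @export
form_clusters <- function(tmap, pmap, template, p_thr = 0.01) {
  check_same_grid(tmap, pmap, "t and p maps")
  stopifnot(identical(dim(tmap$data), as.integer(template$grid_shape)) ||
              all(dim(tmap$data) == template$grid_shape))
  vox <- which(pmap$data <= p_thr)
  clusters_from_voxels(vox, tmap$data[vox], template)
}

clusters_from_voxels <- function(vox, tvals, template) {
  if (length(vox) == 0L) {
    return(tibble::tibble(cluster_id = integer(0), n_voxels = integer(0),
                          mass = numeric(0), voxels = list(),
                          streamlines = list()))
  }
  comp <- cluster_partition(vox, template)
  ids <- sort(unique(comp))
  rows <- lapply(ids, function(k) {
    sel <- comp == k
    v <- vox[sel]
    sl <- sort(unique(unlist(template$voxel_streamlines[as.character(v)],
                             use.names = FALSE)))
    tibble::tibble(cluster_id = k, n_voxels = sum(sel), mass = sum(tvals[sel]),
                   voxels = list(v), streamlines = list(sl %||% integer(0)))
  })
  out <- do.call(rbind, rows)
  out[order(-out$mass), ]
}

#' Family-wise error correction by the maximum cluster mass
#'
#' Re-forms suprathreshold clusters for every stored permutation under the
#' same threshold, records each permutation's maximum cluster mass, and
#' assigns `p_fwe = (1 + #\{max_mass_perm >= mass\}) / (n_perm + 1)`.
#' The uncorrected cluster p compares the mass against the pooled
#' distribution of all permutation cluster masses (capped at `p_fwe`).
#'
#' @param clusters tibble from [form_clusters()].
#' @param perm a `tbca_perm` object from [permutation_p()].
#' @param template the [hypervoxel_template()][build_template] used for
#'   cluster formation.
#' @param p_thr the same cluster-forming threshold.
#' @param alpha significance level recorded in the output.
#' @return the cluster tibble with `p_uncorrected`, `p_fwe` and
#'   `significant` columns added, plus attribute `null_max_mass`.
#' @export
fwe_correct <- function(clusters, perm, template, p_thr = 0.01, alpha = 0.05) {
  stopifnot(inherits(perm, "tbca_perm"))
  n_perm <- perm$n_perm
  null_max <- numeric(n_perm)
  null_all <- vector("list", n_perm)
  for (j in seq_len(n_perm)) {
    supra <- perm$P[j + 1L, ] <= p_thr
    if (!any(supra)) { null_all[[j]] <- numeric(0); next }
    cl <- clusters_from_voxels(perm$voxels[supra], perm$T[j + 1L, supra],
                               template)
    null_max[j] <- max(cl$mass)
    null_all[[j]] <- cl$mass
  }
  pooled <- unlist(null_all, use.names = FALSE)
  if (nrow(clusters) > 0L) {
    clusters$p_fwe <- vapply(clusters$mass, function(m)
      (1 + sum(null_max >= m)) / (n_perm + 1), numeric(1))
    p_unc <- vapply(clusters$mass, function(m)
      (1 + sum(pooled >= m)) / (1 + length(pooled)), numeric(1))
    clusters$p_uncorrected <- pmin(p_unc, clusters$p_fwe)
    clusters$significant <- clusters$p_fwe < alpha
  } else {
    clusters$p_fwe <- numeric(0)
    clusters$p_uncorrected <- numeric(0)
    clusters$significant <- logical(0)
  }
  attr(clusters, "null_max_mass") <- null_max
  clusters
}

#' Run a complete tract-based cluster analysis
#'
#' Permutation GLM on the template's voxels, voxel thresholding at
#' `p_thr`, streamline-aware cluster formation, and max-mass FWE
#' correction, in one call.
#'
#' @param volumes named list of per-subject [scalar_volume()]s for the
#'   analyzed metric, ordered as the cohort rows.
#' @param design a [tbca_design()] (carries the test direction).
#' @param template a [hypervoxel_template()][build_template].
#' @param p_thr cluster-forming threshold on the permutation p-map.
#' @param n_perm permutations.
#' @param alpha FWE significance level.
#' @param seed root seed.
#' @return a list of class `tbca_result`: `clusters` tibble (with
#'   `p_fwe`), `perm` (the permutation stack), `template`, and the call
#'   parameters.
#' @export
tbca_run <- function(volumes, design, template, p_thr = 0.01, n_perm = 1000,
                     alpha = 0.05, seed = 1L) {
  vox <- as.integer(names(template$voxel_streamlines))
  perm <- permutation_p(volumes, design, n_perm = n_perm, seed = seed,
                        mask = vox)
  clusters <- form_clusters(perm$tmap, perm$p, template, p_thr = p_thr)
  clusters <- fwe_correct(clusters, perm, template, p_thr = p_thr, alpha = alpha)
  structure(list(clusters = clusters, perm = perm, template = template,
                 p_thr = p_thr, alpha = alpha, n_perm = perm$n_perm),
            class = "tbca_result")
}

#' @export
print.tbca_result <- function(x, ...) {
  cat(sprintf("<tbca_result> %d cluster(s), %d significant at FWE alpha = %g (%d permutations)\n",
              nrow(x$clusters), sum(x$clusters$significant), x$alpha, x$n_perm))
  invisible(x)
}

#' Per-subject mean metric inside the significant-cluster ROI
#'
#' The significant clusters are unioned and binarized into a single ROI
#' mask; each subject's mean metric value inside the mask is returned.
#'
#' @param result a `tbca_result` (or a cluster tibble with `significant`).
#' @param volumes named list of per-subject [scalar_volume()]s.
#' @return tibble with `subject_id` and `roi_mean`.
#' @export
cluster_roi_means <- function(result, volumes) {
  clusters <- if (inherits(result, "tbca_result")) result$clusters else result
  sig <- clusters[clusters$significant, , drop = FALSE]
  if (nrow(sig) == 0L) stop("no significant clusters: ROI mask is empty")
  roi <- sort(unique(unlist(sig$voxels, use.names = FALSE)))
  tibble::tibble(
    subject_id = if (is.null(names(volumes))) seq_along(volumes) else names(volumes),
    roi_mean = vapply(volumes, function(v) mean(v$data[roi]), numeric(1)))
}
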