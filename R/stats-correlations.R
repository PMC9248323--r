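# Partial Pearson correlation of x and y given covariate columns in Z,
# with t-based p-value on n - 2 - k degrees of freedom. With no
# covariates this is the plain Pearson correlation.
partial_pearson <- function(x, y, Z = NULL) {
  n <- length(x)
  k <- if (is.null(Z)) 0L else ncol(Z)
  if (k > 0L) {
    X <- cbind(1, Z)
    x <- stats::lm.fit(X, x)$residuals
    y <- stats::lm.fit(X, y)$residuals
  }
  r <- stats::cor(x, y)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df)
}

#' Segment-wise Spearman correlation family with Bonferroni correction
#'
#' For each segment, the Spearman correlation between `x` and `y`
#' (computed as the Pearson correlation of ranks, with a t-approximation
#' for the p-value). When covariates are supplied, the partial Spearman
#' correlation is the partial Pearson correlation on rank-transformed
#' data; with an empty covariate set this reduces exactly to the plain
#' Spearman path. Bonferroni correction multiplies the two-tailed p by the
#' family size and caps at 1.
#'
#' @param data data frame in long format.
#' @param x,y column names of the two correlated variables.
#' @param segment column name of the family index (default "segment").
#' @param covariates optional character vector of covariate columns
#'   (e.g. `c("icv", "dbs")`).
#' @param m family size for Bonferroni (defaults to the number of
#'   segments present).
#' @return tibble with `segment`, `n`, `r`, `p`, `p_bonferroni`.
#' @export
spearman_family <- function(data, x, y, segment = "segment",
                            covariates = NULL, m = NULL) {
  segs <- sort(unique(data[[segment]]))
  if (is.null(m)) m <- length(segs)
  rows <- lapply(segs, function(s) {
    d <- data[data[[segment]] == s, , drop = FALSE]
    cols <- c(x, y, covariates)
    d <- d[stats::complete.cases(d[cols]), , drop = FALSE]
    n <- nrow(d)
    if (n < 5L) stop("fewer than 5 complete pairs in segment ", s)
    xv <- d[[x]]; yv <- d[[y]]
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
      stop("constant input in segment ", s)
    }
    Z <- if (length(covariates)) {
      apply(as.matrix(d[covariates]), 2, rank)
    } else NULL
    res <- partial_pearson(rank(xv), rank(yv), Z)
    tibble::tibble(segment = s, n = n, r = res$r, p = res$p,
                   p_bonferroni = pmin(1, m * res$p))
  })
  do.call(rbind, rows)
}
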