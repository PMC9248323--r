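#' Remove within-group outliers beyond 3 standard deviations
#'
#' Values more than 3 SDs from their own group's mean are removed;
#' a point extreme overall but typical within its group is retained.
#'
#' @param data data frame.
#' @param value column name of the dependent variable.
#' @param group column name of the grouping factor (>= 3 values per group).
#' @param sd_limit threshold in within-group SD units.
#' @return list with `data` (filtered) and `removed` (log tibble with the
#'   removed rows' group, value and z-score).
#' @export
remove_outliers <- function(data, value, group, sd_limit = 3) {
  v <- data[[value]]
  g <- data[[group]]
  stopifnot(!is.null(v), !is.null(g), all(table(g) >= 3))
  z <- stats::ave(v, g, FUN = function(x) (x - mean(x)) / stats::sd(x))
  drop <- abs(z) > sd_limit
  removed <- tibble::tibble(row = which(drop), group = as.character(g[drop]),
                            value = v[drop], z = z[drop])
  list(data = data[!drop, , drop = FALSE], removed = removed)
}

#' Screen candidate covariates by correlation with the outcome
#'
#' Candidates whose absolute Pearson correlation with the outcome exceeds
#' `threshold` (a moderate relationship) are selected for the ANCOVA.
#'
#' @param outcome numeric outcome vector.
#' @param candidates data frame of candidate covariates (complete pairs
#'   used).
#' @param threshold absolute-correlation cutoff (default 0.3; strict
#'   inequality).
#' @return tibble with `covariate`, `r`, `selected`.
#' @export
screen_covariates <- function(outcome, candidates, threshold = 0.3) {
  rs <- vapply(candidates, function(x)
    stats::cor(outcome, x, use = "complete.obs"), numeric(1))
  tibble::tibble(covariate = names(candidates), r = rs,
                 selected = abs(rs) > threshold)
}

#' ANCOVA on component scores with Type III sums of squares
#'
#' Ordinary least squares with sum-to-zero factor coding and Type III
#' F-tests (matching SPSS-style ANCOVA output for unbalanced groups).
#' The model always contains the main effects of `group` and `segment`;
#' interactions and covariates are added as requested. Adjusted
#' group x segment means are evaluated at the covariate means.
#'
#' @param scores data frame with one row per subject x segment: columns
#'   `group` (2-level factor), `segment` (factor or integer 1-7), `score`,
#'   plus any covariate columns.
#' @param covariates character vector of covariate columns.
#' @param interactions character vector of extra interaction terms, e.g.
#'   `c("group:segment", "group:age")` (`group:segment` is the default).
#' @return list of class `ancova_result`: `table` (term, F, df1, df2, p),
#'   `adjusted_means` tibble, and the fitted `model`.
#' @export
ancova_scores <- function(scores,
                          covariates = character(0),
                          interactions = "group:segment") {
  df <- as.data.frame(scores)
  df$group <- droplevels(as.factor(df$group))
  df$segment <- as.factor(df$segment)
  stopifnot(nlevels(df$group) == 2L, "score" %in% names(df))
  if (nlevels(df$segment) < 2L) {
    # degenerate single-segment input: plain between-group ANCOVA
    interactions <- setdiff(interactions, grep("segment", interactions,
                                               value = TRUE))
    terms <- c("group", covariates, interactions)
  } else {
    terms <- c("group", "segment", covariates, interactions)
  }
  fml <- stats::reformulate(terms, response = "score")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  model <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(model)))) {
    stop("rank-deficient ANCOVA model; aliased terms: ",
         paste(names(stats::coef(model))[is.na(stats::coef(model))],
               collapse = ", "))
  }
  a3 <- car::Anova(model, type = 3)
  keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
  tab <- tibble::tibble(term = rownames(a3)[keep],
                        sum_sq = a3$`Sum Sq`[keep],
                        df1 = a3$Df[keep],
                        df2 = a3$Df[rownames(a3) == "Residuals"],
                        F = a3$`F value`[keep],
                        p = a3$`Pr(>F)`[keep])
  grid <- expand.grid(group = levels(df$group),
                      segment = levels(droplevels(df$segment)),
                      KEEP.OUT.ATTRS = FALSE)
  if (!"segment" %in% terms) grid$segment <- NULL
  grid <- unique(grid)
  for (cv in covariates) grid[[cv]] <- mean(df[[cv]])
  grid$adjusted_mean <- as.numeric(stats::predict(model, newdata = grid))
  structure(list(table = tab, adjusted_means = tibble::as_tibble(grid),
                 model = model, data = df, covariates = covariates),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Simple-slopes moderation: the group effect within each segment
#'
#' For each segment level the model is refit with that segment as the
#' reference level and treatment-coded factors, so the `group` coefficient
#' is the conditional patient-minus-control difference at that segment
#' with covariates centered at their means (so the conditional effect is
#' evaluated there even when group-by-covariate interactions are in the
#' model); its SE, t and p come from the ordinary least-squares fit.
#'
#' @param ancova an `ancova_result` whose model contains `group:segment`
#'   (error otherwise).
#' @return tibble with `segment`, `beta`, `se`, `t`, `p`.
#' @export
simple_slopes <- function(ancova) {
  stopifnot(inherits(ancova, "ancova_result"))
  model <- ancova$model
  if (!any(grepl("group:segment|segment:group",
                 attr(stats::terms(model), "term.labels")))) {
    stop("model does not contain a group:segment interaction")
  }
  df <- ancova$data
  fml <- stats::formula(model)
  old <- options(contrasts = c("contr.treatment", "contr.poly"))
  on.exit(options(old))
  rows <- lapply(levels(df$segment), function(s) {
    d <- df
    for (cv in ancova$covariates) d[[cv]] <- d[[cv]] - mean(d[[cv]])
    d$segment <- stats::relevel(d$segment, ref = s)
    fit <- stats::lm(fml, data = d)
    cf <- summary(fit)$coefficients
    row <- grep("^group", rownames(cf))[1]
    tibble::tibble(segment = s, beta = cf[row, 1], se = cf[row, 2],
                   t = cf[row, 3], p = cf[row, 4])
  })
  do.call(rbind, rows)
}
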