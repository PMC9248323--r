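test_that("outlier removal is within-group: far point out, 2.9 SD in, shifted groups kept", {
  withr::with_seed(1, base <- as.numeric(scale(rnorm(40))))
  d <- tibble::tibble(
    value = c(base, 10,          # group a: one point far beyond 3 within-group SD
              base, 2.9,         # group b: borderline point stays
              base + 100),       # group c: extreme overall, typical within group
    group = rep(c("a", "b", "c"), c(41, 41, 40)))
  out <- remove_outliers(d, "value", "group")
  expect_equal(nrow(out$removed), 1L)
  expect_equal(out$removed$group, "a")
  expect_gt(out$removed$z, 3)
  expect_true(2.9 %in% out$data$value)
  expect_equal(sum(out$data$group == "c"), 40L)
})

test_that("adequacy: identity correlation gives zero chi-square; p = 2 closed form; singular errors", {
  withr::with_seed(4, X <- matrix(rnorm(600), 100, 6))
  # force an exactly identity correlation via whitening
  Xw <- scale(X %*% solve(chol(cov(X))))
  adq <- pca_adequacy(Xw)
  expect_equal(adq$bartlett_chisq, 0, tolerance = 1e-8)
  expect_equal(adq$df, 15)

  withr::with_seed(5, {
    x <- rnorm(60)
    y <- 0.6 * x + 0.8 * rnorm(60)
  })
  adq2 <- pca_adequacy(cbind(x, y))
  r <- cor(x, y)
  expect_equal(adq2$bartlett_chisq, -(60 - 1 - 9 / 6) * log(1 - r^2),
               tolerance = 1e-10)
  expect_equal(adq2$df, 1)
  expect_error(pca_adequacy(cbind(x, x)), "singular")
})

test_that("varimax preserves communalities; a single component is unrotated", {
  withr::with_seed(6, {
    F2 <- matrix(rnorm(400), 200, 2)
    L <- rbind(c(0.9, 0), c(0.85, 0.1), c(0.8, -0.1), c(0.1, 0.9), c(0, 0.85))
    X <- F2 %*% t(L) + matrix(rnorm(1000, sd = 0.4), 200, 5)
  })
  colnames(X) <- paste0("v", 1:5)
  res <- pca_varimax(X, retain = "fixed", k = 2)
  expect_equal(rowSums(res$loadings^2), rowSums(res$unrotated^2),
               tolerance = 1e-10)
  expect_equal(crossprod(res$rotation), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # scores have zero mean; unrotated retained scores are uncorrelated
  expect_equal(colMeans(res$scores), c(PC1 = 0, PC2 = 0), tolerance = 1e-10)
  pcs <- scale(X, scale = TRUE) %*% res$unrotated
  expect_lt(abs(cor(pcs)[1, 2]), 1e-10)

  res1 <- pca_varimax(X, retain = "fixed", k = 1)
  expect_equal(abs(res1$loadings[, 1]), abs(res1$unrotated[, 1]))
  expect_error(pca_varimax(cbind(X, const = 0)), "zero-variance")
})

test_that("Kaiser retention recovers a planted two-component structure", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      F2 <- matrix(rnorm(343 * 2), 343, 2)
      # four co-loading metrics plus one dominating its own component with
      # a weak secondary loading (an isolated variable has population
      # eigenvalue exactly 1, so a mild cross-loading is what makes the
      # second component retainable)
      L <- rbind(c(0.8, 0), c(0.8, 0), c(0.8, 0), c(0.8, -0.3), c(0, 0.9))
      E <- matrix(rnorm(343 * 5), 343, 5) %*%
        diag(sqrt(pmax(1 - rowSums(L^2), 0.05)))
      X <- F2 %*% t(L) + E
    })
    colnames(X) <- paste0("v", 1:5)
    pca_varimax(X, retain = "kaiser")$n_components == 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("planted salient loadings are recovered at the cognitive-battery scale", {
  hits <- vapply(1:20, function(s) {
    co <- tibble::tibble(id = sprintf("s%02d", 1:21))
    loading <- c(rep(0.9, 10), rep(0, 3))
    sc <- make_cognitive_scores(co, loading = loading, noise_sd = 0.4, seed = s)
    X <- as.matrix(sc[, -1])
    res <- pca_varimax(X, retain = "fixed", k = 1)
    all(res$salient[1:10, 1]) && !any(res$salient[11:13, 1])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("covariate screening uses |r| > 0.3 strictly and handles the null", {
  # constructed exact correlations around the threshold
  make_pair <- function(r, n = 2000, seed = 1) {
    withr::with_seed(seed, {
      x <- scale(rnorm(n))[, 1]
      e <- scale(resid(lm(rnorm(n) ~ x)))[, 1]
    })
    list(x = x, y = r * x + sqrt(1 - r^2) * e)
  }
  p1 <- make_pair(0.31); p2 <- make_pair(0.29); p3 <- make_pair(-0.35)
  scr <- screen_covariates(p1$y, data.frame(a = p1$x))
  expect_true(scr$selected)
  expect_false(screen_covariates(p2$y, data.frame(a = p2$x))$selected)
  expect_true(screen_covariates(p3$y, data.frame(a = p3$x))$selected)
  # independent candidates rarely pass at large n
  sel <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      y <- rnorm(200)
      cand <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
    })
    any(screen_covariates(y, cand)$selected)
  }, logical(1))
  expect_gte(mean(!sel), 0.9)
})

test_that("balanced two-group ANCOVA: group F equals the squared two-sample t", {
  withr::with_seed(11, {
    d <- data.frame(subject = 1:32, segment = 1)
    d$group <- factor(rep(c("control", "patient"), each = 16),
                      levels = c("control", "patient"))
    d$score <- rnorm(nrow(d)) + 0.4 * (d$group == "patient")
  })
  fit <- ancova_scores(d, interactions = character(0))
  tt <- t.test(score ~ group, data = d, var.equal = TRUE)
  Fg <- fit$table$F[fit$table$term == "group"]
  expect_equal(Fg, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("fully balanced orthogonal design: Type III equals Type I sums of squares", {
  withr::with_seed(12, {
    d <- expand.grid(subject = 1:12, segment = 1:7)
    d$group <- factor(rep(c("control", "patient"), each = 6)[d$subject],
                      levels = c("control", "patient"))
    d$score <- rnorm(nrow(d)) + 0.5 * (d$group == "patient") +
      0.2 * as.numeric(d$segment)
  })
  fit <- ancova_scores(d, interactions = "group:segment")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  a1 <- anova(lm(score ~ group * factor(segment), data = d)) # sequential
  for (trm in c("group", "segment", "group:segment")) {
    t1 <- sub("segment", "factor(segment)", trm, fixed = TRUE)
    expect_equal(fit$table$sum_sq[fit$table$term == trm],
                 a1$`Sum Sq`[rownames(a1) == t1], tolerance = 1e-10)
  }
})

test_that("ANCOVA F statistics are invariant to affine rescaling of covariates", {
  withr::with_seed(13, {
    d <- expand.grid(subject = 1:14, segment = 1:7)
    d$group <- factor(rep(c("control", "patient"), each = 7)[d$subject])
    d$age <- rep(runif(14, 25, 70), 7)
    d$score <- rnorm(nrow(d)) - 0.02 * d$age
  })
  f1 <- ancova_scores(d, covariates = "age", interactions = "group:segment")
  d2 <- d; d2$age <- (d2$age - 47) / 12
  f2 <- ancova_scores(d2, covariates = "age", interactions = "group:segment")
  expect_equal(f1$table$F, f2$table$F, tolerance = 1e-8)
})

test_that("simple slopes equal raw group differences in balanced data and recover planted shifts", {
  withr::with_seed(14, {
    d <- expand.grid(subject = 1:20, segment = 1:7)
    d$group <- factor(rep(c("control", "patient"), each = 10)[d$subject],
                      levels = c("control", "patient"))
    d$score <- rnorm(nrow(d))
    d$score[d$group == "patient" & d$segment == 3] <-
      d$score[d$group == "patient" & d$segment == 3] + 1
  })
  fit <- ancova_scores(d, interactions = "group:segment")
  ss <- simple_slopes(fit)
  raw <- tapply(d$score, list(d$segment, d$group), mean)
  expect_equal(ss$beta, unname(raw[, "patient"] - raw[, "control"]),
               tolerance = 1e-10)
  # sum of segment betas = 7 x overall adjusted group effect
  overall <- mean(raw[, "patient"] - raw[, "control"])
  expect_equal(sum(ss$beta), 7 * overall, tolerance = 1e-10)
  expect_error(simple_slopes(ancova_scores(d, interactions = character(0))),
               "interaction")
})

test_that("planted opposite shifts in segments 1 and 7 are the ones detected", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(100 + s, {
      d <- expand.grid(subject = 1:49, segment = 1:7)
      d$group <- factor(rep(c("control", "patient"), c(24, 25))[d$subject],
                        levels = c("control", "patient"))
      d$score <- rnorm(nrow(d))
      pat <- d$group == "patient"
      d$score[pat & d$segment == 1] <- d$score[pat & d$segment == 1] + 1
      d$score[pat & d$segment == 7] <- d$score[pat & d$segment == 7] - 1
    })
    ss <- simple_slopes(ancova_scores(d, interactions = "group:segment"))
    ss$p[1] < 0.05 && ss$beta[1] > 0 && ss$p[7] < 0.05 && ss$beta[7] < 0 &&
      all(ss$p[2:6] > 0.05 | abs(ss$beta[2:6]) < 0.5)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("spearman family: monotone relation, Bonferroni cap, exact reduction, confounds", {
  d <- tibble::tibble(segment = rep(1:7, each = 10),
                      x = rep(1:10, 7))
  d$y <- exp(d$x) # strictly monotone
  fam <- spearman_family(d, "x", "y")
  expect_equal(fam$r, rep(1, 7))
  expect_true(all(fam$p_bonferroni == pmin(1, 7 * fam$p)))
  # empty covariate set reduces exactly to plain Spearman
  withr::with_seed(20, {
    d$y <- rnorm(70) + 0.5 * d$x
  })
  plain <- spearman_family(d, "x", "y")
  partial0 <- spearman_family(d, "x", "y", covariates = character(0))
  expect_equal(plain, partial0)
  # x and y linked only through z: partial r collapses toward zero
  med_r <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      z <- rnorm(200)
      dd <- tibble::tibble(segment = 1, x = z + rnorm(200),
                           y = z + rnorm(200), z = z)
    })
    abs(spearman_family(dd, "x", "y", covariates = "z", m = 1)$r)
  }, numeric(1))
  expect_lt(stats::median(med_r), 0.15)
  # constant input rejected
  dc <- tibble::tibble(segment = 1, x = rep(1, 10), y = 1:10)
  expect_error(spearman_family(dc, "x", "y", m = 1), "constant")
})

test_that("disease burden score is the exact age x (CAG - 35.5) product", {
  expect_equal(dbs(40, 40.5), 200)
  expect_equal(dbs(63, 35.5), 0)
  expect_equal(dbs(0, 42), 0)
  expect_error(dbs(40, -1))
})

test_that("Bonferroni decisions are invariant to segment ordering", {
  withr::with_seed(30, {
    d <- tibble::tibble(segment = rep(1:7, each = 12),
                        x = rnorm(84))
    d$y <- d$x * rep(runif(7, 0, 0.8), each = 12) + rnorm(84)
  })
  f1 <- spearman_family(d, "x", "y")
  d2 <- d[order(-d$segment), ]
  f2 <- spearman_family(d2, "x", "y")
  expect_equal(f1, f2)
})

test_that("CAG-MTR correlations strengthen after partialling ICV and disease burden", {
  # the generator's age slope and group-by-age interaction dilute the raw
  # CAG association; DBS carries the age variance, so partialling it out
  # recovers the mutation link
  res <- vapply(1:10, function(s) {
    cfg <- phantom_config(grid_shape = c(24, 24, 24),
                          n_streamlines_per_bundle = 100, seed = 900 + s)
    ch <- make_cohort(14, 2, effect_spec(), cfg, metrics = "MTR")
    tab <- build_tractometry_table(ch, metrics = "MTR")
    d <- merge(tab, ch$cohort, by.x = "subject_id", by.y = "id")
    d <- d[d$group == "patient", ]
    raw <- spearman_family(d, "value", "cag")
    part <- spearman_family(d, "value", "cag", covariates = c("icv", "dbs"))
    c(raw = mean(raw$r), part = mean(part$r))
  }, numeric(2))
  expect_gte(mean(res["part", ] > res["raw", ]), 0.8)
  expect_true(all(res["part", ] > 0))
})
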