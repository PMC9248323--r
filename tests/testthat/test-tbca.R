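# helpers to build small voxel-value cohorts ------------------------------

toy_volumes <- function(values_by_subject, dim = c(4, 4, 1)) {
  lapply(values_by_subject, function(v)
    scalar_volume(array(v, dim = dim), diag(4), "m"))
}

toy_cohort <- function(n1, n2, ages = NULL, sexes = NULL) {
  n <- n1 + n2
  tibble::tibble(
    id = sprintf("s%02d", 1:n),
    group = factor(rep(c("control", "patient"), c(n1, n2)),
                   levels = c("control", "patient")),
    age = ages %||% seq(30, 60, length.out = n),
    sex = factor(sexes %||% rep(c("F", "M"), length.out = n)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("with no covariates the GLM t equals the pooled two-sample t", {
  withr::with_seed(10, {
    co <- toy_cohort(6, 6)
    vols <- toy_volumes(lapply(1:12, function(i) rnorm(16, mean = (i > 6) * 0.5)))
  })
  des <- tbca_design(co, covariates = character(0))
  tmap <- glm_tmap(vols, des)
  Y <- sapply(vols, function(v) as.vector(v$data))
  oracle <- apply(Y, 1, function(y) {
    unname(stats::t.test(y[7:12], y[1:6], var.equal = TRUE)$statistic)
  })
  expect_equal(as.vector(tmap$data), oracle, tolerance = 1e-10)
})

test_that("null data give near-zero t and constant maps are flagged degenerate", {
  co <- toy_cohort(5, 5)
  vols <- toy_volumes(rep(list(rep(2, 16)), 10))
  des <- tbca_design(co, covariates = character(0))
  tmap <- glm_tmap(vols, des)
  expect_true(all(tmap$data == 0))
  expect_equal(attr(tmap, "n_degenerate"), 16L)
})

test_that("permutation p attains its lower bound and is seed-reproducible", {
  withr::with_seed(2, {
    co <- toy_cohort(5, 5)
    vals <- lapply(1:10, function(i) rnorm(16) + (i > 5) * 5) # huge effect
    vols <- toy_volumes(vals)
  })
  des <- tbca_design(co, covariates = character(0))
  pr <- permutation_p(vols, des, n_perm = 200, seed = 4)
  expect_equal(min(pr$p$data), 1 / 201)
  pr2 <- permutation_p(vols, des, n_perm = 200, seed = 4)
  expect_identical(pr$P, pr2$P)
})

test_that("Freedman-Lane with no covariates reduces to direct label permutation", {
  withr::with_seed(6, {
    co <- toy_cohort(5, 5)
    vols <- toy_volumes(lapply(1:10, function(i) rnorm(16)))
  })
  des <- tbca_design(co, covariates = character(0))
  pr <- permutation_p(vols, des, n_perm = 150, seed = 9)
  # direct oracle: permute the subject labels with the same permutation set
  Y <- t(sapply(vols, function(v) as.vector(v$data)))
  X <- des$X
  perms <- withr::with_seed(substream_seed(9, "tbca_permutations"),
                            lapply(1:150, function(i) sample.int(10)))
  Tdir <- matrix(0, 151, 16)
  tstat <- function(Ymat) {
    apply(Ymat, 2, function(y)
      unname(stats::t.test(y[6:10], y[1:5], var.equal = TRUE)$statistic))
  }
  Tdir[1, ] <- tstat(Y)
  for (j in 1:150) Tdir[j + 1, ] <- tstat(Y[perms[[j]], ])
  expect_equal(pr$T, Tdir, tolerance = 1e-10)
})

test_that("n_perm beyond the distinct permutations is capped with enumeration", {
  withr::with_seed(3, {
    co <- toy_cohort(2, 2)
    vols <- toy_volumes(lapply(1:4, function(i) rnorm(4, (i > 2))), dim = c(2, 2, 1))
  })
  des <- tbca_design(co, covariates = character(0))
  expect_warning(pr <- permutation_p(vols, des, n_perm = 1000, seed = 1),
                 "exhaustiv")
  expect_equal(pr$n_perm, factorial(4) - 1)
})

test_that("adjacent voxels cluster together; streamline bridging merges distant blobs", {
  gs <- c(25, 3, 3)
  tarr <- array(0, gs); parr <- array(1, gs)
  # two blobs 20 voxels apart along x
  tarr[c(1, 2), 2, 2] <- 5; parr[c(1, 2), 2, 2] <- 0.001
  tarr[22, 2, 2] <- 4; parr[22, 2, 2] <- 0.001
  tmap <- scalar_volume(tarr, diag(4), "t")
  pmap <- scalar_volume(parr, diag(4), "p")
  bridge <- matrix(c(0, 1, 1,
                     21, 1, 1), 2, 3, byrow = TRUE)
  far <- matrix(c(0, 0, 0, 0.5, 0, 0), 2, 3, byrow = TRUE)
  with_bridge <- build_template(tractogram(list(bridge)), gs, diag(4))
  without <- build_template(tractogram(list(far)), gs, diag(4))
  cl1 <- form_clusters(tmap, pmap, with_bridge, p_thr = 0.01)
  expect_equal(nrow(cl1), 1L)
  expect_equal(cl1$n_voxels, 3L)
  expect_equal(cl1$mass, 14)
  cl2 <- form_clusters(tmap, pmap, without, p_thr = 0.01)
  expect_equal(nrow(cl2), 2L)
  expect_equal(sort(cl2$n_voxels), c(1L, 2L))
})

test_that("cluster partition matches a brute-force graph search on random instances", {
  gs <- c(10, 10, 10)
  for (rep in 1:20) {
    withr::with_seed(1000 + rep, {
      vox <- sort(sample(1000, 60))
      sls <- lapply(1:8, function(i) {
        n <- sample(2:5, 1)
        matrix(runif(n * 3, 0, 9), n, 3)
      })
    })
    tmpl <- build_template(tractogram(sls), gs, diag(4))
    part <- hdwm:::cluster_partition(vox, tmpl)

    # brute force: explicit edge list + breadth-first search
    coord <- cbind((vox - 1) %% 10, ((vox - 1) %/% 10) %% 10, (vox - 1) %/% 100)
    n <- length(vox)
    adj <- matrix(FALSE, n, n)
    for (i in 1:n) for (j in 1:n) {
      if (i != j && all(abs(coord[i, ] - coord[j, ]) <= 1)) adj[i, j] <- TRUE
    }
    for (sid in names(tmpl$streamline_voxels)) {
      members <- which(vox %in% tmpl$streamline_voxels[[sid]])
      if (length(members) > 1) adj[members, members] <- TRUE
    }
    bfs_label <- rep(NA_integer_, n)
    comp <- 0L
    for (s in 1:n) {
      if (!is.na(bfs_label[s])) next
      comp <- comp + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (!is.na(bfs_label[v])) next
        bfs_label[v] <- comp
        queue <- c(queue, which(adj[v, ] & is.na(bfs_label)))
      }
    }
    # identical partitions up to label renaming
    expect_equal(length(unique(part)), length(unique(bfs_label)))
    expect_true(all(tapply(bfs_label, part, function(x) length(unique(x))) == 1))
  }
})

test_that("partition is invariant to voxel order and streamline relabeling", {
  gs <- c(10, 10, 10)
  withr::with_seed(77, {
    vox <- sort(sample(1000, 50))
    sls <- lapply(1:6, function(i) matrix(runif(9, 0, 9), 3, 3))
  })
  tmpl <- build_template(tractogram(sls), gs, diag(4))
  p1 <- hdwm:::cluster_partition(vox, tmpl)
  ord <- withr::with_seed(1, sample(length(vox)))
  p2 <- hdwm:::cluster_partition(vox[ord], tmpl)
  # same groupings after undoing the reordering
  expect_true(all(tapply(p2[order(ord)], p1, function(x) length(unique(x))) == 1))
  tmpl2 <- build_template(tractogram(rev(sls)), gs, diag(4))
  p3 <- hdwm:::cluster_partition(vox, tmpl2)
  expect_true(all(tapply(p3, p1, function(x) length(unique(x))) == 1))
})

test_that("lowering the cluster-forming threshold never grows a cluster", {
  ch <- tiny_cohort()
  des <- tbca_design(ch$cohort, direction = "less")
  vols <- metric_volumes(ch, "MTR")
  vox <- as.integer(names(ch$template$voxel_streamlines))
  pr <- permutation_p(vols, des, n_perm = 150, seed = 3, mask = vox)
  cl_loose <- form_clusters(pr$tmap, pr$p, ch$template, p_thr = 0.02)
  cl_tight <- form_clusters(pr$tmap, pr$p, ch$template, p_thr = 0.005)
  loose_vox <- unlist(cl_loose$voxels)
  for (i in seq_len(nrow(cl_tight))) {
    expect_true(all(cl_tight$voxels[[i]] %in% loose_vox))
  }
  expect_lte(sum(cl_tight$n_voxels), sum(cl_loose$n_voxels))
})

test_that("without streamline edges TBCA reduces to plain 26-connectivity clustering", {
  gs <- c(12, 12, 1)
  withr::with_seed(8, {
    vox <- sort(sample(144, 40))
    tvals <- runif(40, 3, 5)
  })
  # template with one far-away streamline: no shared-streamline edges
  lone <- matrix(c(11, 11, 0, 11.2, 11, 0), 2, 3, byrow = TRUE)
  tmpl <- build_template(tractogram(list(lone)), gs, diag(4))
  part <- hdwm:::cluster_partition(vox, tmpl)
  # plain spatial clustering oracle
  coord <- cbind((vox - 1) %% 12, ((vox - 1) %/% 12) %% 12, 0)
  n <- length(vox)
  lab <- rep(NA_integer_, n); comp <- 0L
  for (s in 1:n) {
    if (!is.na(lab[s])) next
    comp <- comp + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(lab[v])) next
      lab[v] <- comp
      nb <- which(is.na(lab) &
                    apply(abs(coord - matrix(coord[v, ], n, 3, byrow = TRUE)), 1,
                          max) <= 1)
      queue <- c(queue, nb)
    }
  }
  expect_equal(length(unique(part)), length(unique(lab)))
  expect_true(all(tapply(lab, part, function(x) length(unique(x))) == 1))
})

test_that("FWE bound: a mass above every permuted maximum gets the minimum p", {
  ch <- tiny_cohort()
  des <- tbca_design(ch$cohort, direction = "greater")
  vols <- metric_volumes(ch, "FR")
  res <- tbca_run(vols, des, ch$template, n_perm = 150, seed = 5)
  cl <- res$clusters
  expect_true(nrow(cl) >= 1)
  null_max <- attr(cl, "null_max_mass")
  top <- which.max(cl$mass)
  if (cl$mass[top] > max(null_max)) {
    expect_equal(cl$p_fwe[top], 1 / 151)
  }
  expect_true(all(cl$p_fwe >= cl$p_uncorrected))
  expect_true(all(cl$p_fwe > 0 & cl$p_fwe <= 1))
  # mass is positive for a one-sided analysis
  expect_true(all(cl$mass > 0))
})

test_that("ROI means: single voxel, constant map, two-voxel average", {
  cl <- tibble::tibble(cluster_id = 1L, n_voxels = 2L, mass = 5,
                       voxels = list(c(3L, 7L)), streamlines = list(1L),
                       p_uncorrected = 0.001, p_fwe = 0.01, significant = TRUE)
  arr <- array(0, c(3, 3, 1)); arr[3] <- 1; arr[7] <- 3
  vols <- list(a = scalar_volume(arr, diag(4), "m"),
               b = scalar_volume(array(4, c(3, 3, 1)), diag(4), "m"))
  rm_ <- cluster_roi_means(cl, vols)
  expect_equal(rm_$roi_mean, c(2, 4), ignore_attr = TRUE)
  cl$significant <- FALSE
  expect_error(cluster_roi_means(cl, vols), "empty")
})
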