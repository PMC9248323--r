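pipeline_schema <- list(
  required = c("seed", "n_patients", "n_controls"),
  optional = list(
    grid_shape = c(24L, 24L, 24L), voxel_size = 2,
    n_streamlines_per_bundle = 200L, n_vertices = 30L, smooth_fwhm = 4,
    null_effects = FALSE, aggregate = "vertex-median-streamline-mean",
    n_perm = 300L, p_thr = 0.01, alpha = 0.05,
    tbca = list(list(metric = "MTR", direction = "less"),
                list(metric = "FR", direction = "greater"))
  )
)

#' Validate and complete a pipeline configuration
#'
#' @param config named list (e.g. from [read_pipeline_config()]). Required
#'   keys: `seed`, `n_patients`, `n_controls`. Optional keys take the demo
#'   defaults; unknown keys are rejected.
#' @return the completed config list.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  missing_keys <- setdiff(pipeline_schema$required, names(config))
  if (length(missing_keys)) {
    stop("config is missing required key(s): ",
         paste(missing_keys, collapse = ", "))
  }
  unknown <- setdiff(names(config),
                     c(pipeline_schema$required, names(pipeline_schema$optional)))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(pipeline_schema$optional, config)
  stopifnot(out$n_patients >= 2, out$n_controls >= 2, out$n_perm >= 100,
            out$p_thr > 0, out$p_thr < 1, out$alpha > 0, out$alpha < 1)
  out
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of key-value pairs.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  validate_config(yaml::read_yaml(path))
}

run_stage <- function(name, log_con, expr) {
  cat("stage:", name, "\n", file = log_con, append = TRUE)
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate, maps, tractometry, stats and tbca in order and
#' writes every result table (CSV), the per-subject NIfTI volumes, the
#' phantom TCK tractogram with its label CSV, and a verbatim copy of the
#' configuration to `out_dir`. The whole output tree is a pure function of
#' (config, seed).
#'
#' @param config validated config list or path to a YAML config.
#' @param out_dir output directory (created if needed).
#' @param write_volumes write per-subject NIfTI maps (disable to save
#'   time/space; CSV outputs are unaffected).
#' @return invisibly, a list with the cohort, tractometry table, stats
#'   results and TBCA results.
#' @export
run_pipeline <- function(config, out_dir, write_volumes = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  log_path <- file.path(out_dir, "log.txt")
  cat("hdwm pipeline, package version ",
      as.character(utils::packageVersion("hdwm")), "\n",
      sep = "", file = log_path)

  pc <- phantom_config(grid_shape = config$grid_shape,
                       voxel_size = config$voxel_size,
                       n_streamlines_per_bundle = config$n_streamlines_per_bundle,
                       n_vertices = config$n_vertices,
                       smooth_fwhm = config$smooth_fwhm,
                       seed = config$seed)
  effects <- effect_spec(null = config$null_effects)

  cohort <- run_stage("simulate", log_path, {
    ch <- make_cohort(config$n_patients, config$n_controls, effects, pc)
    utils::write.csv(ch$cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    write_tck(ch$tractogram, file.path(out_dir, "tractogram.tck"))
    ch
  })

  run_stage("maps", log_path, {
    # MTR is re-derived through the saturation-ratio formula from
    # synthesized S0/SMT pairs, exercising the map computation in-pipeline
    for (id in cohort$cohort$id) {
      mtr <- cohort$volumes[[id]]$MTR
      s0 <- scalar_volume(array(1000, dim(mtr$data)), mtr$affine, "S0")
      smt <- scalar_volume(1000 * (1 - mtr$data / 100), mtr$affine, "SMT")
      cohort$volumes[[id]]$MTR <- compute_mtr(s0, smt)
    }
    if (write_volumes) {
      vdir <- file.path(out_dir, "volumes")
      dir.create(vdir, showWarnings = FALSE)
      for (id in cohort$cohort$id) {
        for (m in names(cohort$volumes[[id]])) {
          write_volume(cohort$volumes[[id]][[m]],
                       file.path(vdir, paste0(id, "_", m, ".nii.gz")))
        }
      }
    }
    NULL
  })

  tract_tab <- run_stage("tractometry", log_path, {
    tab <- build_tractometry_table(cohort,
                                   metrics = c("FA", "AD", "RD", "FR", "MTR", "FWF"),
                                   aggregate = config$aggregate)
    utils::write.csv(tab, file.path(out_dir, "tractometry.csv"),
                     row.names = FALSE)
    tab
  })

  stats_res <- run_stage("stats", log_path,
                         pipeline_stats(cohort$cohort, tract_tab, out_dir))

  tbca_res <- run_stage("tbca", log_path, {
    res <- list()
    for (an in config$tbca) {
      design <- tbca_design(cohort$cohort, covariates = c("age", "sex"),
                            direction = an$direction)
      vols <- lapply(cohort$cohort$id, function(id) cohort$volumes[[id]][[an$metric]])
      names(vols) <- cohort$cohort$id
      res[[paste(an$metric, an$direction, sep = "_")]] <-
        tbca_run(vols, design, cohort$template, p_thr = config$p_thr,
                 n_perm = config$n_perm, alpha = config$alpha,
                 seed = substream_seed(config$seed, paste0("tbca:", an$metric,
                                                           ":", an$direction)))
    }
    ctab <- do.call(rbind, lapply(names(res), function(nm) {
      cl <- res[[nm]]$clusters
      if (nrow(cl) == 0L) return(NULL)
      tibble::tibble(analysis = nm, cluster_id = cl$cluster_id,
                     n_voxels = cl$n_voxels, mass = cl$mass,
                     p_uncorrected = cl$p_uncorrected, p_fwe = cl$p_fwe,
                     significant = cl$significant)
    }))
    if (is.null(ctab)) {
      ctab <- tibble::tibble(analysis = character(0), cluster_id = integer(0),
                             n_voxels = integer(0), mass = numeric(0),
                             p_uncorrected = numeric(0), p_fwe = numeric(0),
                             significant = logical(0))
    }
    utils::write.csv(ctab, file.path(out_dir, "tbca_clusters.csv"),
                     row.names = FALSE)

    # ROI means of each significant analysis + cross-metric correlations
    roi <- list()
    for (nm in names(res)) {
      if (!any(res[[nm]]$clusters$significant)) next
      metric <- sub("_.*$", "", nm)
      vols <- lapply(cohort$cohort$id, function(id) cohort$volumes[[id]][[metric]])
      names(vols) <- cohort$cohort$id
      rm_ <- cluster_roi_means(res[[nm]], vols)
      roi[[nm]] <- stats::setNames(rm_$roi_mean, rm_$subject_id)
    }
    if (length(roi) > 0L) {
      roi_tab <- tibble::tibble(subject_id = cohort$cohort$id)
      for (nm in names(roi)) roi_tab[[nm]] <- roi[[nm]][roi_tab$subject_id]
      utils::write.csv(roi_tab, file.path(out_dir, "tbca_roi_means.csv"),
                       row.names = FALSE)
      if (length(roi) >= 2L) {
        pats <- cohort$cohort$group == "patient"
        prs <- utils::combn(names(roi), 2, simplify = FALSE)
        m <- length(prs)
        cors <- do.call(rbind, lapply(prs, function(pr) {
          pp <- partial_pearson(rank(roi[[pr[1]]][pats]), rank(roi[[pr[2]]][pats]))
          tibble::tibble(roi_a = pr[1], roi_b = pr[2], r = pp$r, p = pp$p,
                         p_bonferroni = pmin(1, m * pp$p))
        }))
        utils::write.csv(cors, file.path(out_dir, "tbca_roi_correlations.csv"),
                         row.names = FALSE)
      }
    }
    res
  })

  invisible(list(config = config, cohort = cohort, tractometry = tract_tab,
                 stats = stats_res, tbca = tbca_res))
}

# statistics stage: metric PCA, ANCOVAs, simple slopes, correlation
# families; writes the stats CSV outputs
pipeline_stats <- function(cohort, tract_tab, out_dir) {
  wide <- stats::reshape(as.data.frame(tract_tab[tract_tab$metric != "FWF", ]),
                         idvar = c("subject_id", "segment"),
                         timevar = "metric", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  metrics <- c("FA", "AD", "RD", "FR", "MTR")
  adequacy <- pca_adequacy(wide[metrics])
  pca <- pca_varimax(wide[metrics], retain = "kaiser")
  if (!all(c("magnetization transfer", "axon density") %in% pca$labels)) {
    # retention combines the eigenvalue rule with interpretability: the
    # two a-priori components are kept even when the second eigenvalue
    # falls marginally below 1
    pca <- pca_varimax(wide[metrics], retain = "fixed", k = 2)
  }

  loadings <- tibble::tibble(metric = rownames(pca$loadings))
  for (j in seq_len(pca$n_components)) loadings[[paste0("PC", j)]] <- pca$loadings[, j]
  utils::write.csv(loadings, file.path(out_dir, "pca_loadings.csv"),
                   row.names = FALSE)

  scores <- tibble::tibble(subject_id = wide$subject_id,
                           segment = as.integer(wide$segment))
  for (j in seq_len(pca$n_components)) scores[[paste0("PC", j)]] <- pca$scores[, j]
  scores <- merge(scores, cohort[c("id", "group", "age", "sex", "icv", "cag", "dbs")],
                  by.x = "subject_id", by.y = "id")
  # per-subject overall mean free-water fraction, as covariate
  fwf <- tract_tab[tract_tab$metric == "FWF", ]
  fwf_mean <- tapply(fwf$value, fwf$subject_id, mean)
  scores$fwf <- as.numeric(fwf_mean[scores$subject_id])
  utils::write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)

  mt_pc <- which(pca$labels == "magnetization transfer")[1]
  ax_pc <- which(pca$labels == "axon density")[1]

  ancova_rows <- list()
  slopes <- NULL
  mt_model <- NULL
  for (comp in c(ax_pc, mt_pc)) {
    if (is.na(comp)) next
    d <- scores
    d$score <- d[[paste0("PC", comp)]]
    filt <- remove_outliers(d, "score", "group")
    d <- filt$data
    scr <- screen_covariates(d$score, d[c("age", "icv")])
    covs <- scr$covariate[scr$selected]
    is_mt <- identical(comp, mt_pc)
    inter <- if (is_mt && "age" %in% covs) c("group:segment", "group:age")
             else "group:segment"
    fit <- ancova_scores(d, covariates = intersect(covs, "age"),
                         interactions = inter)
    lab <- pca$labels[comp]
    ancova_rows[[lab]] <- tibble::tibble(component = lab, fit$table,
                                         n_outliers_removed = nrow(filt$removed))
    if (is_mt) {
      slopes <- simple_slopes(fit)
      mt_model <- fit
      # post-hoc partial-volume control: FWF, ICV as extra covariates with
      # the slope-heterogeneity interactions
      fwf_fit <- ancova_scores(d, covariates = c("age", "icv", "fwf"),
                               interactions = c("group:segment", "group:age",
                                                "group:fwf"))
      ancova_rows[["mt_fwf_covaried"]] <-
        tibble::tibble(component = "magnetization transfer (FWF-covaried)",
                       fwf_fit$table, n_outliers_removed = nrow(filt$removed))
    }
  }
  ancova_tab <- do.call(rbind, ancova_rows)
  utils::write.csv(ancova_tab, file.path(out_dir, "ancova.csv"), row.names = FALSE)
  if (!is.null(slopes)) {
    utils::write.csv(slopes, file.path(out_dir, "simple_slopes.csv"),
                     row.names = FALSE)
  }

  # cognitive PCA (patients, complete cases, single extracted component)
  pats <- cohort[cohort$group == "patient", ]
  cg <- pats[stats::complete.cases(pats[cognitive_outcomes]), ]
  cog_pca <- pca_varimax(cg[cognitive_outcomes], retain = "fixed", k = 1)
  cog_scores <- stats::setNames(cog_pca$scores[, 1], cg$id)

  # correlation families in the patient group: MT component score per
  # segment against cognition, CAG and DBS; partial (ICV, DBS) for CAG
  cors <- NULL
  if (!is.na(mt_pc)) {
    pat_scores <- scores[scores$group == "patient", ]
    pat_scores$mt <- pat_scores[[paste0("PC", mt_pc)]]
    pat_scores$cognitive <- as.numeric(cog_scores[pat_scores$subject_id])
    fams <- list(
      cognitive = spearman_family(pat_scores, "mt", "cognitive"),
      cag = spearman_family(pat_scores, "mt", "cag"),
      dbs = spearman_family(pat_scores, "mt", "dbs"),
      cag_partial = spearman_family(pat_scores, "mt", "cag",
                                    covariates = c("icv", "dbs")))
    cors <- do.call(rbind, lapply(names(fams), function(nm)
      tibble::tibble(family = nm, fams[[nm]])))
    utils::write.csv(cors, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
  }

  list(adequacy = adequacy, pca = pca, ancova = ancova_tab, slopes = slopes,
       mt_model = mt_model, correlations = cors, cognitive_pca = cog_pca)
}
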