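# Baseline map values per metric: background tissue vs white-matter bundle.
# MTR in percent units; diffusivities in mm^2/s; FA, FR, FWF unitless.
metric_baselines <- list(
  MTR = c(bg = 25,    bundle = 38),
  FA  = c(bg = 0.15,  bundle = 0.55),
  AD  = c(bg = 1.0e-3, bundle = 1.6e-3),
  RD  = c(bg = 0.8e-3, bundle = 0.45e-3),
  FR  = c(bg = 0.10,  bundle = 0.35),
  FWF = c(bg = 0.25,  bundle = 0.08)
)

hd_metrics <- names(metric_baselines)

# reference points for centered covariate effects: fixed, not sample means,
# so that map generation for one subject never depends on the others
ref_age <- 45.5
ref_cag <- 41

#' Generate a synthetic premanifest-HD cohort with metric maps
#'
#' Draws a patient/control cohort with matched ages, patient CAG repeat
#' lengths, intracranial volume, disease burden score (DBS = age x
#' (CAG - 35.5)) and a 13-outcome cognitive battery, and builds per-subject
#' quantitative maps (MTR, FA, RD, AD, FR, FWF) as a smooth bundle
#' baseline plus the planted effects of an [effect_spec()] plus Gaussian
#' noise, smoothed with the configured FWHM.
#'
#' @param n_patients,n_controls group sizes (each >= 2).
#' @param effects an [effect_spec()].
#' @param config a [phantom_config()].
#' @param metrics subset of `c("MTR","FA","RD","AD","FR","FWF")` to
#'   generate maps for (all by default; restricting saves memory and time).
#' @param tracts optional pre-built phantom [tractogram()] (rebuilt from
#'   `config` when omitted).
#' @param template optional pre-built [build_template()] incidence for
#'   `tracts` (rebuilt when omitted); passing both makes repeated cohort
#'   draws over one phantom cheap.
#' @return a list of class `hd_cohort` with elements `cohort` (tibble),
#'   `volumes` (per-subject named lists of [scalar_volume()]), `tractogram`,
#'   `template` (the voxel-streamline incidence) and `affine`.
#' @export
make_cohort <- function(n_patients, n_controls, effects = effect_spec(),
                        config = phantom_config(), metrics = hd_metrics,
                        tracts = NULL, template = NULL) {
  stopifnot(n_patients >= 2L, n_controls >= 2L,
            inherits(effects, "effect_spec"),
            inherits(config, "phantom_config"))
  metrics <- match.arg(metrics, hd_metrics, several.ok = TRUE)
  affine <- phantom_affine(config)
  if (is.null(tracts)) tracts <- make_phantom_tractogram(config)
  if (is.null(template)) template <- build_template(tracts, config$grid_shape, affine)
  # effects are painted on masks dilated by one voxel so that trilinear
  # sampling at any traversed vertex sees bundle values on all 8 corners
  seg_masks <- lapply(c(as.character(1:7), "CST"), function(lab) {
    sel <- which(template$labels == lab)
    vox <- unique(unlist(template$streamline_voxels[sel], use.names = FALSE))
    dilate_voxels(vox, config$grid_shape)
  })
  names(seg_masks) <- c(as.character(1:7), "CST")

  cohort <- with_substream(config$seed, "cohort", {
    n <- n_patients + n_controls
    age_p <- stats::runif(n_patients, config$age_range[1], config$age_range[2])
    # controls age-matched: permuted patient ages plus a small shift
    age_c <- sample(age_p, n_controls, replace = n_controls > n_patients) +
      stats::runif(n_controls, -2, 2)
    age_c <- pmin(pmax(age_c, config$age_range[1]), config$age_range[2] + 1)
    sex <- c(sample(c("M", "F"), n_patients, TRUE, prob = c(0.6, 0.4)),
             sample(c("M", "F"), n_controls, TRUE, prob = c(0.56, 0.44)))
    cag <- c(sample(seq(config$cag_range[1], config$cag_range[2]),
                    n_patients, replace = TRUE),
             rep(NA_integer_, n_controls))
    icv <- stats::rnorm(n, 1.5e6, 1.2e5)
    tibble::tibble(
      id = sprintf("sub-%03d", seq_len(n)),
      group = factor(rep(c("patient", "control"), c(n_patients, n_controls)),
                     levels = c("control", "patient")),
      age = c(age_p, age_c),
      sex = factor(sex, levels = c("F", "M")),
      cag = cag,
      icv = icv,
      dbs = dbs(c(age_p, age_c), cag)
    )
  })
  cohort <- make_cognitive_scores(cohort, seed = config$seed)

  base_maps <- lapply(metrics, function(m) {
    b <- metric_baselines[[m]]
    arr <- array(b["bg"], dim = config$grid_shape)
    for (k in 1:7) {
      grad <- if (m %in% names(effects$density_gradient)) {
        sgn <- if (m == "RD") -1 else 1
        sgn * effects$density_gradient[[m]] * (k - 4) / 6
      } else 0
      arr[seg_masks[[k]]] <- b["bundle"] + grad
    }
    arr[seg_masks[["CST"]]] <- b["bundle"]
    arr
  })
  names(base_maps) <- metrics

  volumes <- lapply(seq_len(nrow(cohort)), function(i) {
    subj <- cohort[i, ]
    is_pat <- subj$group == "patient"
    # latent per-subject myelin factor: drives the MTR offset and leaks
    # weakly into RD, coupling the two metrics as in real tissue
    myelin <- with_substream(config$seed, paste0("myelin:", subj$id),
                             stats::rnorm(1))
    vols <- lapply(metrics, function(m) {
      arr <- base_maps[[m]]
      if (m == "MTR") {
        callosal_coef <- effects$age_mtr_slope * (subj$age - ref_age)
        if (is_pat) {
          callosal_coef <- callosal_coef +
            effects$cag_mtr_slope * (subj$cag - ref_cag) +
            effects$group_age_interaction * (subj$age - ref_age)
        }
        for (k in 1:7) {
          coef <- callosal_coef +
            if (is_pat) effects$group_segment_mtr[k] else 0
          arr[seg_masks[[k]]] <- arr[seg_masks[[k]]] + coef
        }
        arr[seg_masks[["CST"]]] <- arr[seg_masks[["CST"]]] +
          effects$age_mtr_slope * (subj$age - ref_age)
      }
      if (m == "FR" && is_pat) {
        arr[seg_masks[["CST"]]] <- arr[seg_masks[["CST"]]] + effects$cst_fr_offset
      }
      intercept <- if (m == "MTR") {
        config$subject_sd$MTR * myelin
      } else if (m == "RD") {
        config$myelin_rd_cross * myelin +
          with_substream(config$seed, paste0("maps:", subj$id, ":RD:intercept"),
                         stats::rnorm(1, 0, config$subject_sd$RD))
      } else {
        with_substream(config$seed, paste0("maps:", subj$id, ":", m, ":intercept"),
                       stats::rnorm(1, 0, config$subject_sd[[m]]))
      }
      arr <- arr + intercept +
        with_substream(config$seed, paste0("maps:", subj$id, ":", m),
                       array(stats::rnorm(length(arr), 0, config$noise_sd[[m]]),
                             dim = dim(arr)))
      arr <- smooth_gaussian(arr, config$smooth_fwhm, config$voxel_size)
      scalar_volume(arr, affine, m)
    })
    names(vols) <- metrics
    vols
  })
  names(volumes) <- cohort$id

  structure(list(cohort = cohort, volumes = volumes, tractogram = tracts,
                 template = template, affine = affine, config = config,
                 effects = effects),
            class = "hd_cohort")
}

#' @export
print.hd_cohort <- function(x, ...) {
  cat(sprintf("<hd_cohort> %d patients / %d controls, metrics: %s, grid %s\n",
              sum(x$cohort$group == "patient"), sum(x$cohort$group == "control"),
              paste(names(x$volumes[[1]]), collapse = "/"),
              paste(x$config$grid_shape, collapse = "x")))
  invisible(x)
}

# names of the 13 cognitive outcome variables (working memory, speed,
# inhibition, fluency, switching batteries)
cognitive_outcomes <- c(
  "nback_1back", "nback_2back", "digit_span", "visual_patterns",
  "finger_tapping", "stroop_word", "stroop_color", "stroop_interference",
  "fluency_phonetic", "fluency_category", "trails_a", "trails_b",
  "symbol_digit"
)

# one dominant executive factor; the digit span loads weakly
default_cognitive_loading <- c(0.80, 0.75, 0.20, 0.70, 0.65, 0.70, 0.65,
                               0.75, 0.60, 0.70, 0.60, 0.65, 0.70)

#' Generate cognitive battery scores with a single dominant factor
#'
#' Each of the 13 outcomes is `loading * latent + noise`, where `latent`
#' is a per-subject standard normal factor, optionally correlated with a
#' designated covariate column of the cohort table.
#'
#' @param cohort a cohort tibble (one row per subject).
#' @param loading numeric factor loadings, length 13.
#' @param noise_sd residual standard deviation per outcome.
#' @param latent_covariate optional column name of `cohort`; when given,
#'   the latent factor has correlation `latent_cor` with it.
#' @param latent_cor target correlation in `[-1, 1]`.
#' @param seed root seed (substream "cognitive").
#' @return the cohort tibble with 13 outcome columns appended.
#' @export
make_cognitive_scores <- function(cohort, loading = default_cognitive_loading,
                                  noise_sd = 0.6, latent_covariate = NULL,
                                  latent_cor = 0, seed = 1L) {
  if (length(loading) != length(cognitive_outcomes)) {
    stop("loading must have length ", length(cognitive_outcomes),
         " (one per cognitive outcome), got ", length(loading))
  }
  n <- nrow(cohort)
  with_substream(seed, "cognitive", {
    latent <- stats::rnorm(n)
    if (!is.null(latent_covariate)) {
      z <- as.numeric(scale(cohort[[latent_covariate]]))
      latent <- latent_cor * z + sqrt(1 - latent_cor^2) * latent
    }
    for (j in seq_along(cognitive_outcomes)) {
      cohort[[cognitive_outcomes[j]]] <-
        loading[j] * latent + stats::rnorm(n, 0, noise_sd)
    }
  })
  cohort
}

#' Disease burden score
#'
#' `DBS = age x (CAG - 35.5)`; undefined (NA) when CAG is missing, as for
#' controls.
#'
#' @param age age in years.
#' @param cag CAG repeat length (> 0).
#' @return numeric disease burden score.
#' @export
dbs <- function(age, cag) {
  stopifnot(all(cag > 0, na.rm = TRUE))
  age * (cag - 35.5)
}
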