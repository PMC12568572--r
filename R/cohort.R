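## Two-cohort synthetic study generator.
##
## Group effects are injected at the truth level: each eye receives true
## morphometric parameters (caliber, branching angle, disc and cup areas,
## tortuosity amplitude) drawn from group-specific distributions, and the
## rendered scene realizes those parameters, so pipeline recovery can be
## scored against known truth. Baseline (lowland) parameter means and the
## highland offsets copy the published cohort's effect directions; covariate
## distributions copy the published covariate imbalance.

# lowland baseline truth means
.base_vc_um <- 81.663
.base_vba_deg <- 63.611
.base_disc_mm2 <- 2.365
.base_cup_mm2 <- 0.557
.base_tort_amp <- 3.0

# covariate effects on caliber (finer vessels in males and longer eyes)
.beta_axl_vc <- -3.0   # um per mm of axial length (centered at 23.1 mm)
.beta_male_vc <- -1.5  # um

# noise decomposition (um / deg / mm2): subject-level + eye-level
.sd_vc <- c(subject = 3.0, eye = sqrt(11^2 - 3^2))
.sd_vba <- c(subject = 5.0, eye = 5.5)
.sd_disc <- c(subject = 0.30, eye = 0.26)
.sd_cup <- c(subject = 0.15, eye = 0.17)
.sd_tort <- c(subject = 0.3, eye = 0.3)

#' Generate a synthetic two-cohort study
#'
#' Draws per-subject covariates (age, sex, axial length) from group-specific
#' distributions and per-eye true morphometric parameters (baseline +
#' highland group offset + covariate effects + subject- and eye-level
#' noise). Both eyes of a subject share the subject's covariates. With
#' `render = TRUE` each eye is additionally rendered as a fundus image whose
#' vessel calibers, branching angles, and disc/cup geometry realize the
#' drawn truth parameters.
#'
#' @param spec A [cohort_spec()].
#' @param render Render fundus images and ground truth for every eye
#'   (slow); the truth-level cohort table is always returned.
#' @param size Frame side in px for rendered scenes.
#' @param noise_level Pixel noise SD for rendered scenes.
#' @return A list with `cohort` (one row per eye: subject_id, eye, group,
#'   age, sex, axl_mm, and true parameters `vc_um`, `vba_deg`,
#'   `disc_area_mm2`, `cup_area_mm2`, `cdr`, `tort_amp_px`), and, when
#'   rendered, parallel lists `images` and `truths`.
#' @export
generate_cohort <- function(spec, render = FALSE, size = 1024,
                            noise_level = 0.02) {
  stopifnot(inherits(spec, "cohort_spec"))
  eff <- function(nm) unname(spec$group_effects[nm] %||% 0)
  cd <- spec$covariate_dists
  eyes <- c("OD", "OS")[seq_len(spec$eyes_per_subject)]

  n <- spec$n_per_group
  m <- length(eyes)
  cohort <- with_rng(spec$seed, {
    per_group <- lapply(c("HLC", "LLC"), function(grp) {
      ghl <- as.numeric(grp == "HLC")
      age <- stats::rnorm(n, cd$age[[grp]]["mean"], cd$age[[grp]]["sd"])
      sex <- ifelse(stats::runif(n) < cd$male_prop[[grp]], "male", "female")
      axl <- stats::rnorm(n, cd$axl[[grp]]["mean"], cd$axl[[grp]]["sd"])
      s_vc <- stats::rnorm(n, 0, .sd_vc["subject"])
      s_vba <- stats::rnorm(n, 0, .sd_vba["subject"])
      s_disc <- stats::rnorm(n, 0, .sd_disc["subject"])
      s_cup <- stats::rnorm(n, 0, .sd_cup["subject"])
      s_tort <- stats::rnorm(n, 0, .sd_tort["subject"])
      idx <- rep(seq_len(n), each = m)      # subject index per eye row
      vc <- .base_vc_um + ghl * eff("vc_um") +
        .beta_axl_vc * (axl[idx] - 23.1) +
        .beta_male_vc * (sex[idx] == "male") +
        s_vc[idx] + stats::rnorm(n * m, 0, .sd_vc["eye"])
      vba <- clamp(.base_vba_deg + ghl * eff("vba_deg") + s_vba[idx] +
                     stats::rnorm(n * m, 0, .sd_vba["eye"]), 20, 150)
      disc_a <- clamp(.base_disc_mm2 + ghl * eff("disc_area_mm2") +
                        s_disc[idx] +
                        stats::rnorm(n * m, 0, .sd_disc["eye"]), 1.3, 4.5)
      cup_a <- clamp(clamp(.base_cup_mm2 + ghl * eff("cup_area_mm2") +
                             s_cup[idx] +
                             stats::rnorm(n * m, 0, .sd_cup["eye"]),
                           0.12, Inf), 0.12, 0.55 * disc_a)
      tort <- clamp(.base_tort_amp + s_tort[idx] +
                      stats::rnorm(n * m, 0, .sd_tort["eye"]), 0.5, 6)
      data.frame(
        subject_id = sprintf("%s%03d", grp, idx),
        eye = rep(eyes, times = n), group = grp,
        age = age[idx], sex = sex[idx], axl_mm = axl[idx],
        vc_um = vc, vba_deg = vba, disc_area_mm2 = disc_a,
        cup_area_mm2 = cup_a, cdr = cup_a / disc_a, tort_amp_px = tort,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, per_group)
  })
  rownames(cohort) <- NULL

  out <- list(cohort = cohort, images = NULL, truths = NULL)
  if (render) {
    images <- vector("list", nrow(cohort))
    truths <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      sc <- scene_from_params(cohort[i, ], seed = child_seed(spec$seed, i),
                              size = size, noise_level = noise_level)
      images[[i]] <- sc$image
      truths[[i]] <- sc$truth
    }
    names(images) <- names(truths) <-
      paste(cohort$subject_id, cohort$eye, sep = "_")
    out$images <- images
    out$truths <- truths
  }
  out
}

#' Render the fundus scene realizing one cohort row's truth parameters
#'
#' @param row One row of the cohort table from [generate_cohort()].
#' @param seed Scene seed.
#' @param size Frame side in px.
#' @param noise_level Pixel noise SD.
#' @return `list(image, truth)` as [render_fundus()].
#' @export
scene_from_params <- function(row, seed = 0L, size = 1024,
                              noise_level = 0.02) {
  sc <- size / 1024
  pitch <- 10 / sc
  r_disc_px <- sqrt(row$disc_area_mm2 / pi) * 1000 / pitch
  r_cup_px <- sqrt(row$cup_area_mm2 / pi) * 1000 / pitch
  mirror <- if (row$eye == "OD") 1 else -1
  disc <- disc_spec(
    center = c((size + 1) / 2 + mirror * 0.10 * size, (size + 1) / 2),
    disc_radius = r_disc_px, cup_radius = r_cup_px, pixel_pitch = pitch
  )
  cal_scale <- row$vc_um / .base_vc_um
  tree <- tree_spec(
    trunk_caliber_artery = 10 * sc * cal_scale,
    trunk_caliber_vein = 13 * sc * cal_scale,
    branch_angle_mean = row$vba_deg, branch_angle_sd = 8,
    tortuosity_amplitude = row$tort_amp_px * sc,
    tortuosity_wavelength = 60 * sc, min_caliber = 2.6 * sc
  )
  default_scene(seed = seed, size = size, noise_level = noise_level,
                eye = row$eye, tree = tree, disc = disc,
                subject_id = row$subject_id)
}
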