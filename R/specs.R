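#' Vessel tree specification
#'
#' Parameters controlling one synthetic vascular tree: trunk widths for the
#' arterial and venous roots, the Murray-type taper exponent linking parent
#' and daughter calibers at bifurcations, the branching-angle distribution,
#' and the sinusoidal centerline perturbation that produces a known
#' tortuosity.
#'
#' @param trunk_caliber_artery Arterial trunk width (vessel diameter) in px.
#' @param trunk_caliber_vein Venous trunk width in px; must be at least the
#'   arterial trunk width (veins are the wider class).
#' @param taper_exponent Murray-law exponent `e`: at every bifurcation the
#'   daughter calibers satisfy `parent^e = sum(child^e)`. The classical value
#'   is 3.
#' @param branch_angle_mean,branch_angle_sd Mean and SD (degrees) of the
#'   total angle between the two daughter branches at a bifurcation.
#' @param tortuosity_amplitude Peak perpendicular displacement (px) of the
#'   sinusoidal centerline perturbation; 0 gives perfectly straight segments.
#' @param tortuosity_wavelength Wavelength (px) of the perturbation.
#' @param depth Maximum number of branching generations (trunk =
#'   generation 1); the caliber floor usually terminates twig lines first.
#' @param trunk_length Trunk segment length in px; by default derived from
#'   the disc radius when the tree is generated (`0.5 * disc_radius`,
#'   first bifurcation close to the disc border).
#' @param min_caliber Width floor in px below which branching stops
#'   (default 2.6 px, about the resolution limit of fundus
#'   photography at the default 10 µm/px pitch).
#' @param seed Integer seed making the tree reproducible.
#' @return An object of class `tree_spec`.
#' @export
tree_spec <- function(trunk_caliber_artery = 10,
                      trunk_caliber_vein = 13,
                      taper_exponent = 3,
                      branch_angle_mean = 63.6,
                      branch_angle_sd = 7.5,
                      tortuosity_amplitude = 3,
                      tortuosity_wavelength = 60,
                      depth = 12,
                      trunk_length = NULL,
                      min_caliber = 2.6,
                      seed = 0L) {
  if (!(trunk_caliber_vein >= trunk_caliber_artery &&
          trunk_caliber_artery > 0)) {
    stopf("tree_spec: need trunk_caliber_vein >= trunk_caliber_artery > 0")
  }
  if (depth < 1) stopf("tree_spec: depth must be >= 1")
  if (!(branch_angle_mean > 0 && branch_angle_mean < 180)) {
    stopf("tree_spec: branch_angle_mean must lie in (0, 180) degrees")
  }
  if (tortuosity_wavelength <= 0) stopf("tree_spec: wavelength must be > 0")
  if (tortuosity_amplitude < 0) stopf("tree_spec: amplitude must be >= 0")
  structure(
    list(
      trunk_caliber_artery = trunk_caliber_artery,
      trunk_caliber_vein = trunk_caliber_vein,
      taper_exponent = taper_exponent,
      branch_angle_mean = branch_angle_mean,
      branch_angle_sd = branch_angle_sd,
      tortuosity_amplitude = tortuosity_amplitude,
      tortuosity_wavelength = tortuosity_wavelength,
      depth = as.integer(depth),
      trunk_length = trunk_length,
      min_caliber = min_caliber,
      seed = as.integer(seed)
    ),
    class = "tree_spec"
  )
}

#' Optic disc and cup geometry
#'
#' @param center Disc center `c(x, y)` in px (top-left origin, y downward).
#' @param disc_radius Disc radius in px.
#' @param cup_radius Cup radius in px; must satisfy `0 < cup < disc`.
#' @param pixel_pitch Physical pixel size in µm/px, the calibration that
#'   converts px measurements to µm and mm².
#' @return An object of class `disc_spec`.
#' @export
disc_spec <- function(center = c(612, 512), disc_radius = 87,
                      cup_radius = 42.5, pixel_pitch = 10) {
  if (!(cup_radius > 0 && cup_radius < disc_radius)) {
    stopf("disc_spec: need 0 < cup_radius < disc_radius")
  }
  if (pixel_pitch <= 0) stopf("disc_spec: pixel_pitch must be > 0")
  structure(
    list(center = as.numeric(center), disc_radius = disc_radius,
         cup_radius = cup_radius, pixel_pitch = pixel_pitch),
    class = "disc_spec"
  )
}

#' Two-cohort simulation specification
#'
#' Describes a highland (HLC) vs lowland (LLC) style two-group study: group
#' sizes, additive highland offsets on the morphometric truth parameters, and
#' group-specific covariate distributions. Defaults copy the published
#' covariate imbalance of an 8–9-year-old highland/lowland comparison (age
#' 8.66±0.66 vs 8.08±0.28 y, male 43.8% vs 52.2%, axial length 22.76±1.51 vs
#' 23.27±0.79 mm) and highland effect directions (narrower caliber, smaller
#' branching angle, larger disc and cup).
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param group_effects Named additive offsets applied to the HLC group's
#'   truth parameters: `vc_um` (caliber, µm), `vba_deg` (branching angle,
#'   degrees), `disc_area_mm2`, `cup_area_mm2`.
#' @param covariate_dists List with per-group age mean/sd (years), male
#'   proportion, axial-length mean/sd (mm).
#' @param eyes_per_subject 1 or 2; with 2, both eyes share the subject's
#'   covariates and enter downstream analyses as separate rows.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 100,
                        group_effects = c(vc_um = -4, vba_deg = -1.5,
                                          disc_area_mm2 = 0.184,
                                          cup_area_mm2 = 0.068),
                        covariate_dists = list(
                          age = list(HLC = c(mean = 8.66, sd = 0.66),
                                     LLC = c(mean = 8.08, sd = 0.28)),
                          male_prop = c(HLC = 0.438, LLC = 0.522),
                          axl = list(HLC = c(mean = 22.76, sd = 1.51),
                                     LLC = c(mean = 23.27, sd = 0.79))
                        ),
                        eyes_per_subject = 2,
                        seed = 0L) {
  if (n_per_group < 2) stopf("cohort_spec: n_per_group must be >= 2")
  if (!eyes_per_subject %in% c(1L, 2L)) {
    stopf("cohort_spec: eyes_per_subject must be 1 or 2")
  }
  mp <- covariate_dists$male_prop
  if (any(mp < 0 | mp > 1)) stopf("cohort_spec: male proportions in [0, 1]")
  structure(
    list(n_per_group = as.integer(n_per_group),
         group_effects = group_effects,
         covariate_dists = covariate_dists,
         eyes_per_subject = as.integer(eyes_per_subject),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}
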