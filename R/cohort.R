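#' Specification of a synthetic lesion cohort
#'
#' Class-conditional distributions for a cohort of lesion phantoms imaged
#' at several probe rotations.  Defaults encode the margin mechanics that
#' motivate the elastogram-to-B-mode ratio: benign lesions have a
#' receded parametric extent (negative margin width, parametric lesion
#' smaller than B-mode), malignant lesions an extended, mechanically
#' altered margin.  A configurable fraction of malignant margins is
#' drawn on the background's peak-displacement level set
#' ("confounded" margins): one branch stiffer but less viscous, the
#' other softer but more viscous, so the margin is invisible in a
#' displacement image while still contrasted in elasticity or viscosity.
#'
#' All two-element numeric entries are uniform-distribution bounds.
#'
#' @param n_lesions number of lesions (>= 2).
#' @param benign_fraction fraction of benign lesions; `round(n_lesions *
#'   benign_fraction)` lesions are labelled benign.
#' @param rotations probe rotation angles in degrees.
#' @param grid_shape phantom grid `(axial, lateral)` used for cohort
#'   imaging.
#' @param axial_extent_mm,lateral_spacing physical grid scale; axial
#'   spacing is `axial_extent_mm / axial samples`.
#' @param background_E,background_mu background material (kPa, Pa.s).
#' @param semi_major,aspect,depth lesion-size and depth distributions:
#'   semi-major axis (mm), major/minor aspect ratio, axial center (mm).
#' @param base_angle lesion orientation distribution in degrees.
#' @param heterogeneity_cv material heterogeneity CV applied to every
#'   phantom.
#' @param benign,malignant per-class parameter distributions: lists with
#'   `margin_width` (mm), `core_E_factor`, `core_mu_factor`,
#'   `margin_E_factor`, `margin_mu_factor` (all relative to background)
#'   and, for malignant, `confound_fraction` (fraction of lesions whose
#'   margin is PD-matched to the background, split evenly between the
#'   stiff and the viscous branch).
#' @param seq the [tracking_seq()] used when constructing PD-matched
#'   margins.
#' @param seed cohort seed.
#' @return An object of class `visr_cohort_spec`.
#' @export
cohort_spec <- function(n_lesions = 40, benign_fraction = 0.65,
                        rotations = c(0, 30, 60, 90),
                        grid_shape = c(256, 40),
                        axial_extent_mm = 40, lateral_spacing = 0.5,
                        background_E = 5, background_mu = 2,
                        semi_major = c(4.5, 6), aspect = c(1.2, 1.6),
                        depth = c(14, 26), base_angle = c(0, 180),
                        heterogeneity_cv = 0.3,
                        benign = list(margin_width = c(-2, -0.3),
                                      core_E_factor = c(1.5, 2),
                                      core_mu_factor = c(1.5, 2),
                                      margin_E_factor = c(1, 1),
                                      margin_mu_factor = c(1, 1),
                                      confound_fraction = 0),
                        malignant = list(margin_width = c(0.5, 2.5),
                                         core_E_factor = c(1.8, 2.4),
                                         core_mu_factor = c(1.8, 2.4),
                                         margin_E_factor = c(2.5, 3),
                                         margin_mu_factor = c(2.5, 3),
                                         stiff_E_factor = c(2.2, 2.6),
                                         viscous_E_divisor = 8,
                                         confound_fraction = 2 / 3),
                        seq = tracking_seq(), seed = 1) {
  stopifnot(n_lesions >= 2, benign_fraction >= 0, benign_fraction <= 1,
            length(rotations) >= 1, all(grid_shape >= 2))
  n_benign <- round(n_lesions * benign_fraction)
  if (n_benign < 1 || n_benign >= n_lesions) {
    stop("both classes must be represented in the cohort")
  }
  structure(list(n_lesions = as.integer(n_lesions),
                 benign_fraction = benign_fraction,
                 rotations = rotations, grid_shape = as.integer(grid_shape),
                 axial_extent_mm = axial_extent_mm,
                 lateral_spacing = lateral_spacing,
                 background_E = background_E, background_mu = background_mu,
                 semi_major = semi_major, aspect = aspect, depth = depth,
                 base_angle = base_angle,
                 heterogeneity_cv = heterogeneity_cv,
                 benign = benign, malignant = malignant,
                 seq = seq, seed = as.integer(seed)),
            class = "visr_cohort_spec")
}

#' Cohort with margin effects switched off
#'
#' A copy of [cohort_spec()] in which both classes have zero margin
#' width and unit margin factors: parametric and B-mode lesion extents
#' coincide, so the expected E/B is 1 for every lesion and no class
#' signal remains.  Used as the negative control for classifier studies.
#'
#' @param ... arguments passed to [cohort_spec()].
#' @return A `visr_cohort_spec`.
#' @export
null_cohort_spec <- function(...) {
  cs <- cohort_spec(...)
  for (cls in c("benign", "malignant")) {
    cs[[cls]]$margin_width <- c(0, 0)
    cs[[cls]]$margin_E_factor <- c(1, 1)
    cs[[cls]]$margin_mu_factor <- c(1, 1)
    cs[[cls]]$confound_fraction <- 0
  }
  cs
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

# Draw one lesion's geometry and materials from its class distributions.
# Everything except the rotation-dependent heterogeneity seed is decided
# here, at the lesion level, so rotations image the same lesion.
# `mechanism` fixes the margin type ("none", "stiff" or "viscous"); the
# cohort-level composition is deterministic, mirroring the exact label
# counting rule.
draw_lesion <- function(cohort, label, lesion_seed, mechanism = "none") {
  cls <- cohort[[label]]
  with_seed(lesion_seed, {
    semi_major <- runif_range(1, cohort$semi_major)
    aspect <- runif_range(1, cohort$aspect)
    semi_minor <- semi_major / aspect
    depth <- runif_range(1, cohort$depth)
    angle <- runif_range(1, cohort$base_angle)
    mw <- runif_range(1, cls$margin_width)
    core_E <- cohort$background_E * runif_range(1, cls$core_E_factor)
    core_mu <- cohort$background_mu * runif_range(1, cls$core_mu_factor)
    mf_E <- runif_range(1, cls$margin_E_factor)
    mf_mu <- runif_range(1, cls$margin_mu_factor)
    stiff_f <- runif_range(1, cls$stiff_E_factor %||% c(2, 2.6))
  })
  confound <- "none"
  if (mechanism != "none" && mw > 0) {
    if (mechanism == "stiff") {
      # stiff branch: margin stiffer but less viscous, PD-matched
      pair <- pd_matched_pair(cohort$background_E, cohort$background_mu,
                              cohort$seq,
                              E2 = cohort$background_E * stiff_f)
      confound <- "stiff"
    } else {
      # viscous branch: margin much softer and more viscous, PD-matched
      pair <- pd_matched_pair(
        cohort$background_E, cohort$background_mu, cohort$seq,
        E2 = cohort$background_E / (cls$viscous_E_divisor %||% 8))
      confound <- "viscous"
    }
    mf_E <- pair$E2 / cohort$background_E
    mf_mu <- pair$mu2 / cohort$background_mu
  }
  if (abs(mw) >= semi_minor) mw <- sign(mw) * 0.9 * semi_minor
  list(semi_major = semi_major, semi_minor = semi_minor, depth = depth,
       angle = angle, margin_width = mw, core_E = core_E,
       core_mu = core_mu, margin_E_factor = mf_E, margin_mu_factor = mf_mu,
       confound = confound)
}

#' Sample a lesion cohort
#'
#' Draws `n_lesions` lesions from the class-conditional distributions and
#' realizes one phantom per probe rotation for each.  Rotating the probe
#' rotates the lesion geometry about its center; the material
#' heterogeneity field is re-sampled deterministically per rotation from
#' the lesion-level seed.  Class labels are assigned so that exactly
#' `round(n_lesions * benign_fraction)` lesions are benign, in a
#' seed-determined order.
#'
#' @param cohort a [cohort_spec()].
#' @return A list of lesions; each element has `lesion_id`, `label`,
#'   `params` (the drawn lesion parameters) and `phantoms` (one
#'   [make_phantom()] result per rotation).
#' @export
sample_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "visr_cohort_spec"))
  n <- cohort$n_lesions
  n_benign <- round(n * cohort$benign_fraction)
  labels <- with_seed(derive_seed(cohort$seed, "labels"), {
    sample(c(rep("benign", n_benign), rep("malignant", n - n_benign)))
  })
  # margin-mechanism composition is exact up to rounding (like the label
  # count): round(f * n_malignant) confounded margins, split as evenly
  # as possible between the stiff and viscous branches, assigned to the
  # malignant lesions in seed-shuffled order
  n_mal <- n - n_benign
  f_conf <- cohort$malignant$confound_fraction %||% 0
  n_conf <- round(f_conf * n_mal)
  n_stiff <- floor(n_conf / 2)
  mech_pool <- c(rep("stiff", n_stiff), rep("viscous", n_conf - n_stiff),
                 rep("none", n_mal - n_conf))
  mech_pool <- with_seed(derive_seed(cohort$seed, "mechanisms"),
                         sample(mech_pool))
  mechanisms <- rep("none", n)
  mechanisms[labels == "malignant"] <- mech_pool
  nz <- cohort$grid_shape[1]
  axial_spacing <- cohort$axial_extent_mm / nz
  lat_center <- (cohort$grid_shape[2] - 1) * cohort$lateral_spacing / 2
  lapply(seq_len(n), function(i) {
    lesion_seed <- derive_seed(cohort$seed, "lesion", i)
    par <- draw_lesion(cohort, labels[i], lesion_seed, mechanisms[i])
    phantoms <- lapply(seq_along(cohort$rotations), function(j) {
      rot <- cohort$rotations[j]
      spec <- phantom_spec(
        grid_shape = cohort$grid_shape,
        axial_spacing = axial_spacing,
        lateral_spacing = cohort$lateral_spacing,
        background_E = cohort$background_E,
        background_mu = cohort$background_mu,
        lesion_center = c(lat_center, par$depth),
        lesion_axes = c(par$semi_major, par$semi_minor),
        lesion_rotation = par$angle + rot,
        lesion_E = par$core_E, lesion_mu = par$core_mu,
        margin_width = par$margin_width,
        margin_E_factor = par$margin_E_factor,
        margin_mu_factor = par$margin_mu_factor,
        heterogeneity_cv = cohort$heterogeneity_cv,
        label = labels[i],
        seed = derive_seed(lesion_seed, "rotation", j))
      make_phantom(spec)
    })
    list(lesion_id = i, label = labels[i], params = par,
         phantoms = phantoms, rotations = cohort$rotations)
  })
}
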