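#' Specification of a viscoelastic lesion phantom
#'
#' Describes a 2-D (axial x lateral) field of elasticity and viscosity
#' containing one elliptical lesion whose mechanical margin may extend
#' beyond, or recede inside, the B-mode-visible boundary.  The default
#' grid matches the acquisition geometry: 2049 axial samples over ~40 mm
#' and 40 lateral lines over 20 mm.
#'
#' The signed `margin_width` encodes the class-conditional margin
#' mechanics: positive widths place a mechanically altered annulus
#' outside the B-mode ellipse (parametric lesion larger than B-mode, the
#' malignant pattern), negative widths replace the outer ring of the
#' lesion with background-like material (parametric lesion smaller, the
#' benign pattern).  Margin material is `margin_E_factor` /
#' `margin_mu_factor` times the background values.
#'
#' @param grid_shape integer vector `(axial_samples, lateral_lines)`.
#' @param axial_spacing axial sample spacing in mm.
#' @param lateral_spacing lateral line spacing in mm.
#' @param background_E,background_mu background elasticity (kPa) and
#'   viscosity (Pa.s).
#' @param lesion_center `(lateral mm, axial mm)` of the lesion center.
#' @param lesion_axes `(semi-major mm, semi-minor mm)` of the B-mode
#'   ellipse.
#' @param lesion_rotation rotation of the major axis in degrees
#'   (0 = lateral).
#' @param lesion_E,lesion_mu lesion-core elasticity (kPa) and viscosity
#'   (Pa.s).
#' @param margin_width signed parametric margin width in mm (see above);
#'   must satisfy `abs(margin_width) < semi-minor axis`.
#' @param margin_E_factor,margin_mu_factor margin material as multiples
#'   of the background values.
#' @param heterogeneity_cv fractional coefficient of variation of the
#'   multiplicative lognormal material heterogeneity (spatially white).
#' @param bmode_contrast_db lesion echogenicity relative to background in
#'   dB (negative = hypoechoic).
#' @param scatterers_per_mm point-scatterer density per mm of depth per
#'   line; the default (24/mm, about 12 per two-cycle 6.15 MHz pulse)
#'   gives fully developed speckle.
#' @param label `"benign"` or `"malignant"`.
#' @param seed integer seed making the phantom deterministic.
#' @return An object of class `visr_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(2049, 40),
                         axial_spacing = 0.0195, lateral_spacing = 0.5,
                         background_E = 5, background_mu = 1,
                         lesion_center = c(10, 20),
                         lesion_axes = c(6, 4), lesion_rotation = 0,
                         lesion_E = 10, lesion_mu = 2,
                         margin_width = 0,
                         margin_E_factor = 1, margin_mu_factor = 1,
                         heterogeneity_cv = 0, bmode_contrast_db = -6,
                         scatterers_per_mm = 24,
                         label = "benign", seed = 1) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 2),
            axial_spacing > 0, lateral_spacing > 0,
            background_E > 0, background_mu >= 0,
            lesion_E > 0, lesion_mu >= 0,
            margin_E_factor > 0, margin_mu_factor >= 0,
            all(lesion_axes > 0), heterogeneity_cv >= 0,
            scatterers_per_mm > 0,
            label %in% c("benign", "malignant"))
  if (abs(margin_width) >= lesion_axes[2]) {
    stop("abs(margin_width) must be smaller than the semi-minor axis")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 axial_spacing = axial_spacing,
                 lateral_spacing = lateral_spacing,
                 background_E = background_E, background_mu = background_mu,
                 lesion_center = lesion_center, lesion_axes = lesion_axes,
                 lesion_rotation = lesion_rotation,
                 lesion_E = lesion_E, lesion_mu = lesion_mu,
                 margin_width = margin_width,
                 margin_E_factor = margin_E_factor,
                 margin_mu_factor = margin_mu_factor,
                 heterogeneity_cv = heterogeneity_cv,
                 bmode_contrast_db = bmode_contrast_db,
                 scatterers_per_mm = scatterers_per_mm,
                 label = label, seed = as.integer(seed)),
            class = "visr_phantom_spec")
}

# Squared elliptical radius of grid/arbitrary points for given semi-axes,
# in the lesion's rotated frame.
ellipse_q <- function(lat, ax, center, axes, rot_deg) {
  th <- rot_deg * pi / 180
  u <- lat - center[1]; v <- ax - center[2]
  p <- u * cos(th) + v * sin(th)
  q <- -u * sin(th) + v * cos(th)
  (p / axes[1])^2 + (q / axes[2])^2
}


#' Generate a lesion phantom
#'
#' Realizes a [phantom_spec()] into per-pixel elasticity and viscosity
#' maps, the B-mode lesion mask, and per-line point-scatterer sets for RF
#' synthesis.  Material maps are background (times lognormal
#' heterogeneity with the requested CV) outside the lesion, lesion-core
#' values inside, and margin-factor-scaled background in an elliptical
#' annulus of width `abs(margin_width)` placed outside
#' (`margin_width > 0`) or inside (`margin_width < 0`) the B-mode
#' boundary.  Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `visr_phantom` with elements `E_map`,
#'   `mu_map`, `bmode_mask`, `echo_map`, `scatterers`, `axial_mm`,
#'   `lateral_mm` and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "visr_phantom_spec"))
  nz <- spec$grid_shape[1]; nx <- spec$grid_shape[2]
  axial_mm <- (seq_len(nz) - 1) * spec$axial_spacing
  lateral_mm <- (seq_len(nx) - 1) * spec$lateral_spacing
  a <- spec$lesion_axes[1]; b <- spec$lesion_axes[2]
  mw <- spec$margin_width
  # reject lesions (including a positive margin) not fully inside the grid
  th <- spec$lesion_rotation * pi / 180
  ext_a <- a + max(mw, 0); ext_b <- b + max(mw, 0)
  half_lat <- sqrt((ext_a * cos(th))^2 + (ext_b * sin(th))^2)
  half_ax <- sqrt((ext_a * sin(th))^2 + (ext_b * cos(th))^2)
  if (spec$lesion_center[1] - half_lat < 0 ||
      spec$lesion_center[1] + half_lat > max(lateral_mm)) {
    stop("lesion extends outside the grid along the lateral axis")
  }
  if (spec$lesion_center[2] - half_ax < 0 ||
      spec$lesion_center[2] + half_ax > max(axial_mm)) {
    stop("lesion extends outside the grid along the axial axis")
  }
  lat_g <- matrix(lateral_mm, nz, nx, byrow = TRUE)
  ax_g <- matrix(axial_mm, nz, nx)
  q_bmode <- ellipse_q(lat_g, ax_g, spec$lesion_center,
                       c(a, b), spec$lesion_rotation)
  bmode_mask <- q_bmode <= 1
  if (mw >= 0) {
    core <- bmode_mask
    q_out <- ellipse_q(lat_g, ax_g, spec$lesion_center,
                       c(a + mw, b + mw), spec$lesion_rotation)
    annulus <- (q_out <= 1) & !bmode_mask
  } else {
    q_in <- ellipse_q(lat_g, ax_g, spec$lesion_center,
                      c(a + mw, b + mw), spec$lesion_rotation)
    core <- q_in <= 1
    annulus <- bmode_mask & !core
  }
  E_map <- matrix(spec$background_E, nz, nx)
  mu_map <- matrix(spec$background_mu, nz, nx)
  E_map[annulus] <- spec$background_E * spec$margin_E_factor
  mu_map[annulus] <- spec$background_mu * spec$margin_mu_factor
  E_map[core] <- spec$lesion_E
  mu_map[core] <- spec$lesion_mu
  with_seed(derive_seed(spec$seed, "material"), {
    E_map <- E_map * lognormal_noise(nz * nx, spec$heterogeneity_cv)
    mu_map <- mu_map * lognormal_noise(nz * nx, spec$heterogeneity_cv)
  })
  echo_amp <- 10^(spec$bmode_contrast_db / 20)
  echo_map <- matrix(1, nz, nx)
  echo_map[bmode_mask] <- echo_amp
  depth_extent <- max(axial_mm)
  n_scat <- max(2L, round(spec$scatterers_per_mm * depth_extent))
  scatterers <- with_seed(derive_seed(spec$seed, "scatterers"), {
    lapply(seq_len(nx), function(j) {
      z <- sort(stats::runif(n_scat, 0, depth_extent))
      amp <- stats::rnorm(n_scat)
      q <- ellipse_q(lateral_mm[j], z, spec$lesion_center,
                     c(a, b), spec$lesion_rotation)
      amp <- amp * ifelse(q <= 1, echo_amp, 1)
      data.frame(axial_mm = z, reflectivity = amp)
    })
  })
  structure(list(E_map = E_map, mu_map = mu_map, bmode_mask = bmode_mask,
                 echo_map = echo_map, scatterers = scatterers,
                 axial_mm = axial_mm, lateral_mm = lateral_mm,
                 lesion_q = q_bmode, spec = spec),
            class = "visr_phantom")
}

#' Lesion boundary polygon
#'
#' Traces the contour of the phantom's B-mode lesion mask as a closed
#' polygon in physical mm coordinates, resampled to evenly spaced
#' vertices in counter-clockwise orientation (positive shoelace area in
#' the (lateral, axial) plane).  The contour is extracted at the
#' half-level of the smooth lesion indicator, giving sub-pixel accuracy;
#' it stands in for the radiologist's B-mode outline.
#'
#' @param phantom a [make_phantom()] result.
#' @param n_vertices number of evenly spaced vertices (>= 8).
#' @return A `visr_polygon`: data frame with columns `lateral_mm`,
#'   `axial_mm`, attribute `source = "bmode"`.
#' @export
lesion_boundary <- function(phantom, n_vertices = 256) {
  stopifnot(inherits(phantom, "visr_phantom"), n_vertices >= 8)
  if (!any(phantom$bmode_mask)) stop("bmode_mask is empty")
  z <- phantom$lesion_q
  cl <- grDevices::contourLines(x = phantom$axial_mm, y = phantom$lateral_mm,
                                z = z, levels = 1)
  if (!length(cl)) stop("no lesion contour found")
  # largest contour by enclosed area
  areas <- vapply(cl, function(cc) abs(shoelace_area(cc$y, cc$x)), numeric(1))
  cc <- cl[[which.max(areas)]]
  poly <- resample_polygon(cc$y, cc$x, n_vertices)
  structure(data.frame(lateral_mm = poly$x, axial_mm = poly$y),
            class = c("visr_polygon", "data.frame"), source = "bmode")
}

# Resample a closed polygon to n evenly spaced vertices by arc length and
# force counter-clockwise orientation (positive shoelace area).
resample_polygon <- function(x, y, n) {
  if (x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  if (shoelace_area(x, y) < 0) {
    x <- rev(x); y <- rev(y)
  }
  xc <- c(x, x[1]); yc <- c(y, y[1])
  seg <- sqrt(diff(xc)^2 + diff(yc)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  t_new <- seq(0, total, length.out = n + 1)[-(n + 1)]
  xi <- stats::approx(s, xc, xout = t_new)$y
  yi <- stats::approx(s, yc, xout = t_new)$y
  list(x = xi, y = yi)
}

#' Polygon area and perimeter
#'
#' Shoelace area (mm^2) and arc-length perimeter (mm) of a boundary
#' polygon.
#'
#' @param polygon a `visr_polygon`.
#' @return A list with `area`, `perimeter`, `centroid` (lateral, axial).
#' @export
polygon_measures <- function(polygon) {
  x <- polygon$lateral_mm; y <- polygon$axial_mm
  A <- shoelace_area(x, y)
  n <- length(x); j <- c(2:n, 1)
  cross <- x * y[j] - x[j] * y
  cx <- sum((x + x[j]) * cross) / (6 * A)
  cy <- sum((y + y[j]) * cross) / (6 * A)
  list(area = abs(A), perimeter = polygon_perimeter(x, y),
       centroid = c(cx, cy), signed_area = A)
}

#' PD-matched viscoelastic parameter pair
#'
#' Finds a second Voigt parameter pair whose sampled double-push peak
#' displacement matches that of `(E1, mu1)` under the given sequence.
#' With the elasticity fixed at `E2 = E1 / 2`, the viscosity `mu2 > mu1`
#' is found by 1-D root solving, producing the softer-but-more-viscous
#' member of a peak-displacement level set: two materials a displacement
#' image cannot distinguish although their elasticity differs two-fold.
#'
#' @param E1 elasticity in kPa.
#' @param mu1 viscosity in Pa.s (small relative to the push duration
#'   time-scale, so that the level set reaches `E1 / 2`).
#' @param seq a [tracking_seq()].
#' @return A list `E2`, `mu2`, `pd1`, `pd2`, `pd_ratio`.
#' @export
confound_pair <- function(E1, mu1, seq = tracking_seq()) {
  pd_matched_pair(E1, mu1, seq, E2 = E1 / 2)
}

#' @rdname confound_pair
#' @param E2 elasticity of the matched pair in kPa (any positive value on
#'   the reachable part of the peak-displacement level set).
#' @export
pd_matched_pair <- function(E1, mu1, seq = tracking_seq(), E2) {
  stopifnot(E1 > 0, mu1 >= 0, E2 > 0)
  tl <- tracking_times(seq)
  sched <- force_schedule(seq, 1)
  pd_of <- function(E, mu) {
    peak_displacement(voigt_response(material_point(E, mu), sched,
                                     tl$sample_times_s))
  }
  target <- pd_of(E1, mu1)
  # Sampled PD is not monotone in viscosity: it vanishes as mu -> 0
  # (the material relaxes before the first post-push sample) and decays
  # again for large mu.  Solve on the decreasing branch beyond the PD
  # peak, which selects the more-viscous member of the level set.
  pk <- stats::optimize(function(lmu) -pd_of(E2, exp(lmu)),
                        c(log(1e-8), log(1e4)), tol = 1e-9)
  mu_pk <- exp(pk$minimum)
  if (-pk$objective < target) {
    stop("no root in bracket [", signif(mu_pk, 3), ", 1e4] Pa.s: ",
         "maximal sampled peak displacement at E2 = ", E2, " kPa is ",
         signif(-pk$objective, 6), " um, below the target ",
         signif(target, 6), " um")
  }
  f <- function(lmu) pd_of(E2, exp(lmu)) - target
  lo <- log(mu_pk); hi <- lo + log(10)
  while (f(hi) > 0 && hi < log(1e6)) hi <- hi + log(10)
  if (f(hi) > 0) {
    stop("no root in bracket [", signif(exp(lo), 3), ", ",
         signif(exp(hi), 3), "] Pa.s for E2 = ", E2, " kPa")
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
  mu2 <- exp(root$root)
  pd2 <- pd_of(E2, mu2)
  list(E2 = E2, mu2 = mu2, pd1 = target, pd2 = pd2, pd_ratio = pd2 / target)
}
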