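#' Compute co-registered parametric images for one lesion view
#'
#' Runs the per-pixel estimation chain on a phantom: peak displacement
#' (PD) from the maximum of the displacement profile, relative
#' elasticity (RE) and relative viscosity (RV) from the Voigt double-push
#' fit, and a B-mode image, all on the phantom grid.
#'
#' In `"ideal"` mode the displacement profiles are the closed-form Voigt
#' responses of the local material (no RF, no tracking noise) with the
#' push amplitude scaled by the depth-attenuation profile, and B-mode is
#' an echogenicity rendering of the lesion with multiplicative speckle
#' noise.  In `"rf"` mode RF speckle is synthesized per line, axial
#' displacement is recovered by normalized cross-correlation, profiles
#' are resampled to the phantom grid rows, and B-mode is the
#' log-compressed envelope of the reference RF.
#'
#' Pixels whose fit does not converge are filled with the 3x3 median of
#' converged neighbours and flagged in `converged`.
#'
#' @param phantom a [make_phantom()] result.
#' @param seq a [tracking_seq()].
#' @param ac an [acoustics_spec()].
#' @param mode `"ideal"` or `"rf"`.
#' @param seed seed for RF synthesis and B-mode speckle.
#' @param fit_cfg fit settings from [visr_fit_config()].
#' @return An object of class `visr_images` with matrices `bmode`, `pd`,
#'   `re`, `rv`, `converged`, plus grid geometry and the originating
#'   phantom spec.
#' @export
compute_images <- function(phantom, seq = tracking_seq(),
                           ac = acoustics_spec(), mode = c("ideal", "rf"),
                           seed = 1, fit_cfg = visr_fit_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(phantom, "visr_phantom"))
  nz <- nrow(phantom$E_map); nx <- ncol(phantom$E_map)
  tl <- tracking_times(seq)
  nt <- length(tl$sample_times_s)
  if (mode == "ideal") {
    E <- as.vector(phantom$E_map)
    mu <- as.vector(phantom$mu_map)
    z <- rep(phantom$axial_mm, times = nx)
    amp <- depth_amplitude(ac, z, seq$push_freq)
    tau_s <- (mu / E) * 1e-3
    A <- visr_force_scale * amp / (E * 1000)
    D <- voigt_profile_matrix(tau_s, A, tl$sample_times_s,
                              tl$push_onsets_s, tl$push_dur_s)
    bmode <- phantom$echo_map *
      matrix(with_seed(derive_seed(seed, "bmode"),
                       lognormal_noise(nz * nx, 0.25)), nz, nx)
  } else {
    rf <- synth_rf(phantom, seq, ac, seed = seed)
    trk <- ncc_track(rf)
    D <- matrix(0, nz * nx, nt)
    track_cols <- which(!tl$is_reference)
    env_ref <- matrix(0, nz, nx)
    for (j in seq_len(nx)) {
      dl <- trk$lines[[j]]
      # resample kernel-grid displacement onto the phantom rows
      for (k in seq_along(track_cols)) {
        D[(j - 1) * nz + seq_len(nz), track_cols[k]] <-
          stats::approx(trk$kernel_centers_mm, dl$disp_um[, k],
                        xout = phantom$axial_mm, rule = 2)$y
      }
      env <- rf_envelope(rf$lines[[j]]$ref)
      env_ref[, j] <- stats::approx(rf$z_mm, env,
                                    xout = phantom$axial_mm, rule = 2)$y
    }
    env_ref <- env_ref / max(env_ref)
    bmode <- 20 * log10(pmax(env_ref, 1e-4))   # dB, log-compressed
    bmode <- bmode - min(bmode)
  }
  fit <- fit_visr_grid(D, seq, fit_cfg)
  re <- matrix(fit$re, nz, nx)
  rv <- matrix(fit$rv, nz, nx)
  pd <- matrix(fit$pd, nz, nx)
  conv <- matrix(fit$converged, nz, nx)
  if (!all(conv)) {
    re <- fill_unconverged(re, conv)
    rv <- fill_unconverged(rv, conv)
  }
  structure(list(bmode = bmode, pd = pd, re = re, rv = rv,
                 converged = conv,
                 axial_mm = phantom$axial_mm,
                 lateral_mm = phantom$lateral_mm,
                 rotation = phantom$spec$lesion_rotation,
                 mode = mode, spec = phantom$spec),
            class = "visr_images")
}

# Replace non-converged pixels with the median of converged neighbours in
# a 3x3 window (left NA if no converged neighbour exists).
fill_unconverged <- function(img, conv) {
  bad <- which(!conv, arr.ind = TRUE)
  nz <- nrow(img); nx <- ncol(img)
  for (r in seq_len(nrow(bad))) {
    i <- bad[r, 1]; j <- bad[r, 2]
    ii <- max(1, i - 1):min(nz, i + 1)
    jj <- max(1, j - 1):min(nx, j + 1)
    vals <- img[ii, jj][conv[ii, jj]]
    img[i, j] <- if (length(vals)) stats::median(vals) else NA_real_
  }
  img
}

#' Calibration settings for depth and elasticity corrections
#'
#' @param E,mu homogeneous calibration material (kPa, Pa.s).
#' @param grid_shape calibration phantom grid.
#' @param axial_extent_mm axial extent of the calibration grid.
#' @param E_grid,mu_grid known material grids for the elasticity-bias
#'   table.
#' @return A list of calibration settings.
#' @export
calibration_spec <- function(E = 5, mu = 1, grid_shape = c(256, 12),
                             axial_extent_mm = 40,
                             E_grid = seq(2, 20, by = 2),
                             mu_grid = seq(0, 4, by = 0.5)) {
  list(E = E, mu = mu, grid_shape = as.integer(grid_shape),
       axial_extent_mm = axial_extent_mm, E_grid = E_grid,
       mu_grid = mu_grid)
}

# Build a homogeneous phantom: a degenerate lesion identical to the
# background, used for calibration runs.
homogeneous_phantom <- function(E, mu, grid_shape, axial_extent_mm,
                                heterogeneity_cv = 0, seed = 1) {
  nz <- grid_shape[1]
  spec <- phantom_spec(grid_shape = grid_shape,
                       axial_spacing = axial_extent_mm / nz,
                       lateral_spacing = 0.5,
                       background_E = E, background_mu = mu,
                       lesion_E = E, lesion_mu = mu,
                       lesion_center = c((grid_shape[2] - 1) * 0.25,
                                         axial_extent_mm / 2),
                       lesion_rotation = 0,
                       lesion_axes = c(2, 1.5),
                       heterogeneity_cv = heterogeneity_cv,
                       bmode_contrast_db = 0, seed = seed)
  make_phantom(spec)
}

#' Build depth and elasticity calibration curves
#'
#' Simulates a homogeneous phantom under the depth-dependent push
#' amplitude and records the median fitted RE, RV and PD per depth row
#' (the depth curves), then simulates a grid of known `(E, mu)` points at
#' the focal depth and tabulates the RV bias factor (fitted RV over the
#' RV expected from the true relaxation time) as a function of fitted RE
#' (the elasticity-bias table).  Calibration runs on the analytic
#' (ideal-mode) chain.
#'
#' @param seq a [tracking_seq()].
#' @param ac an [acoustics_spec()].
#' @param cal_spec a [calibration_spec()].
#' @param fit_cfg fit settings.
#' @return An object of class `visr_calibration`: `depth_mm`, `re_curve`,
#'   `rv_curve`, `pd_curve`, `focal_depth_mm`, and `bias_table`
#'   (`re`, `factor`).
#' @export
build_calibration <- function(seq = tracking_seq(), ac = acoustics_spec(),
                              cal_spec = calibration_spec(),
                              fit_cfg = visr_fit_config()) {
  ph <- homogeneous_phantom(cal_spec$E, cal_spec$mu, cal_spec$grid_shape,
                            cal_spec$axial_extent_mm)
  img <- compute_images(ph, seq, ac, mode = "ideal", fit_cfg = fit_cfg)
  re_curve <- apply(img$re, 1, stats::median)
  rv_curve <- apply(img$rv, 1, stats::median)
  pd_curve <- apply(img$pd, 1, stats::median)
  # elasticity-bias table at focal depth
  tl <- tracking_times(seq)
  amp_f <- depth_amplitude(ac, ac$focal_depth_mm, seq$push_freq)
  grid <- expand.grid(E = cal_spec$E_grid, mu = cal_spec$mu_grid)
  tau_s <- (grid$mu / grid$E) * 1e-3
  A <- visr_force_scale * amp_f / (grid$E * 1000)
  D <- voigt_profile_matrix(tau_s, A, tl$sample_times_s,
                            tl$push_onsets_s, tl$push_dur_s)
  fit <- fit_visr_grid(D, seq, fit_cfg)
  rv_true <- (grid$mu / grid$E) / A      # true tau (ms) times true RE
  bias <- ifelse(rv_true > 1e-9 * max(rv_true, 1), fit$rv / rv_true, 1)
  ord <- order(fit$re)
  bias_table <- data.frame(re = fit$re[ord], factor = bias[ord])
  # pool duplicated RE values (same E, different mu)
  bias_table <- stats::aggregate(factor ~ re, bias_table, stats::median)
  structure(list(depth_mm = ph$axial_mm, re_curve = re_curve,
                 rv_curve = rv_curve, pd_curve = pd_curve,
                 focal_depth_mm = ac$focal_depth_mm,
                 bias_table = bias_table),
            class = "visr_calibration")
}

#' Apply depth and elasticity corrections
#'
#' Multiplies RE and RV per image row by the ratio of the calibration
#' curve's focal-depth median to its row median (depth correction), then
#' divides RV by the elasticity-bias factor interpolated at the local
#' corrected RE (elasticity correction).  PD is left uncorrected.
#' Depths outside the calibration range use nearest-edge extrapolation
#' with a warning.
#'
#' @param images a [compute_images()] result.
#' @param cal a [build_calibration()] result.
#' @return The corrected `visr_images` object (attribute `corrected`).
#' @export
apply_corrections <- function(images, cal) {
  stopifnot(inherits(images, "visr_images"), inherits(cal, "visr_calibration"))
  z <- images$axial_mm
  if (min(z) < min(cal$depth_mm) - 1e-9 ||
      max(z) > max(cal$depth_mm) + 1e-9) {
    warning("image depth range extends outside the calibration curves; ",
            "using nearest-edge extrapolation")
  }
  ref_re <- stats::approx(cal$depth_mm, cal$re_curve,
                          xout = cal$focal_depth_mm, rule = 2)$y
  ref_rv <- stats::approx(cal$depth_mm, cal$rv_curve,
                          xout = cal$focal_depth_mm, rule = 2)$y
  row_re <- stats::approx(cal$depth_mm, cal$re_curve, xout = z, rule = 2)$y
  row_rv <- stats::approx(cal$depth_mm, cal$rv_curve, xout = z, rule = 2)$y
  images$re <- images$re * (ref_re / row_re)
  images$rv <- images$rv * (ref_rv / row_rv)
  bt <- cal$bias_table
  if (nrow(bt) >= 2) {
    bias <- stats::approx(bt$re, bt$factor, xout = as.vector(images$re),
                          rule = 2)$y
  } else {
    bias <- rep(bt$factor, length(images$re))
  }
  images$rv <- images$rv / matrix(bias, nrow(images$rv), ncol(images$rv))
  attr(images, "corrected") <- TRUE
  images
}
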