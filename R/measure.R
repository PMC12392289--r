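#' Measurement settings for automated E/B
#'
#' @param step_frac profile sampling step as a fraction of the smaller
#'   pixel spacing (quarter-pixel by default).
#' @param extension_frac search-window extension beyond each B-mode
#'   endpoint, as a fraction of the B-mode radius.
#' @param contrast_floor minimum relative lesion/background contrast
#'   `|L - B| / ((|L| + |B|)/2)` below which endpoints are not adjusted.
#' @param cnr_threshold contrast-to-noise threshold below which an image
#'   is flagged unsure.
#' @param persistence_mm length over which the profile must stay on the
#'   far side of the half level for a crossing to count as a boundary
#'   (suppresses single-pixel noise excursions).
#' @return A list of measurement settings.
#' @export
measure_config <- function(step_frac = 0.25, extension_frac = 0.5,
                           contrast_floor = 0.05, cnr_threshold = 0.5,
                           persistence_mm = 0.5) {
  stopifnot(step_frac > 0, extension_frac > 0, contrast_floor >= 0,
            cnr_threshold >= 0, persistence_mm >= 0)
  list(step_frac = step_frac, extension_frac = extension_frac,
       contrast_floor = contrast_floor, cnr_threshold = cnr_threshold,
       persistence_mm = persistence_mm)
}

new_roi <- function(p1, p2, modality) {
  len <- sqrt(sum((p2 - p1)^2))
  structure(list(endpoints = rbind(p1, p2), length = len,
                 modality = modality), class = "visr_roi")
}

#' Largest lesion diameter from the boundary polygon
#'
#' Brute-force search over all vertex pairs of the (resampled) boundary
#' for the pair with maximal Euclidean distance; ties are broken towards
#' the pair whose segment makes the smallest angle with the lateral
#' axis.
#'
#' @param boundary a `visr_polygon`.
#' @param modality modality tag stored on the ROI.
#' @return A `visr_roi` with `endpoints` (2 x 2 matrix of (lateral,
#'   axial) mm) and `length` in mm.
#' @export
largest_diameter <- function(boundary, modality = "bmode") {
  x <- boundary$lateral_mm; y <- boundary$axial_mm
  if (abs(shoelace_area(x, y)) < 1e-9) stop("degenerate polygon (zero area)")
  n <- length(x)
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  d2 <- dx^2 + dy^2
  dmax <- max(d2)
  cand <- which(d2 >= dmax * (1 - 1e-12), arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  if (nrow(cand) > 1) {
    ang <- abs(atan2(y[cand[, 2]] - y[cand[, 1]],
                     x[cand[, 2]] - x[cand[, 1]]))
    ang <- pmin(ang, pi - ang)
    cand <- cand[which.min(ang), , drop = FALSE]
  }
  i <- cand[1, 1]; j <- cand[1, 2]
  new_roi(c(x[i], y[i]), c(x[j], y[j]), modality)
}

# Sample an image along the (extended) diameter line.  Returns the
# parameter grid t (mm along the line from endpoint 1), the profile, and
# the in-boundary flag of each sample.
profile_along_line <- function(roi, image, axial_mm, lateral_mm,
                               boundary, cfg) {
  p1 <- roi$endpoints[1, ]; p2 <- roi$endpoints[2, ]
  L <- roi$length
  u <- (p2 - p1) / L
  ext <- cfg$extension_frac * (L / 2)
  step <- cfg$step_frac * min(diff(axial_mm)[1], diff(lateral_mm)[1])
  t <- seq(-ext, L + ext, by = step)
  lat <- p1[1] + t * u[1]
  ax <- p1[2] + t * u[2]
  prof <- bilinear_sample(image, axial_mm, lateral_mm, ax, lat)
  inside <- points_in_polygon(lat, ax, boundary$lateral_mm,
                              boundary$axial_mm)
  list(t = t, profile = prof, inside = inside, step = step, u = u,
       p1 = p1, p2 = p2, L = L)
}

#' Adjust diameter endpoints on a parametric image
#'
#' Automated surrogate for the reader's endpoint adjustment: the B-mode
#' diameter line is fixed in position and orientation; along it
#' (extended by `extension_frac` of the B-mode radius beyond each
#' endpoint) the parametric profile is sampled at quarter-pixel steps
#' with bilinear interpolation.  The lesion level `L` is the median
#' profile value inside the B-mode boundary; the background level `B`
#' is the median of the image over the surrounding annulus (the
#' perceived background; the line tails alone can be dominated by an
#' extended margin).  Each endpoint moves to the crossing of the half
#' level `(L + B)/2` found by walking along the line from the B-mode
#' endpoint: outward while the profile stays on the lesion side of the
#' level (capturing an extended margin up to the window edge), inward
#' otherwise (capturing a receded parametric extent).  If no crossing
#' exists within the window the endpoint stays at the B-mode location.
#' If the lesion/background contrast is below `contrast_floor` the ROI
#' is returned unchanged with a `low_contrast` attribute.
#'
#' @param roi the B-mode `visr_roi`.
#' @param image parametric image matrix (axial x lateral).
#' @param axial_mm,lateral_mm grid coordinates of `image`.
#' @param boundary the B-mode `visr_polygon`.
#' @param cfg a [measure_config()].
#' @param modality modality tag for the returned ROI.
#' @param masks optional precomputed [boundary_masks()] result.
#' @return A `visr_roi` with adjusted endpoints; attributes
#'   `low_contrast` (logical) and `n_unadjusted` (count of endpoints
#'   left at the B-mode location).
#' @export
adjust_endpoints <- function(roi, image, axial_mm, lateral_mm, boundary,
                             cfg = measure_config(), modality = "param",
                             masks = NULL) {
  pr <- profile_along_line(roi, image, axial_mm, lateral_mm, boundary, cfg)
  if (is.null(masks)) {
    masks <- boundary_masks(axial_mm, lateral_mm, boundary)
  }
  Lmed <- stats::median(pr$profile[pr$inside])
  Bmed <- stats::median(image[masks$annulus], na.rm = TRUE)
  if (!is.finite(Lmed) || !is.finite(Bmed)) {
    out <- new_roi(pr$p1, pr$p2, modality)
    attr(out, "low_contrast") <- TRUE
    return(out)
  }
  contrast <- abs(Lmed - Bmed) / ((abs(Lmed) + abs(Bmed)) / 2 + 1e-300)
  if (contrast < cfg$contrast_floor) {
    out <- new_roi(pr$p1, pr$p2, modality)
    attr(out, "low_contrast") <- TRUE
    attr(out, "n_unadjusted") <- 2L
    return(out)
  }
  level <- (Lmed + Bmed) / 2
  # signed profile: positive on the lesion side of the half level
  g <- (pr$profile - level) * sign(Lmed - Bmed)
  # Walk from the B-mode endpoint: if the profile there is on the lesion
  # side, move outward to the first crossing of the half level (the
  # outermost edge of the connected lesion-side run, immune to isolated
  # noise excursions further out); otherwise move inward to the first
  # crossing.  NULL if the walk leaves the window without crossing.
  n_pers <- max(1L, round(cfg$persistence_mm / pr$step))
  find_endpoint <- function(t_end, outward_positive) {
    i_end <- which.min(abs(pr$t - t_end))
    dir_out <- if (outward_positive) 1L else -1L
    walk <- function(from, dir, want_negative) {
      idx <- seq(from, if (dir > 0) length(g) else 1L, by = dir)
      if (length(idx) < 2) return(NULL)
      for (k in 2:length(idx)) {
        i0 <- idx[k - 1]; i1 <- idx[k]
        hit <- if (want_negative) g[i1] <= 0 else g[i1] > 0
        if (hit) {
          # crossing counts only if the profile stays on the new side
          # (on average) over the persistence window
          win <- idx[k:min(k + n_pers - 1, length(idx))]
          gbar <- mean(g[win])
          sustained <- if (want_negative) gbar <= 0 else gbar > 0
          if (!sustained) next
          if (g[i1] == g[i0]) return(pr$t[i1])
          return(pr$t[i0] + (pr$t[i1] - pr$t[i0]) * g[i0] / (g[i0] - g[i1]))
        }
      }
      NULL
    }
    if (g[i_end] > 0) {
      walk(i_end, dir_out, want_negative = TRUE)
    } else {
      walk(i_end, -dir_out, want_negative = FALSE)
    }
  }
  t1 <- find_endpoint(0, outward_positive = FALSE)
  t2 <- find_endpoint(pr$L, outward_positive = TRUE)
  n_unadj <- sum(is.null(t1), is.null(t2))
  t1 <- t1 %||% 0
  t2 <- t2 %||% pr$L
  if (t2 <= t1) {   # degenerate adjustment: fall back to B-mode ROI
    t1 <- 0; t2 <- pr$L; n_unadj <- 2L
  }
  q1 <- pr$p1 + t1 * pr$u
  q2 <- pr$p1 + t2 * pr$u
  out <- new_roi(q1, q2, modality)
  attr(out, "low_contrast") <- FALSE
  attr(out, "n_unadjusted") <- n_unadj
  out
}

#' Elastogram-to-B-mode diameter ratio
#'
#' @param param_roi diameter ROI measured on the parametric image.
#' @param bmode_roi diameter ROI on B-mode.
#' @return The ratio of parametric to B-mode diameter length.
#' @export
eb_ratio <- function(param_roi, bmode_roi) {
  if (param_roi$length <= 0 || bmode_roi$length <= 0) {
    stop("diameter lengths must be positive")
  }
  param_roi$length / bmode_roi$length
}

#' Contrast-to-noise quality flag
#'
#' CNR between the lesion interior and a surrounding annulus of width
#' one lesion-equivalent radius:
#' `CNR = |mean_in - mean_out| / sqrt(var_in + var_out)`.
#' Images with CNR below the threshold are flagged unsure (the lesion
#' boundary is taken to be visually unrecognizable).
#'
#' @param image parametric image matrix.
#' @param axial_mm,lateral_mm grid coordinates.
#' @param boundary the B-mode `visr_polygon`.
#' @param threshold unsure threshold on CNR.
#' @param masks optional precomputed list `(inside, annulus)` of logical
#'   matrices, to avoid repeated point-in-polygon tests.
#' @return A list `cnr`, `unsure`, `threshold`.
#' @export
quality_flag <- function(image, axial_mm, lateral_mm, boundary,
                         threshold = 0.5, masks = NULL) {
  if (is.null(masks)) {
    masks <- boundary_masks(axial_mm, lateral_mm, boundary)
  }
  vin <- image[masks$inside]
  vout <- image[masks$annulus]
  vin <- vin[is.finite(vin)]; vout <- vout[is.finite(vout)]
  if (!length(vin) || !length(vout)) {
    return(list(cnr = 0, unsure = TRUE, threshold = threshold))
  }
  cnr <- abs(mean(vin) - mean(vout)) /
    sqrt(stats::var(vin) + stats::var(vout) + 1e-300)
  list(cnr = cnr, unsure = cnr < threshold, threshold = threshold)
}

#' Lesion-interior and background-annulus masks
#'
#' Pixel masks of the lesion interior and of a background annulus of
#' one lesion-equivalent-radius width, built by scaling the boundary
#' polygon about its centroid and clipping to the grid.  The annulus
#' starts half an equivalent radius outside the boundary so that the
#' zone where an altered parametric margin may sit does not contaminate
#' the background estimate.
#'
#' @param axial_mm,lateral_mm grid coordinates.
#' @param boundary a `visr_polygon`.
#' @return A list of logical matrices `inside` and `annulus`.
#' @export
boundary_masks <- function(axial_mm, lateral_mm, boundary) {
  pm <- polygon_measures(boundary)
  r_eq <- sqrt(pm$area / pi)
  s_in <- (r_eq + 0.5 * r_eq) / r_eq
  s_out <- (r_eq + 1.5 * r_eq) / r_eq
  cx <- pm$centroid[1]; cy <- pm$centroid[2]
  nz <- length(axial_mm); nx <- length(lateral_mm)
  lat_g <- rep(lateral_mm, each = nz)
  ax_g <- rep(axial_mm, times = nx)
  inside <- points_in_polygon(lat_g, ax_g, boundary$lateral_mm,
                              boundary$axial_mm)
  in_lo <- points_in_polygon(lat_g, ax_g,
                             cx + s_in * (boundary$lateral_mm - cx),
                             cy + s_in * (boundary$axial_mm - cy))
  in_hi <- points_in_polygon(lat_g, ax_g,
                             cx + s_out * (boundary$lateral_mm - cx),
                             cy + s_out * (boundary$axial_mm - cy))
  list(inside = matrix(inside, nz, nx),
       annulus = matrix(in_hi & !in_lo, nz, nx))
}

#' Lesion characteristics
#'
#' Depth (boundary centroid axial coordinate), area (shoelace),
#' circularity (`4 * pi * area / perimeter^2`) from the B-mode outline,
#' and the degree of anisotropy (DoA) of each parametric modality across
#' probe rotations: the ratio of the maximum to the minimum (over
#' rotations) of the median in-lesion parameter value.
#'
#' @param boundary the reference-rotation B-mode `visr_polygon`.
#' @param image_sets list of `visr_images`, one per rotation (>= 2 for
#'   DoA; with a single rotation the DoA values are `NA`).
#' @param boundaries optional list of per-rotation boundaries (defaults
#'   to `boundary` for all).
#' @return A list with `depth`, `area`, `circularity`, `doa_pd`,
#'   `doa_re`, `doa_rv`.
#' @export
lesion_characteristics <- function(boundary, image_sets,
                                   boundaries = NULL) {
  pm <- polygon_measures(boundary)
  circ <- 4 * pi * pm$area / pm$perimeter^2
  n_rot <- length(image_sets)
  if (is.null(boundaries)) boundaries <- rep(list(boundary), n_rot)
  doa <- function(field) {
    if (n_rot < 2) return(NA_real_)
    med <- vapply(seq_len(n_rot), function(k) {
      img <- image_sets[[k]]
      masks <- attr(image_sets[[k]], "masks") %||%
        boundary_masks(img$axial_mm, img$lateral_mm, boundaries[[k]])
      stats::median(img[[field]][masks$inside], na.rm = TRUE)
    }, numeric(1))
    max(med) / min(med)
  }
  list(depth = pm$centroid[2], area = pm$area, circularity = circ,
       doa_pd = doa("pd"), doa_re = doa("re"), doa_rv = doa("rv"))
}

#' Measure E/B for one lesion view
#'
#' Runs the automated measurement on one `visr_images` set: largest
#' B-mode diameter from the annotation polygon, endpoint adjustment on
#' each of the PD, RE and RV images, E/B ratios, and CNR-based unsure
#' flags.  The B-mode diameter itself is the annotated largest extent
#' and is not adjusted, so B-mode measured against itself gives E/B = 1
#' exactly.
#'
#' @param images a `visr_images` object.
#' @param boundary the B-mode `visr_polygon` for this view.
#' @param cfg a [measure_config()].
#' @param masks optional precomputed [boundary_masks()] result.
#' @return A data frame with one row per modality (`pd`, `re`, `rv`):
#'   `modality`, `eb`, `bmode_length`, `param_length`, `cnr`, `unsure`,
#'   `low_contrast`.
#' @export
measure_view <- function(images, boundary, cfg = measure_config(),
                         masks = NULL) {
  broi <- largest_diameter(boundary)
  if (is.null(masks)) {
    masks <- boundary_masks(images$axial_mm, images$lateral_mm, boundary)
  }
  rows <- lapply(c("pd", "re", "rv"), function(mod) {
    img <- images[[mod]]
    roi <- adjust_endpoints(broi, img, images$axial_mm, images$lateral_mm,
                            boundary, cfg, modality = mod, masks = masks)
    qf <- quality_flag(img, images$axial_mm, images$lateral_mm, boundary,
                       threshold = cfg$cnr_threshold, masks = masks)
    low <- isTRUE(attr(roi, "low_contrast"))
    data.frame(modality = mod,
               eb = eb_ratio(roi, broi),
               bmode_length = broi$length,
               param_length = roi$length,
               cnr = qf$cnr,
               unsure = qf$unsure || low,
               low_contrast = low)
  })
  do.call(rbind, rows)
}
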