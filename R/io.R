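#' Read and write phantom specifications as structured config
#'
#' Phantom and cohort specifications round-trip through YAML key-value
#' files.
#'
#' @param spec a `visr_phantom_spec` or `visr_cohort_spec`.
#' @param path file path.
#' @return `write_spec_yaml` invisibly returns `path`;
#'   `read_phantom_spec` returns a `visr_phantom_spec`.
#' @export
write_spec_yaml <- function(spec, path) {
  x <- unclass(spec)
  x$.class <- class(spec)[1]
  if (!is.null(x$seq)) x$seq <- unclass(x$seq)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_spec_yaml
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$.class <- NULL
  x$grid_shape <- as.integer(unlist(x$grid_shape))
  x$lesion_center <- as.numeric(unlist(x$lesion_center))
  x$lesion_axes <- as.numeric(unlist(x$lesion_axes))
  do.call(phantom_spec, x)
}

#' Write a boundary polygon as CSV
#'
#' @param polygon a `visr_polygon`.
#' @param path file path; columns are `lateral_mm`, `axial_mm`.
#' @return Invisibly, `path`.
#' @export
write_polygon_csv <- function(polygon, path) {
  utils::write.csv(as.data.frame(polygon)[, c("lateral_mm", "axial_mm")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_polygon_csv
#' @export
read_polygon_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(data.frame(lateral_mm = df$lateral_mm,
                       axial_mm = df$axial_mm),
            class = c("visr_polygon", "data.frame"))
}

#' Write a displacement profile as CSV
#'
#' @param profile a `visr_profile`.
#' @param path file path; columns are `time_s`, `disp_um`.
#' @return Invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  displacement_profile(df$time_s, df$disp_um)
}

#' Export parametric images as TIFF with a text sidecar
#'
#' Each image layer (B-mode, PD, RE, RV) is min-max normalized to [0, 1]
#' and written as one directory of a multi-page 32-bit float TIFF; the
#' normalization constants and grid geometry go to a YAML sidecar so the
#' physical values can be restored.
#'
#' @param images a `visr_images` object.
#' @param path output TIFF path; the sidecar is `paste0(path, ".yaml")`.
#' @return Invisibly, `path`.
#' @export
export_images_tiff <- function(images, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export")
  }
  layers <- c("bmode", "pd", "re", "rv")
  norm <- list()
  pages <- lapply(layers, function(nm) {
    img <- images[[nm]]
    img[!is.finite(img)] <- 0
    lo <- min(img); hi <- max(img)
    norm[[nm]] <<- list(min = lo, max = hi)
    if (hi > lo) (img - lo) / (hi - lo) else img * 0
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  side <- list(layers = layers, normalization = norm,
               axial_spacing_mm = diff(images$axial_mm)[1],
               lateral_spacing_mm = diff(images$lateral_mm)[1],
               rotation_deg = images$rotation, mode = images$mode)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' Render parametric images to a grayscale PNG
#'
#' The four co-registered images are normalized independently and tiled
#' side by side with a shared gray colormap, mirroring how they are
#' displayed for reading.
#'
#' @param images a `visr_images` object.
#' @param path output PNG path.
#' @return Invisibly, `path`.
#' @export
export_images_png <- function(images, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  norm <- function(img) {
    img[!is.finite(img)] <- 0
    lo <- stats::quantile(img, 0.01); hi <- stats::quantile(img, 0.99)
    pmin(pmax((img - lo) / max(hi - lo, 1e-12), 0), 1)
  }
  tiles <- lapply(c("bmode", "pd", "re", "rv"),
                  function(nm) norm(images[[nm]]))
  sep <- matrix(1, nrow(tiles[[1]]), 2)
  canvas <- tiles[[1]]
  for (k in 2:4) canvas <- cbind(canvas, sep, tiles[[k]])
  png::writePNG(canvas, path)
  invisible(path)
}
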