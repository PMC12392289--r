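# E/B feature subsets evaluated by every study, in reporting order.
eb_feature_sets <- function() {
  list(pd = "pd", re = "re", rv = "rv",
       pd_re = c("pd", "re"), pd_rv = c("pd", "rv"),
       re_rv = c("re", "rv"), pd_re_rv = c("pd", "re", "rv"))
}

#' End-to-end study configuration
#'
#' Bundles the cohort, sequence, acoustics, measurement and analysis
#' settings of a seeded in-silico E/B study.  The master seed fixes all
#' downstream seeds by a documented derivation, so a study is fully
#' regenerable from its configuration.
#'
#' @param cohort a [cohort_spec()].
#' @param seq a [tracking_seq()].
#' @param ac an [acoustics_spec()].
#' @param measure a [measure_config()].
#' @param fit_cfg a [visr_fit_config()].
#' @param mode `"ideal"` (analytic displacement profiles) or `"rf"`
#'   (synthesized RF plus speckle tracking).
#' @param correct apply depth and elasticity corrections to RE/RV before
#'   measurement.
#' @param seed master seed.
#' @return An object of class `visr_study_config`.
#' @export
study_config <- function(cohort = cohort_spec(), seq = tracking_seq(),
                         ac = acoustics_spec(), measure = measure_config(),
                         fit_cfg = visr_fit_config(),
                         mode = c("ideal", "rf"), correct = TRUE,
                         seed = 1) {
  mode <- match.arg(mode)
  structure(list(cohort = cohort, seq = seq, ac = ac, measure = measure,
                 fit_cfg = fit_cfg, mode = mode, correct = correct,
                 seed = as.integer(seed)),
            class = "visr_study_config")
}

#' Run a full in-silico E/B study
#'
#' Executes the whole pipeline: samples the cohort, computes parametric
#' images for every lesion view, applies the corrections, measures E/B
#' per modality with unsure flagging, derives lesion characteristics,
#' fits logistic-regression classifiers for the seven E/B feature
#' subsets (PD, RE, RV, and their combinations) with in-sample ROC
#' analysis, and assembles the correlation tables.  Records flagged
#' unsure in any member modality of a feature subset are excluded from
#' that subset's model.  Deterministic for a fixed master seed.
#'
#' @param cfg a [study_config()].
#' @return An object of class `visr_report`: `records` (one row per
#'   lesion-view-modality), `characteristics`, `models` (per feature
#'   set), `model_summary` data frame, `unsure_fractions`,
#'   `correlations_eb`, `correlations_unsure`, `manifest`, `config`.
#' @export
run_study <- function(cfg = study_config()) {
  stopifnot(inherits(cfg, "visr_study_config"))
  cohort <- cfg$cohort
  cohort$seed <- derive_seed(cfg$seed, "cohort")
  lesions <- sample_cohort(cohort)
  cal <- if (cfg$correct) {
    build_calibration(cfg$seq, cfg$ac,
                      calibration_spec(E = cohort$background_E,
                                       mu = cohort$background_mu,
                                       grid_shape = c(cohort$grid_shape[1], 12),
                                       axial_extent_mm = cohort$axial_extent_mm),
                      fit_cfg = cfg$fit_cfg)
  } else NULL
  records <- list()
  chars <- list()
  for (les in lesions) {
    stage_guard <- function(stage, expr) {
      tryCatch(expr, error = function(e) {
        stop("stage '", stage, "' failed for lesion ", les$lesion_id,
             ": ", conditionMessage(e), call. = FALSE)
      })
    }
    image_sets <- list(); boundaries <- list()
    for (j in seq_along(les$phantoms)) {
      ph <- les$phantoms[[j]]
      img <- stage_guard("imaging", compute_images(
        ph, cfg$seq, cfg$ac, mode = cfg$mode,
        seed = derive_seed(cfg$seed, "imaging",
                           les$lesion_id * 101 + j),
        fit_cfg = cfg$fit_cfg))
      if (!is.null(cal)) img <- stage_guard("correction",
                                            apply_corrections(img, cal))
      bnd <- stage_guard("annotation", lesion_boundary(ph))
      masks <- boundary_masks(img$axial_mm, img$lateral_mm, bnd)
      m <- stage_guard("measurement",
                      measure_view(img, bnd, cfg$measure, masks = masks))
      m$lesion_id <- les$lesion_id
      m$rotation_deg <- les$rotations[j]
      m$label <- les$label
      records[[length(records) + 1]] <- m
      attr(img, "masks") <- masks
      image_sets[[j]] <- img
      boundaries[[j]] <- bnd
    }
    ch <- stage_guard("characteristics",
                      lesion_characteristics(boundaries[[1]], image_sets,
                                             boundaries))
    chars[[length(chars) + 1]] <-
      data.frame(lesion_id = les$lesion_id, label = les$label,
                 depth = ch$depth, area = ch$area,
                 circularity = ch$circularity, doa_pd = ch$doa_pd,
                 doa_re = ch$doa_re, doa_rv = ch$doa_rv)
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  characteristics <- do.call(rbind, chars)
  wide <- eb_wide_table(records)
  models <- lapply(eb_feature_sets(), function(feats) {
    tab <- feature_table(wide, feats)
    if (is.null(tab)) return(NULL)
    fit <- fit_logistic(tab[, feats, drop = FALSE], tab$label)
    scores <- predict(fit, tab[, feats, drop = FALSE])
    roc <- roc_analysis(scores, tab$label)
    list(features = feats, fit = fit, roc = roc, n = nrow(tab))
  })
  model_summary <- do.call(rbind, lapply(names(models), function(nm) {
    m <- models[[nm]]
    if (is.null(m)) {
      return(data.frame(feature_set = nm, auc = NA_real_, sens = NA_real_,
                        spec = NA_real_, n = 0L))
    }
    data.frame(feature_set = nm, auc = m$roc$auc,
               sens = m$roc$sensitivity, spec = m$roc$specificity,
               n = m$n)
  }))
  unsure_fractions <- tapply(records$unsure, records$modality, mean)
  report <- structure(
    list(records = records, characteristics = characteristics,
         models = models, model_summary = model_summary,
         unsure_fractions = unsure_fractions,
         correlations_eb = eb_characteristic_correlations(
           records, characteristics),
         correlations_unsure = unsure_characteristic_correlations(
           records, characteristics),
         manifest = data.frame(
           lesion_id = vapply(lesions, `[[`, integer(1), "lesion_id"),
           label = vapply(lesions, `[[`, character(1), "label"),
           margin_width = vapply(lesions, function(l)
             l$params$margin_width, numeric(1)),
           confound = vapply(lesions, function(l)
             l$params$confound, character(1))),
         config = cfg),
    class = "visr_report")
  report
}

# Records in wide (one row per lesion view) layout with per-modality E/B
# and unsure columns.
eb_wide_table <- function(records) {
  key <- interaction(records$lesion_id, records$rotation_deg, drop = TRUE)
  base <- records[records$modality == "pd",
                  c("lesion_id", "rotation_deg", "label")]
  out <- base
  for (mod in c("pd", "re", "rv")) {
    sel <- records$modality == mod
    stopifnot(sum(sel) == nrow(base))
    out[[paste0(mod)]] <- records$eb[sel]
    out[[paste0("unsure_", mod)]] <- records$unsure[sel]
  }
  out
}

# Rows usable for a feature subset: none of the member modalities unsure.
feature_table <- function(wide, feats) {
  keep <- rep(TRUE, nrow(wide))
  for (f in feats) keep <- keep & !wide[[paste0("unsure_", f)]]
  tab <- wide[keep, , drop = FALSE]
  if (length(unique(tab$label)) < 2 || min(table(tab$label)) < 2) {
    return(NULL)
  }
  tab
}

# Pearson correlations between per-lesion mean E/B and lesion
# characteristics, one row per characteristic, one column per modality.
eb_characteristic_correlations <- function(records, characteristics) {
  props <- c("depth", "area", "circularity", "doa_pd", "doa_re", "doa_rv")
  out <- data.frame(property = props)
  for (mod in c("pd", "re", "rv")) {
    sel <- records$modality == mod & !records$unsure
    eb_mean <- tapply(records$eb[sel], records$lesion_id[sel], mean)
    ids <- as.integer(names(eb_mean))
    ch <- characteristics[match(ids, characteristics$lesion_id), ]
    out[[paste0(mod, "_eb")]] <- vapply(props, function(p) {
      v <- ch[[p]]
      ok <- is.finite(v) & is.finite(eb_mean)
      if (sum(ok) < 3 || stats::sd(v[ok]) == 0 ||
          stats::sd(eb_mean[ok]) == 0) return(NA_real_)
      correlate(eb_mean[ok], v[ok], "pearson")$r
    }, numeric(1))
  }
  out
}

# Spearman correlations between per-lesion unsure counts and
# characteristics.
unsure_characteristic_correlations <- function(records, characteristics) {
  props <- c("depth", "area", "circularity", "doa_pd", "doa_re", "doa_rv")
  out <- data.frame(property = props)
  for (mod in c("pd", "re", "rv")) {
    sel <- records$modality == mod
    n_unsure <- tapply(records$unsure[sel], records$lesion_id[sel], sum)
    ids <- as.integer(names(n_unsure))
    ch <- characteristics[match(ids, characteristics$lesion_id), ]
    out[[paste0(mod, "_images")]] <- vapply(props, function(p) {
      v <- ch[[p]]
      ok <- is.finite(v) & is.finite(n_unsure)
      if (sum(ok) < 3 || stats::sd(v[ok]) == 0 ||
          stats::sd(n_unsure[ok]) == 0) return(NA_real_)
      correlate(as.numeric(n_unsure[ok]), v[ok], "spearman")$r
    }, numeric(1))
  }
  out
}

#' Export a study report to files
#'
#' Writes the report tables as CSV with stable column names, plus a
#' grayscale PNG rendering of one example parametric image set when the
#' `png` package is available.
#'
#' @param report a [run_study()] result.
#' @param dir output directory (created if missing).
#' @param example_images optional `visr_images` object to render.
#' @return Invisibly, the vector of files written.
#' @export
export_report <- function(report, dir, example_images = NULL) {
  stopifnot(inherits(report, "visr_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(report$model_summary, "model_summary.csv")
  wr(report$records, "eb_records.csv")
  wr(report$records[report$records$unsure, , drop = FALSE],
     "exclusions.csv")
  wr(report$characteristics, "characteristics.csv")
  wr(report$correlations_eb, "correlations_eb.csv")
  wr(report$correlations_unsure, "correlations_unsure.csv")
  wr(report$manifest, "manifest.csv")
  uf <- data.frame(modality = names(report$unsure_fractions),
                   unsure_fraction = as.numeric(report$unsure_fractions))
  wr(uf, "unsure_fractions.csv")
  if (!is.null(example_images) &&
      requireNamespace("png", quietly = TRUE)) {
    path <- file.path(dir, "example_images.png")
    export_images_png(example_images, path)
    files <- c(files, path)
  }
  invisible(files)
}
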