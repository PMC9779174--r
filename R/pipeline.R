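#' Default run configuration
#'
#' All settings of the end-to-end study, with defaults matching the
#' reference protocol: all 19 indices, 256 Otsu bins, RBF SVM with
#' `gamma = 0.333` and no rejection class, ROI counts 60/60 train, 15/15
#' test, 80/80 validation, the five FVC grade bands, and `alpha = 0.05`
#' for the grade-wise comparisons.
#'
#' @param seed Root seed; all per-scene and per-stage randomness is derived
#'   from it.
#' @param out Optional output directory; when set, [run_full_study()]
#'   writes its CSV artifacts there.
#' @return A list of class `run_config`.
#' @export
default_config <- function(seed = 1L, out = NULL) {
  structure(list(
    seed = as.integer(seed),
    out = out,
    indices = vi_names(),
    otsu_bins = 256L,
    svm = list(gamma = 0.333, cost = 1, max_per_class = 10000L,
               chromatic_features = FALSE),
    roi_counts = list(train = c(60L, 60L), test = c(15L, 15L),
                      validation = c(80L, 80L)),
    validation_fraction = 0.12,
    alpha = 0.05,
    n_per_grade = 6L,
    scene = list(height = 512L, width = 512L, spectral_overlap = 0.15,
                 noise_sd = 2, shadow_fraction = 0,
                 non_desertification_overlap = 0.45),
    group_by = "intended",       # or "reference": grade scenes by V_SUP
    polarity_overrides = list(), # per-index manual vegetation side
    drop_failed_cells = FALSE
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Round-trips [default_config()] (and edited copies) through a structured
#' YAML file; reading an unedited written default changes no behavior.
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  for (role in names(cfg$roi_counts))
    cfg$roi_counts[[role]] <- as.integer(cfg$roi_counts[[role]])
  cfg
}

#' Evaluate every vegetation index on one scene
#'
#' For one scene with a known reference: computes each index map, binarizes
#' it by Otsu's threshold, derives its FVC, and scores the mask on the
#' validation ROIs (OA, kappa) and against the reference FVC (RE).
#'
#' @param image An [rgb_image()].
#' @param rois An [roi_set()] with a validation role.
#' @param v_sup Reference FVC (percent), e.g. from the supervised
#'   classification mask.
#' @param indices Index subset (default all 19).
#' @param otsu_bins Histogram bins for the threshold.
#' @param polarity_overrides Named list of manual `"above"`/`"below"`
#'   polarities per index.
#' @return A data frame with one row per index: threshold diagnostics, FVC,
#'   OA (percent), kappa, signed RE and `abs_re`. Indices whose map is
#'   degenerate (constant) get `NA` metrics.
#' @export
evaluate_indices_on_scene <- function(image, rois, v_sup,
                                      indices = vi_names(),
                                      otsu_bins = 256L,
                                      polarity_overrides = list()) {
  image <- rgb_image(image)
  chrom <- normalize_chromatic(image)
  rows <- lapply(indices, function(nm) {
    map <- compute_index(image, nm, chrom)
    res <- tryCatch({
      mask <- binarize(map, chrom, n_bins = otsu_bins,
                       polarity = polarity_overrides[[nm]])
      th <- attr(mask, "threshold")
      cm <- confusion_from_rois(mask, rois, role = "validation")
      v_vi <- compute_fvc(mask)$fvc
      re <- relative_error(v_sup, v_vi)
      data.frame(index = nm, threshold = th$threshold,
                 between_class_variance = th$between_class_variance,
                 polarity = attr(mask, "polarity"),
                 fvc_vi = v_vi, oa = 100 * overall_accuracy(cm),
                 kappa = kappa_coefficient(cm),
                 re = re[["re"]], abs_re = re[["abs_re"]])
    }, error = function(e) {
      data.frame(index = nm, threshold = NA_real_,
                 between_class_variance = NA_real_,
                 polarity = NA_character_, fvc_vi = NA_real_,
                 oa = NA_real_, kappa = NA_real_,
                 re = NA_real_, abs_re = NA_real_)
    })
    res
  })
  do.call(rbind, rows)
}

#' Run the full study replication on a synthetic panel
#'
#' Generates (or accepts) a balanced five-grade scene panel and runs the
#' complete pipeline on every scene: ROI sampling, SVM reference
#' classification (test-ROI OA/kappa, reference FVC `V_SUP`, reference
#' grade), then each vegetation index through Otsu segmentation, FVC, and
#' the three accuracy metrics. Finishes with the grade-wise ANOVA + Duncan
#' comparison of the indices for OA, kappa and `|RE|`.
#'
#' @param config A [default_config()] style `run_config`.
#' @param panel Optional pre-generated [generate_grade_panel()] result; by
#'   default a panel is generated from the config.
#' @return A list of class `study_result`:
#'   `scene_summary` (per scene: achieved/reference FVC, grades, reference
#'   classifier OA and kappa), `metrics` (per scene x index accuracy rows),
#'   `metric_table` (long form for the grade-wise statistics),
#'   `report` ([replicate_study()] output), `config`, and the panel
#'   `manifest`. With `config$out` set, all tables are written as CSV
#'   together with a run manifest.
#' @export
run_full_study <- function(config = default_config(), panel = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(panel)) {
    base <- scene_spec(height = config$scene$height, width = config$scene$width,
                       spectral_overlap = config$scene$spectral_overlap,
                       noise_sd = config$scene$noise_sd,
                       shadow_fraction = config$scene$shadow_fraction)
    panel <- generate_grade_panel(
      n_per_grade = config$n_per_grade, base_spec = base, seed = config$seed,
      non_desertification_overlap = config$scene$non_desertification_overlap)
  }
  scene_rows <- list()
  metric_rows <- list()
  for (i in seq_along(panel$scenes)) {
    sc <- panel$scenes[[i]]
    rois <- sample_rois(sc, counts = config$roi_counts,
                        validation_fraction = config$validation_fraction,
                        seed = (config$seed * 100003L + i) %% .Machine$integer.max)
    samples <- extract_training_samples(
      sc$image, rois, role = "train",
      chromatic_features = config$svm$chromatic_features)
    clf <- fit_pixel_classifier(samples, gamma = config$svm$gamma,
                                cost = config$svm$cost,
                                max_per_class = config$svm$max_per_class,
                                seed = config$seed + i)
    test_eval <- evaluate_classifier(
      clf, sc$image, rois, chromatic_features = config$svm$chromatic_features)
    ref_mask <- classify_image(clf, sc$image,
                               chromatic_features = config$svm$chromatic_features)
    v_sup <- compute_fvc(ref_mask)$fvc
    ref_grade <- assign_grade(v_sup)
    scene_rows[[i]] <- data.frame(
      image = i, achieved_fvc = sc$achieved_fvc,
      intended_grade = as.character(sc$intended_grade),
      v_sup = v_sup, reference_grade = as.character(ref_grade),
      ref_test_oa = test_eval$oa, ref_test_kappa = test_eval$kappa)
    idx <- evaluate_indices_on_scene(
      sc$image, rois, v_sup, indices = config$indices,
      otsu_bins = config$otsu_bins,
      polarity_overrides = config$polarity_overrides)
    grade_for_stats <- if (config$group_by == "reference")
      as.character(ref_grade) else as.character(sc$intended_grade)
    idx$image <- i
    idx$grade <- grade_for_stats
    metric_rows[[i]] <- idx
  }
  scene_summary <- do.call(rbind, scene_rows)
  metrics <- do.call(rbind, metric_rows)
  mt <- build_metric_table(metrics, drop_failed = config$drop_failed_cells)
  report <- replicate_study(mt, alpha = config$alpha)
  out <- structure(list(scene_summary = scene_summary, metrics = metrics,
                        metric_table = mt, report = report,
                        config = config, manifest = panel$manifest),
                   class = "study_result")
  if (!is.null(config$out)) write_study_result(out, config$out)
  out
}

# long metric table (index, image, grade, metric, value) from the per-scene
# accuracy rows; a failed (NA) cell unbalances the design and is refused
# unless drop_failed excludes the affected image from its grade
build_metric_table <- function(metrics, drop_failed = FALSE) {
  long <- rbind(
    data.frame(index = metrics$index, image = metrics$image,
               grade = metrics$grade, metric = "OA", value = metrics$oa),
    data.frame(index = metrics$index, image = metrics$image,
               grade = metrics$grade, metric = "kappa", value = metrics$kappa),
    data.frame(index = metrics$index, image = metrics$image,
               grade = metrics$grade, metric = "RE", value = metrics$abs_re)
  )
  if (anyNA(long$value)) {
    bad <- unique(long$image[is.na(long$value)])
    if (!drop_failed)
      stop("degenerate metric cells on image(s) ", paste(bad, collapse = ", "),
           "; the design would be unbalanced (set drop_failed_cells = TRUE ",
           "to exclude those images)")
    long <- long[!long$image %in% bad, ]
  }
  long
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d scenes x %d indices\n",
              nrow(x$scene_summary), length(unique(x$metrics$index))))
  invisible(x)
}

#' Write all study tables as CSV
#'
#' @param result A [run_full_study()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_result <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$manifest, file.path(dir, "panel_manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(result$scene_summary, file.path(dir, "scene_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(result$metrics, file.path(dir, "index_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$report$anova, file.path(dir, "anova_tables.csv"),
                   row.names = FALSE)
  utils::write.csv(result$report$duncan, file.path(dir, "duncan_letters.csv"),
                   row.names = FALSE)
  utils::write.csv(result$report$means, file.path(dir, "grade_means.csv"),
                   row.names = FALSE)
  write_config(result$config, file.path(dir, "run_config.yaml"))
  invisible(dir)
}
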