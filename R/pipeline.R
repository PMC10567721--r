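#' Core four-step training pipeline on patch features
#'
#' Runs the weakly supervised pipeline on an extracted feature matrix:
#' (1) patch clustering (K chosen by silhouette over `k_range`, or fixed
#' via `fixed_k`), (2) per-cluster patch classifiers with the all-patch
#' classifier as benchmark, (3) selection of the clusters that beat the
#' benchmark on the validation cohort, (4) a final classifier trained on
#' the selected clusters and patient-level majority voting. Slides are
#' split into training and validation cohorts by stratified sampling at
#' 4:1 unless an explicit `cohort` assignment is supplied.
#'
#' @param X A [feature_matrix()] (one row per patch).
#' @param patch_slide Slide id per patch.
#' @param slide_labels Named vector: category per slide id.
#' @param slide_patient Optional named vector slide id -> patient id
#'   (default: the slide id; one patient has one slide).
#' @param cohort Optional named vector slide id -> "train"/"validation".
#' @param k_range Candidate cluster numbers for [score_k()] (default 2:12).
#' @param fixed_k Skip model selection and use this K (default NULL).
#' @param cluster_subsample Max patches used to fit/score the clustering
#'   (default 20000; the model is then applied to all patches).
#' @param seed Global seed; per-stage seeds are derived by fixed offsets.
#' @param classes Category order (default [glioma_classes()]).
#' @return Object of class `pipeline_bundle`: clustering model (+ quality
#'   table), benchmark / per-cluster / final classifiers, the
#'   `cluster_selection`, cohort assignment, validation predictions for the
#'   clustering-based and all-patch models, and their evaluation reports.
#' @export
train_pipeline_features <- function(X, patch_slide, slide_labels,
                                    slide_patient = NULL, cohort = NULL,
                                    k_range = 2:12, fixed_k = NULL,
                                    cluster_subsample = 20000L, seed = 0L,
                                    classes = glioma_classes()) {
  fm <- if (inherits(X, "feature_matrix")) X else feature_matrix(as.matrix(X))
  Xm <- fm$X
  patch_slide <- as.character(patch_slide)
  slide_ids <- unique(patch_slide)
  if (is.null(slide_patient))
    slide_patient <- stats::setNames(slide_ids, slide_ids)
  y_patch <- as.character(slide_labels[patch_slide])
  if (anyNA(y_patch)) stop_invalid("every slide needs a label for training")

  if (is.null(cohort)) {
    plan <- make_folds(slide_ids, slide_labels[slide_ids], n_folds = 5L,
                       seed = seed + 1L)
    cohort <- stats::setNames(ifelse(plan$fold == 1L, "validation", "train"),
                              plan$patient_id)
  }
  is_tr <- cohort[patch_slide] == "train"
  Xtr <- Xm[is_tr, , drop = FALSE]; ytr <- y_patch[is_tr]
  Xva <- Xm[!is_tr, , drop = FALSE]; yva <- y_patch[!is_tr]

  # (1) patch clustering on (a subsample of) the training patches
  fit_idx <- seq_len(nrow(Xtr))
  if (nrow(Xtr) > cluster_subsample)
    fit_idx <- with_seed(seed + 2L, sample.int(nrow(Xtr), cluster_subsample))
  quality <- NULL
  if (is.null(fixed_k)) {
    quality <- score_k(Xtr[fit_idx, , drop = FALSE], k_range = k_range,
                       seed = seed + 2L)
    K <- choose_k(quality)
    cl_model <- attr(quality, "models")[[as.character(K)]]
  } else {
    K <- as.integer(fixed_k)
    cl_model <- fit_kmeans(Xtr[fit_idx, , drop = FALSE], K, seed = seed + 2L)
  }
  cl_model$quality <- quality
  tr_cl <- assign_clusters(Xtr, cl_model)
  va_cl <- assign_clusters(Xva, cl_model)

  # (2) benchmark + per-cluster classifiers
  benchmark <- train_patch_classifier(Xtr, ytr, classes = classes,
                                      seed = seed + 3L)
  per_cluster <- list()
  for (k in seq_len(K)) {
    in_k <- tr_cl == k
    if (!any(in_k)) next
    clf <- tryCatch(
      train_patch_classifier(Xtr[in_k, , drop = FALSE], ytr[in_k],
                             classes = classes, seed = seed + 3L + k),
      gliopatch_invalid_input = function(e) {
        message("cluster ", k, " not trainable (", conditionMessage(e),
                "); excluded from candidacy")
        NULL
      })
    if (!is.null(clf)) per_cluster[[as.character(k)]] <- clf
  }
  if (!length(per_cluster)) stop("no cluster yielded a trainable classifier")

  # (3) benchmark-relative cluster selection on the validation cohort
  selection <- select_clusters(per_cluster, benchmark, Xva, yva, va_cl)

  # (4) final classifier on the selected clusters; patient-level vote
  in_sel <- tr_cl %in% selection$selected
  final <- train_patch_classifier(Xtr[in_sel, , drop = FALSE], ytr[in_sel],
                                  classes = classes, seed = seed + 4L)
  va_slides <- patch_slide[!is_tr]
  va_patients <- as.character(slide_patient[va_slides])
  pred_clustered <- predict_patients(predict_proba(final, Xva), va_cl,
                                     va_patients, selection)
  pred_allpatch <- predict_patients(predict_proba(benchmark, Xva), va_cl,
                                    va_patients, seq_len(K))
  truth_patient <- patient_truth(va_patients, yva)
  bundle <- structure(list(
    clustering = cl_model, benchmark = benchmark, per_cluster = per_cluster,
    selection = selection, final = final, classes = classes,
    cohort = cohort, seed = as.integer(seed),
    predictions = pred_clustered, predictions_allpatch = pred_allpatch,
    report = patient_report(pred_clustered, truth_patient, classes),
    report_allpatch = patient_report(pred_allpatch, truth_patient, classes)),
    class = "pipeline_bundle")
  bundle
}

patient_truth <- function(patient_per_patch, label_per_patch) {
  stats::setNames(label_per_patch[!duplicated(patient_per_patch)],
                  patient_per_patch[!duplicated(patient_per_patch)])
}

# Patient-level eval report from a prediction table (mean selected-patch
# probabilities as the patient score vector).
patient_report <- function(pred, truth, classes) {
  P <- as.matrix(pred[, paste0("proba_", classes)])
  colnames(P) <- classes
  P <- P / rowSums(P)
  ovr_report(as.character(truth[pred$patient_id]), P)
}

#' Per-class (macro) accuracy of patient predictions
#'
#' Unweighted mean over classes of the within-class accuracy (recall), so
#' rare categories weigh equally with common ones.
#'
#' @param predicted,truth Aligned label vectors.
#' @return Macro-averaged accuracy in `[0, 1]`.
#' @export
macro_accuracy <- function(predicted, truth) {
  mean(vapply(unique(truth), function(cl)
    mean(predicted[truth == cl] == cl), 0))
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("<pipeline_bundle> K =", x$clustering$K,
      "; selected:", paste(x$selection$selected, collapse = ","),
      "; validation accuracy =", signif(x$report$accuracy, 4),
      "(all-patch:", paste0(signif(x$report_allpatch$accuracy, 4), ")"), "\n")
  invisible(x)
}

#' Image-tier training pipeline
#'
#' Segments and tiles each slide, extracts features with `extractor`, and
#' hands over to [train_pipeline_features()].
#'
#' @param slides Named list of labeled [slide_record()]s.
#' @param extractor A [feature_extractor()] (default [baseline_extractor()]).
#' @param patch_size,min_tissue_fraction,downsample Tiling parameters
#'   (see [tile_patches()], [segment_tissue()]).
#' @param ... Passed to [train_pipeline_features()].
#' @return A `pipeline_bundle` (with the patch manifest attached as
#'   `manifest`).
#' @export
train_pipeline_slides <- function(slides, extractor = baseline_extractor(),
                                  patch_size = 1024L,
                                  min_tissue_fraction = 0.5,
                                  downsample = 4L, ...) {
  manifests <- lapply(slides, function(sl) {
    mask <- segment_tissue(sl, downsample = downsample)
    tile_patches(sl, mask, patch_size = patch_size,
                 min_tissue_fraction = min_tissue_fraction)
  })
  manifest <- do.call(rbind, manifests)
  rownames(manifest) <- NULL
  fm <- extract_features(manifest, extractor, slides = slides)
  labels <- vapply(slides, function(s) s$label, "")
  patients <- vapply(slides, function(s) s$patient_id, "")
  bundle <- train_pipeline_features(fm, manifest$slide_id, labels,
                                    slide_patient = patients, ...)
  bundle$manifest <- manifest
  bundle$extractor_descriptor <- fm$extractor_descriptor
  bundle
}

#' Predict patient categories with a trained bundle
#'
#' Assigns each patch to its cluster, scores it with the final classifier,
#' and aggregates to patient level by majority vote over the selected
#' clusters. Unlabeled cohorts are allowed.
#'
#' @param bundle A `pipeline_bundle`.
#' @param X Patch [feature_matrix()] (dimensionality must match the bundle).
#' @param patch_patient Patient id per patch.
#' @return Prediction data frame as in [predict_patients()].
#' @export
predict_pipeline <- function(bundle, X, patch_patient) {
  Xm <- as_feature_X(X)
  if (ncol(Xm) != ncol(bundle$clustering$centroids))
    stop_invalid("feature dimension does not match the trained bundle")
  cl <- assign_clusters(Xm, bundle$clustering)
  predict_patients(predict_proba(bundle$final, Xm), cl,
                   as.character(patch_patient), bundle$selection)
}

#' Evaluate patient predictions against true labels
#'
#' @param predictions Prediction data frame from [predict_pipeline()] /
#'   [predict_patients()].
#' @param truth Named vector patient id -> true category.
#' @param classes Category order.
#' @return An `eval_report` (see [ovr_report()]); unmatched patient ids are
#'   an error listing them.
#' @export
eval_predictions <- function(predictions, truth, classes = glioma_classes()) {
  missing <- setdiff(predictions$patient_id, names(truth))
  if (length(missing))
    stop_invalid("no true label for patient(s): ",
                 paste(missing, collapse = ", "))
  patient_report(predictions, truth, classes)
}

#' Persist / load a pipeline bundle as plain-text files
#'
#' Writes the clustering archive, selection JSON, classifier coefficient
#' CSVs, and a config snapshot into `dir`. [read_bundle()] restores a
#' bundle sufficient for [predict_pipeline()].
#'
#' @param bundle A `pipeline_bundle`.
#' @param dir Output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cluster_model(bundle$clustering, file.path(dir, "clustering"))
  jsonlite::write_json(list(
    benchmark_accuracy = bundle$selection$benchmark_accuracy,
    per_cluster_accuracy = as.list(bundle$selection$per_cluster_accuracy),
    selected = bundle$selection$selected),
    file.path(dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  write_patch_classifier(bundle$benchmark, file.path(dir, "benchmark"))
  write_patch_classifier(bundle$final, file.path(dir, "final"))
  for (k in names(bundle$per_cluster))
    write_patch_classifier(bundle$per_cluster[[k]],
                           file.path(dir, paste0("cluster_", k)))
  jsonlite::write_json(list(classes = bundle$classes, seed = bundle$seed,
                            cohort = as.list(bundle$cohort)),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$predictions))
    utils::write.csv(bundle$predictions, file.path(dir, "predictions.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  sel <- jsonlite::read_json(file.path(dir, "selection.json"),
                             simplifyVector = TRUE)
  clfs <- list()
  for (f in list.files(dir, pattern = "^cluster_[0-9]+\\.json$")) {
    k <- sub("^cluster_([0-9]+)\\.json$", "\\1", f)
    clfs[[k]] <- read_patch_classifier(file.path(dir, paste0("cluster_", k)))
  }
  structure(list(
    clustering = read_cluster_model(file.path(dir, "clustering")),
    benchmark = read_patch_classifier(file.path(dir, "benchmark")),
    per_cluster = clfs,
    selection = structure(list(
      benchmark_accuracy = sel$benchmark_accuracy,
      per_cluster_accuracy = unlist(sel$per_cluster_accuracy),
      selected = as.integer(sel$selected)), class = "cluster_selection"),
    final = read_patch_classifier(file.path(dir, "final")),
    classes = cfg$classes, seed = cfg$seed,
    cohort = unlist(cfg$cohort)), class = "pipeline_bundle")
}

#' Run the synthetic benchmark end to end
#'
#' Generates the feature-tier benchmark dataset from `cfg`, trains the full
#' pipeline (clustering at `fixed_k = cfg$n_patterns` by default, matching
#' the planted pattern count; pass `fixed_k = NULL` to select K by
#' silhouette), and summarizes recovery of the planted structure.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Seed for generation + training.
#' @param fixed_k See [train_pipeline_features()].
#' @param ... Passed to [train_pipeline_features()].
#' @return List: the `bundle`, `informative_clusters` (fitted cluster ids
#'   hosting the informative patterns), `recovered` (TRUE when all
#'   informative clusters were selected), `macro_accuracy` /
#'   `macro_accuracy_allpatch` (validation, patient level), `truth`.
#' @export
run_benchmark <- function(cfg = synthetic_config(), seed = 0L,
                          fixed_k = cfg$n_patterns, ...) {
  ds <- gen_feature_dataset(cfg, seed = seed)
  bundle <- train_pipeline_features(ds$features, ds$truth$patch_slide,
                                    ds$truth$slide_labels, fixed_k = fixed_k,
                                    seed = seed, classes = cfg$classes, ...)
  cl_all <- assign_clusters(ds$features, bundle$clustering)
  informative <- vapply(seq_len(cfg$n_informative), function(p) {
    in_p <- ds$truth$patch_pattern == p
    as.integer(names(which.max(table(cl_all[in_p]))))
  }, 0L)
  truth_pat <- patient_truth(ds$truth$patch_slide, ds$truth$patch_class)
  acc <- macro_accuracy(bundle$predictions$predicted,
                        as.character(truth_pat[bundle$predictions$patient_id]))
  acc_ap <- macro_accuracy(bundle$predictions_allpatch$predicted,
                           as.character(truth_pat[bundle$predictions_allpatch$patient_id]))
  list(bundle = bundle, informative_clusters = sort(unique(informative)),
       recovered = all(informative %in% bundle$selection$selected),
       macro_accuracy = acc, macro_accuracy_allpatch = acc_ap,
       truth = ds$truth)
}

#' Image-tier prediction for a set of slides
#'
#' Segments, tiles and featurizes each slide with the same parameters used
#' at training time, then applies [predict_pipeline()].
#'
#' @param bundle A `pipeline_bundle` (or a bundle directory).
#' @param slides Named list of [slide_record()]s (labels not required).
#' @param extractor Feature extractor (must match the bundle's features).
#' @inheritParams train_pipeline_slides
#' @return Prediction data frame, one row per patient.
#' @export
predict_pipeline_slides <- function(bundle, slides,
                                    extractor = baseline_extractor(),
                                    patch_size = 1024L,
                                    min_tissue_fraction = 0.5,
                                    downsample = 4L) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  manifests <- lapply(slides, function(sl) {
    mask <- segment_tissue(sl, downsample = downsample)
    tile_patches(sl, mask, patch_size = patch_size,
                 min_tissue_fraction = min_tissue_fraction)
  })
  manifest <- do.call(rbind, manifests)
  if (is.null(manifest) || nrow(manifest) == 0)
    return(predict_patients(
      matrix(numeric(0), 0, length(bundle$classes),
             dimnames = list(NULL, bundle$classes)),
      integer(0), character(0), bundle$selection))
  fm <- extract_features(manifest, extractor, slides = slides)
  patients <- vapply(slides, function(s) s$patient_id, "")
  predict_pipeline(bundle, fm, patients[manifest$slide_id])
}

read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop_invalid("config needs an out_dir")
  if (is.null(config$slides_dir) && is.null(config$synthetic))
    stop_invalid("config needs either slides_dir or a synthetic block")
  config
}

load_config_slides <- function(config) {
  if (!is.null(config$slides_dir)) {
    meta_csv <- file.path(config$slides_dir, "slides.csv")
    if (!file.exists(meta_csv))
      stop_invalid("slides_dir must contain slides.csv ",
                   "(columns slide_id, patient_id, label)")
    meta <- utils::read.csv(meta_csv, stringsAsFactors = FALSE)
    if (!"label" %in% names(meta)) meta$label <- NA_character_
    slides <- lapply(seq_len(nrow(meta)), function(i)
      slide_record(meta$slide_id[i], meta$patient_id[i],
                   file.path(config$slides_dir,
                             paste0(meta$slide_id[i], ".png")),
                   label = meta$label[i]))
    stats::setNames(slides, meta$slide_id)
  } else {
    cfg <- do.call(synthetic_config, config$synthetic)
    gen_slide_set(cfg, seed = cfg$seed)$slides
  }
}

#' Train the pipeline from a run configuration
#'
#' The configuration (a YAML file or list) names the input slides — either
#' `slides_dir` (a directory with `slides.csv` and one PNG per slide, as
#' written by the `synth` subcommand) or a `synthetic` block of
#' [synthetic_config()] arguments — plus `out_dir` and optional stage
#' parameters (`patch_size`, `min_tissue_fraction`, `downsample`, `k`,
#' `k_min`/`k_max`, `seed`). The trained bundle and a config snapshot are
#' persisted in `out_dir`; re-running with an unchanged configuration is a
#' no-op that returns the cached bundle.
#'
#' @param config YAML path or list.
#' @return A `pipeline_bundle` (invisibly the same as what `out_dir` holds).
#' @export
run_train <- function(config) {
  config <- read_run_config(config)
  snap_path <- file.path(config$out_dir, "run_config.json")
  snapshot <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  if (file.exists(snap_path) &&
      identical(as.character(snapshot),
                paste(readLines(snap_path, warn = FALSE), collapse = "\n")) &&
      file.exists(file.path(config$out_dir, "final.json"))) {
    message("out_dir is up to date for this configuration; skipping training")
    return(invisible(read_bundle(config$out_dir)))
  }
  slides <- load_config_slides(config)
  k_range <- if (!is.null(config$k_min)) config$k_min:config$k_max else 2:12
  bundle <- train_pipeline_slides(
    slides,
    patch_size = config$patch_size %||% 1024L,
    min_tissue_fraction = config$min_tissue_fraction %||% 0.5,
    downsample = config$downsample %||% 4L,
    fixed_k = config$k, k_range = k_range,
    seed = config$seed %||% 0L)
  write_bundle(bundle, config$out_dir)
  writeLines(as.character(snapshot), snap_path)
  message("trained bundle written to ", config$out_dir,
          " (K = ", bundle$clustering$K, ", selected ",
          length(bundle$selection$selected), " clusters)")
  invisible(bundle)
}

#' Predict a cohort from a run configuration
#'
#' Reads the bundle from `config$out_dir`, predicts every slide named by the
#' configuration, and writes `predictions.csv` next to the bundle (or to
#' `config$predictions_csv`).
#'
#' @inheritParams run_train
#' @return Prediction data frame.
#' @export
run_predict <- function(config) {
  config <- read_run_config(config)
  slides <- load_config_slides(config)
  pred <- predict_pipeline_slides(
    config$out_dir, slides,
    patch_size = config$patch_size %||% 1024L,
    min_tissue_fraction = config$min_tissue_fraction %||% 0.5,
    downsample = config$downsample %||% 4L)
  out_csv <- config$predictions_csv %||%
    file.path(config$out_dir, "cohort_predictions.csv")
  utils::write.csv(pred, out_csv, row.names = FALSE)
  invisible(pred)
}

#' Evaluate predictions from files
#'
#' @param predictions_csv Prediction CSV (from [run_predict()]).
#' @param truth_csv CSV with columns `patient_id`, `label`.
#' @param out_stem Path stem for the metrics JSON and curve CSVs.
#' @return An `eval_report`.
#' @export
run_eval <- function(predictions_csv, truth_csv, out_stem) {
  pred <- utils::read.csv(predictions_csv, stringsAsFactors = FALSE)
  tr <- utils::read.csv(truth_csv, stringsAsFactors = FALSE)
  report <- eval_predictions(pred, stats::setNames(tr$label, tr$patient_id))
  write_eval_report(report, out_stem)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
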