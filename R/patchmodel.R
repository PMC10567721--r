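#' Train a patch-level classifier
#'
#' Reference desk-scale learner satisfying the patch-classifier contract:
#' a seeded multinomial logistic regression (fit via [nnet::multinom()]),
#' whose predictions are computed from the stored coefficient matrix so the
#' model round-trips through a plain-text bundle. Any learner honoring the
#' contract (ordered `classes`, `predict_proba` rows summing to 1,
#' deterministic inference) is admissible — including an iterative deep
#' network scheduled by [early_stop_rule()] — and can be plugged into
#' [select_clusters()] and [predict_patient()] unchanged.
#'
#' @param X Training [feature_matrix()] or numeric matrix.
#' @param y Training labels (character or factor; >= 2 classes required).
#' @param val_X,val_y Optional validation set; accuracy recorded in metadata.
#' @param classes Ordered class set (default [glioma_classes()]; labels
#'   outside it are an error).
#' @param seed RNG seed for the fit (default 0).
#' @param maxit Optimizer iteration cap (default 200).
#' @param decay L2 weight decay passed to the optimizer (default 1e-4,
#'   keeps separable problems finite).
#' @return Object of class `patch_classifier` with fields `classes`,
#'   `coef` (`(D+1) x |classes|`, first class as reference), `descriptor`,
#'   `metadata`.
#' @export
train_patch_classifier <- function(X, y, val_X = NULL, val_y = NULL,
                                   classes = glioma_classes(), seed = 0L,
                                   maxit = 200L, decay = 1e-4) {
  X <- as_feature_X(X)
  y <- as.character(y)
  if (length(y) != nrow(X)) stop_invalid("labels must align with feature rows")
  bad <- setdiff(unique(y), classes)
  if (length(bad)) stop_invalid("unknown class label(s): ", paste(bad, collapse = ", "))
  present <- intersect(classes, unique(y))
  if (length(present) < 2)
    stop_invalid("training set contains a single class (", present, ")")
  yf <- factor(y, levels = present)
  df <- data.frame(.y = yf, X)
  fit <- with_seed(seed, nnet::multinom(
    .y ~ ., data = df, trace = FALSE, maxit = maxit, decay = decay,
    MaxNWts = (ncol(X) + 2) * (length(present) + 1)))
  # coefficient matrix on the full class set; classes absent from training
  # are masked to probability 0 at prediction time
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
  B <- matrix(0, ncol(X) + 1, length(classes),
              dimnames = list(NULL, classes))
  for (i in seq_len(nrow(cf))) B[, present[i + 1]] <- cf[i, ]
  clf <- structure(list(classes = classes, coef = B,
                        descriptor = "multinomial-logistic-v1",
                        metadata = list(seed = as.integer(seed), maxit = maxit,
                                        decay = decay, n_train = nrow(X),
                                        classes_present = present)),
                   class = "patch_classifier")
  if (!is.null(val_X) && !is.null(val_y)) {
    acc <- classifier_accuracy(clf, val_X, val_y)
    clf$metadata$val_accuracy <- acc
  }
  clf
}

#' Predict class probabilities for patches
#'
#' Softmax over the stored linear scores; rows sum to 1 and classes absent
#' from training receive probability 0.
#'
#' @param clf A `patch_classifier`.
#' @param X Feature matrix with the training dimensionality.
#' @return `n x |classes|` probability matrix (columns = `clf$classes`).
#' @export
predict_proba <- function(clf, X) {
  X <- as_feature_X(X)
  if (ncol(X) + 1 != nrow(clf$coef))
    stop_invalid("feature dimension does not match the classifier")
  eta <- cbind(1, X) %*% clf$coef
  absent <- !clf$classes %in% clf$metadata$classes_present
  eta[, absent] <- -Inf
  eta <- eta - apply(eta, 1, max)          # numerical stability
  P <- exp(eta)
  P[, absent] <- 0
  P / rowSums(P)
}

#' Predict the argmax class per patch
#' @inheritParams predict_proba
#' @return Character vector of class labels.
#' @export
predict_class <- function(clf, X) {
  P <- predict_proba(clf, X)
  clf$classes[max.col(P, ties.method = "first")]
}

classifier_accuracy <- function(clf, X, y) {
  mean(predict_class(clf, X) == as.character(y))
}

#' Select clusters that beat the all-patch benchmark
#'
#' Computes each cluster's classification accuracy on its own validation
#' patches (using that cluster's classifier) and the benchmark accuracy of
#' the all-patch classifier on all validation patches; clusters with
#' strictly greater accuracy than the benchmark are selected. If no cluster
#' qualifies the single best cluster is selected with a warning; clusters
#' with no validation patches are excluded from candidacy (message).
#'
#' @param per_cluster Named list of `patch_classifier`s keyed by cluster id.
#' @param benchmark The all-patch benchmark `patch_classifier`.
#' @param val_X Validation features.
#' @param val_y Validation labels.
#' @param val_clusters Integer cluster id per validation patch.
#' @return Object of class `cluster_selection`: `benchmark_accuracy`,
#'   `per_cluster_accuracy` (named numeric), `selected` (integer ids).
#' @export
select_clusters <- function(per_cluster, benchmark, val_X, val_y, val_clusters) {
  val_X <- as_feature_X(val_X)
  val_y <- as.character(val_y)
  ids <- sort(as.integer(names(per_cluster)))
  bench_acc <- classifier_accuracy(benchmark, val_X, val_y)
  acc <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (k in ids) {
    in_k <- val_clusters == k
    if (!any(in_k)) {
      message("cluster ", k, " has no validation patches; excluded from candidacy")
      next
    }
    acc[as.character(k)] <- classifier_accuracy(
      per_cluster[[as.character(k)]],
      val_X[in_k, , drop = FALSE], val_y[in_k])
  }
  selected <- ids[!is.na(acc) & acc > bench_acc]
  if (!length(selected)) {
    selected <- ids[which.max(acc)]
    warning("no cluster beats the benchmark (", signif(bench_acc, 4),
            "); falling back to the single best cluster ", selected)
  }
  structure(list(benchmark_accuracy = bench_acc,
                 per_cluster_accuracy = acc, selected = selected),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat("<cluster_selection> benchmark =", signif(x$benchmark_accuracy, 4),
      "; selected clusters:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate patch predictions into a patient-level category
#'
#' Majority vote: each patch assigned to a selected cluster votes its argmax
#' class, and the modal class is the patient-level prediction. Vote ties are
#' broken by the higher mean predicted probability among the tied classes
#' (over the voting patches), then by class order. If none of the patient's
#' patches falls in a selected cluster, all patches vote (fallback, message).
#'
#' @param P `n x |classes|` patch probability matrix for one patient
#'   (columns named by class).
#' @param clusters Integer cluster id per patch.
#' @param selection A `cluster_selection` (or integer vector of selected
#'   cluster ids).
#' @return Object of class `patient_prediction`: `votes` (named counts over
#'   all classes), `mean_proba`, `predicted`, `n_patches_used`.
#' @export
predict_patient <- function(P, clusters, selection) {
  if (is.null(nrow(P)) || nrow(P) < 1) stop_invalid("patient has zero patches")
  classes <- colnames(P)
  sel <- if (inherits(selection, "cluster_selection")) selection$selected else selection
  use <- clusters %in% sel
  if (!any(use)) {
    message("no patch in a selected cluster; falling back to all patches")
    use <- rep(TRUE, nrow(P))
  }
  Pu <- P[use, , drop = FALSE]
  vote_class <- classes[max.col(Pu, ties.method = "first")]
  votes <- table(factor(vote_class, levels = classes))
  mean_proba <- colMeans(Pu)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1) {
    top <- top[order(-mean_proba[top], match(top, classes))]
  }
  structure(list(votes = as.vector(votes, mode = "integer") |>
                   stats::setNames(classes),
                 mean_proba = mean_proba, predicted = top[1],
                 n_patches_used = sum(use)),
            class = "patient_prediction")
}

#' Patient-level predictions for a cohort
#'
#' Applies [predict_patient()] per patient and returns one row per patient.
#'
#' @param P Patch probability matrix (all patients).
#' @param clusters Cluster id per patch.
#' @param patient_ids Patient id per patch.
#' @param selection A `cluster_selection`.
#' @return Data frame: `patient_id`, `predicted`, `n_patches_used`, one
#'   `votes_<class>` and one `proba_<class>` column per class.
#' @export
predict_patients <- function(P, clusters, patient_ids, selection) {
  classes <- colnames(P)
  if (is.null(nrow(P)) || nrow(P) == 0) {
    warning("no patches to predict; returning an empty prediction table")
    out <- data.frame(patient_id = character(), predicted = character(),
                      n_patches_used = integer(), stringsAsFactors = FALSE)
    for (cl in classes) out[[paste0("votes_", cl)]] <- integer()
    for (cl in classes) out[[paste0("proba_", cl)]] <- numeric()
    return(out)
  }
  ids <- unique(patient_ids)
  rows <- lapply(ids, function(pid) {
    i <- patient_ids == pid
    pp <- predict_patient(P[i, , drop = FALSE], clusters[i], selection)
    out <- data.frame(patient_id = pid, predicted = pp$predicted,
                      n_patches_used = pp$n_patches_used,
                      stringsAsFactors = FALSE)
    for (cl in classes) out[[paste0("votes_", cl)]] <- pp$votes[[cl]]
    for (cl in classes) out[[paste0("proba_", cl)]] <- pp$mean_proba[[cl]]
    out
  })
  do.call(rbind, rows)
}

#' Write / read a patch classifier as CSV (coefficients) + JSON metadata
#' @param clf A `patch_classifier`.
#' @param path Path stem.
#' @export
write_patch_classifier <- function(clf, path) {
  utils::write.csv(as.data.frame(clf$coef), paste0(path, ".csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(classes = clf$classes, descriptor = clf$descriptor,
                            metadata = clf$metadata),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_patch_classifier
#' @export
read_patch_classifier <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  B <- as.matrix(utils::read.csv(paste0(path, ".csv"), check.names = FALSE))
  colnames(B) <- meta$classes
  structure(list(classes = meta$classes, coef = B,
                 descriptor = meta$descriptor, metadata = meta$metadata),
            class = "patch_classifier")
}
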