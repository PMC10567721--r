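# AUC by the rank (Mann-Whitney) statistic; ties count 1/2.
auc_rank <- function(y, s) {
  y <- as.logical(y)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(s, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(y, s) {
  ord <- order(s, decreasing = TRUE)
  y <- as.logical(y)[ord]; s <- s[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- !duplicated(s, fromLast = TRUE)   # one point per distinct threshold
  data.frame(threshold = s[keep],
             tpr = tp[keep] / sum(y), fpr = fp[keep] / sum(!y)) |>
    (\(d) rbind(data.frame(threshold = Inf, tpr = 0, fpr = 0), d))()
}

pr_points <- function(y, s) {
  ord <- order(s, decreasing = TRUE)
  y <- as.logical(y)[ord]; s <- s[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- !duplicated(s, fromLast = TRUE)
  data.frame(threshold = s[keep], recall = tp[keep] / sum(y),
             precision = tp[keep] / (tp[keep] + fp[keep]))
}

#' One-vs-rest evaluation report
#'
#' Computes, for each class against the union of the others: AUC via the
#' rank statistic (ties counted 1/2), and accuracy, sensitivity,
#' specificity and F1 derived from argmax class assignments; plus the
#' macro-average AUC (unweighted mean over classes), the confusion matrix,
#' and ROC and precision-recall curve points per class. A class absent from
#' `y_true` has undefined AUC and is reported as `NA` with a warning (and
#' excluded from the macro average).
#'
#' @param y_true Character/factor labels.
#' @param P `n x C` probability matrix, columns named by class, rows
#'   summing to 1 (tolerance 1e-6).
#' @param classes Class order (default the columns of `P`).
#' @return Object of class `eval_report`: `per_class` data frame,
#'   `macro_auc`, `accuracy`, `confusion`, `roc`, `pr`.
#' @export
ovr_report <- function(y_true, P, classes = colnames(P)) {
  P <- as.matrix(P)
  if (is.null(classes)) stop_invalid("P must have class column names")
  if (any(abs(rowSums(P) - 1) > 1e-6))
    stop_invalid("probability rows must sum to 1")
  y_true <- as.character(y_true)
  pred <- classes[max.col(P, ties.method = "first")]
  conf <- table(factor(y_true, levels = classes),
                factor(pred, levels = classes))
  roc <- list(); pr <- list()
  per <- lapply(classes, function(cl) {
    pos <- y_true == cl
    if (!any(pos)) {
      warning("class ", cl, " absent from y_true; AUC undefined")
      return(data.frame(class = cl, auc = NA_real_, accuracy = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_,
                        f1 = NA_real_, support = 0L))
    }
    s <- P[, cl]
    tp <- sum(pos & pred == cl); fn <- sum(pos & pred != cl)
    fp <- sum(!pos & pred == cl); tn <- sum(!pos & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / (tp + fn)
    roc[[cl]] <<- roc_points(pos, s)
    pr[[cl]] <<- pr_points(pos, s)
    data.frame(class = cl, auc = auc_rank(pos, s),
               accuracy = (tp + tn) / length(pos),
               sensitivity = rec,
               specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
               f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
               support = sum(pos))
  })
  per <- do.call(rbind, per)
  structure(list(per_class = per,
                 macro_auc = mean(per$auc, na.rm = TRUE),
                 accuracy = mean(pred == y_true),
                 confusion = conf, roc = roc, pr = pr),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> accuracy =", signif(x$accuracy, 4),
      " macro AUC =", signif(x$macro_auc, 4), "\n")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

# DeLong structural components: for each positive, the fraction of negatives
# it outranks (ties 1/2); and symmetrically for negatives.
delong_components <- function(y, s) {
  pos <- s[y]; neg <- s[!y]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' DeLong test for two correlated (or independent) AUCs
#'
#' Nonparametric comparison of the areas under two ROC curves measured on
#' the same binary labels, using the structural components of the
#' Mann-Whitney statistic. For paired scores the covariance between the two
#' AUCs is estimated from the per-observation components; `z = (AUC1 -
#' AUC2) / se` is referred to the standard normal (two-sided).
#'
#' @param y Binary labels (logical or 0/1); both classes must be present.
#' @param s1,s2 Score vectors for the two models (equal length to `y` when
#'   `paired = TRUE`).
#' @param paired Scores computed on the same observations (default TRUE).
#' @return List: `auc1`, `auc2`, `z`, `p` (two-sided), `se`.
#'   With zero variance, `p = 1` when the AUCs are equal and `p = 0` (with a
#'   warning) otherwise.
#' @export
delong_test <- function(y, s1, s2, paired = TRUE) {
  y <- as.logical(y)
  if (!any(y) || all(y)) stop_invalid("both classes must be present in y")
  if (paired && (length(s1) != length(y) || length(s2) != length(y)))
    stop_invalid("paired scores must align with y")
  c1 <- delong_components(y, s1)
  m <- sum(y); n <- sum(!y)
  if (paired) {
    c2 <- delong_components(y, s2)
    s10 <- stats::cov(cbind(c1$v10, c2$v10))
    s01 <- stats::cov(cbind(c1$v01, c2$v01))
    S <- s10 / m + s01 / n
    v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  } else {
    c2 <- delong_components(y, s2)
    v <- stats::var(c1$v10) / m + stats::var(c1$v01) / n +
         stats::var(c2$v10) / m + stats::var(c2$v01) / n
  }
  d <- c1$auc - c2$auc
  if (v <= 0) {
    if (d == 0) return(list(auc1 = c1$auc, auc2 = c2$auc, z = 0, p = 1, se = 0))
    warning("zero variance with unequal AUCs; p set to 0")
    return(list(auc1 = c1$auc, auc2 = c2$auc, z = sign(d) * Inf, p = 0, se = 0))
  }
  z <- d / sqrt(v)
  list(auc1 = c1$auc, auc2 = c2$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)), se = sqrt(v))
}

#' Stratified fold plan for cross-validation
#'
#' Partitions patients into `n_folds` folds, stratified by label (and
#' optionally further stratification variables): within each stratum,
#' patients are shuffled and dealt round-robin starting from a rotating
#' fold, so per-fold class counts differ from exact proportionality by at
#' most 1. Each fold's validation share is ~`1/n_folds` (a 4:1
#' train:validation split at the default 5 folds).
#'
#' @param patient_ids Patient identifiers (unique).
#' @param labels Class label per patient.
#' @param strata Optional extra stratification variables (data frame or
#'   vector) combined with the label.
#' @param n_folds Number of folds (default 5).
#' @param seed RNG seed.
#' @return Object of class `fold_plan`: data frame `patient_id`, `label`,
#'   `fold` (1-based), with `seed` and `n_folds` attributes.
#' @export
make_folds <- function(patient_ids, labels, strata = NULL, n_folds = 5L,
                       seed = 0L) {
  patient_ids <- as.character(patient_ids)
  if (anyDuplicated(patient_ids)) stop_invalid("patient_ids must be unique")
  labels <- as.character(labels)
  cnt <- table(labels)
  small <- names(cnt)[cnt < n_folds]
  if (length(small))
    stop_invalid("class(es) with fewer than ", n_folds, " patients: ",
                 paste(small, collapse = ", "))
  key <- if (is.null(strata)) labels else
    paste(labels, do.call(paste, as.data.frame(strata)), sep = "|")
  fold <- integer(length(patient_ids))
  with_seed(seed, {
    offset <- 0L
    for (g in unique(key)) {
      idx <- sample(which(key == g))
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
      offset <- (offset + length(idx)) %% n_folds
    }
  })
  structure(data.frame(patient_id = patient_ids, label = labels, fold = fold,
                       stringsAsFactors = FALSE),
            seed = seed, n_folds = as.integer(n_folds), class = c("fold_plan", "data.frame"))
}

#' Early-stopping / model-selection rule over a validation-loss history
#'
#' Training runs for at least `min_epochs` epochs while the `window`-epoch
#' moving average of the validation loss is tracked; the model kept is the
#' one at the end of the window with the lowest moving average. A minimum is
#' considered confirmed — and training stops — when the best window has not
#' improved for `patience` epochs past `min_epochs`; otherwise training
#' halts at `max_epochs`.
#'
#' @param loss_history Per-epoch validation losses (epoch 1..length).
#' @param min_epochs Minimum epochs before stopping (default 50).
#' @param max_epochs Hard cap (default 150).
#' @param window Moving-average width in epochs (default 10).
#' @param patience Epochs without improvement that confirm the minimum
#'   (default 20).
#' @return List: `stop_epoch` (last epoch trained), `selected_epoch` (end of
#'   the best window; `NA` while the history is shorter than `window`),
#'   `best_window` (`c(start, end)`), `stopped` (TRUE when the rule, not the
#'   history length, ended training).
#' @export
early_stop_rule <- function(loss_history, min_epochs = 50L, max_epochs = 150L,
                            window = 10L, patience = 20L) {
  n <- length(loss_history)
  if (n < window)
    return(list(stop_epoch = n, selected_epoch = NA_integer_,
                best_window = NULL, stopped = FALSE))
  ma <- as.numeric(stats::filter(loss_history, rep(1 / window, window),
                                 sides = 1))            # ma[e] over (e-window+1)..e
  best_end <- window - 1L + which.min(ma[window:n])
  stop_epoch <- n
  stopped <- FALSE
  for (e in window:n) {
    cur_best <- window - 1L + which.min(ma[window:e])
    if (e >= min_epochs && (e - cur_best) >= patience) {
      stop_epoch <- e; best_end <- cur_best; stopped <- TRUE; break
    }
    if (e >= max_epochs) { stop_epoch <- e; best_end <- cur_best; stopped <- TRUE; break }
  }
  if (!stopped) best_end <- window - 1L + which.min(ma[window:n])
  list(stop_epoch = as.integer(stop_epoch),
       selected_epoch = as.integer(best_end),
       best_window = c(as.integer(best_end - window + 1L), as.integer(best_end)),
       stopped = stopped)
}

#' Pick the best cross-validation fold
#'
#' The fold whose validation report has the highest macro-average AUC over
#' the categories; ties go to the lowest fold index.
#'
#' @param reports List of `eval_report`s, one per fold.
#' @return 1-based fold index.
#' @export
select_best_fold <- function(reports) {
  if (!length(reports)) stop_invalid("no fold reports")
  aucs <- vapply(reports, function(r) r$macro_auc, 0)
  which.max(aucs)   # which.max takes the first (lowest index) on ties
}

#' Write an evaluation report to files
#'
#' Metrics to `<path>_metrics.json`, ROC and PR curve points to
#' `<path>_roc.csv` / `<path>_pr.csv` (long format with a `class` column).
#'
#' @param report An `eval_report`.
#' @param path Path stem.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(accuracy = report$accuracy,
                            macro_auc = report$macro_auc,
                            per_class = report$per_class),
                       paste0(path, "_metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  bindc <- function(lst) do.call(rbind, lapply(names(lst), function(cl)
    cbind(class = cl, lst[[cl]])))
  if (length(report$roc))
    utils::write.csv(bindc(report$roc), paste0(path, "_roc.csv"), row.names = FALSE)
  if (length(report$pr))
    utils::write.csv(bindc(report$pr), paste0(path, "_pr.csv"), row.names = FALSE)
  invisible(path)
}
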