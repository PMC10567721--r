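mk_probs <- function(scores, classes = c("A2", "GBM")) {
  P <- cbind(scores, 1 - scores)
  colnames(P) <- classes
  P
}

test_that("one-vs-rest AUC equals brute-force pair counting", {
  # perfectly ranked binary scores
  r <- ovr_report(c("A2", "A2", "GBM", "GBM"),
                  mk_probs(c(0.9, 0.8, 0.2, 0.1)))
  expect_equal(r$per_class$auc[r$per_class$class == "A2"], 1.0)

  # reversed ranking
  r <- ovr_report(c("A2", "GBM"), mk_probs(c(0.3, 0.7)))
  expect_equal(r$per_class$auc[r$per_class$class == "A2"], 0.0)

  # the tied worked example: (0.5 + 1 + 0 + 1) / 4
  y <- c("A2", "A2", "GBM", "GBM")
  s <- c(0.8, 0.3, 0.8, 0.2)
  r <- ovr_report(y, mk_probs(s))
  expect_equal(r$per_class$auc[r$per_class$class == "A2"], 0.625)
  expect_equal(auc_brute(y == "A2", s), 0.625)

  # random scores with heavy ties, n <= 200: oracle equivalence
  set.seed(21)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(y) || all(y)) next
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    r <- ovr_report(ifelse(y, "A2", "GBM"), mk_probs(s))
    expect_equal(r$per_class$auc[r$per_class$class == "A2"], auc_brute(y, s),
                 tolerance = 1e-12)
  }
})

test_that("constant scores give AUC 0.5 and PR precision = prevalence", {
  y <- c(rep("A2", 30), rep("GBM", 70))
  r <- ovr_report(y, mk_probs(rep(0.5, 100)))
  expect_equal(r$per_class$auc, c(0.5, 0.5))
  pr <- r$pr[["A2"]]
  expect_equal(pr$precision[pr$recall == 1], 0.3)   # prevalence at full recall
})

test_that("ovr_report validates rows and reports absent classes as NA", {
  expect_error(ovr_report("A2", matrix(c(0.7, 0.6), 1,
                                       dimnames = list(NULL, c("A2", "GBM")))),
               "sum to 1")
  P <- matrix(1 / 6, 4, 6, dimnames = list(NULL, glioma_classes()))
  w <- capture_warnings(r <- ovr_report(c("A2", "A2", "GBM", "O2"), P))
  expect_length(w, 3)                              # A3, A4, O3 absent
  expect_true(all(grepl("absent", w)))
  expect_true(is.na(r$per_class$auc[r$per_class$class == "A3"]))
  # macro AUC excludes the absent classes
  expect_equal(r$macro_auc, 0.5)
  # confusion-matrix row sums equal the class supports
  expect_equal(as.vector(rowSums(r$confusion)),
               as.vector(table(factor(c("A2", "A2", "GBM", "O2"),
                                      levels = glioma_classes()))))
})

test_that("threshold metrics derive from argmax assignments", {
  classes <- c("A2", "A3", "GBM")
  P <- rbind(c(0.8, 0.1, 0.1),   # A2 correct
             c(0.1, 0.8, 0.1),   # A3 correct
             c(0.5, 0.4, 0.1),   # A3 misread as A2
             c(0.1, 0.1, 0.8))   # GBM correct
  colnames(P) <- classes
  r <- ovr_report(c("A2", "A3", "A3", "GBM"), P)
  expect_equal(r$accuracy, 0.75)
  pc <- r$per_class
  expect_equal(pc$sensitivity[pc$class == "A3"], 0.5)
  expect_equal(pc$specificity[pc$class == "A2"], 2 / 3)
  expect_equal(pc$f1[pc$class == "A3"], 2 * (1 * 0.5) / 1.5)
})

test_that("delong_test matches rank AUCs, is symmetric, and handles ties", {
  set.seed(31)
  y <- rep(c(TRUE, FALSE), each = 50)
  s1 <- rnorm(100) + y * 1.2
  s2 <- rnorm(100) + y * 0.6

  d <- delong_test(y, s1, s2)
  expect_equal(d$auc1, auc_brute(y, s1), tolerance = 1e-12)
  expect_equal(d$auc2, auc_brute(y, s2), tolerance = 1e-12)
  expect_true(d$p >= 0 && d$p <= 1)

  # identical scores: delta 0, p = 1
  d0 <- delong_test(y, s1, s1)
  expect_equal(d0$p, 1)
  expect_equal(d0$z, 0)

  # symmetry: swapping the models negates z, keeps p
  ds <- delong_test(y, s2, s1)
  expect_equal(ds$z, -d$z, tolerance = 1e-12)
  expect_equal(ds$p, d$p, tolerance = 1e-12)

  expect_error(delong_test(rep(TRUE, 5), rnorm(5), rnorm(5)), "both classes")
})

test_that("delong_test agrees with the pROC reference implementation", {
  set.seed(17)
  y <- rep(c(1, 0), each = 40)
  s1 <- rnorm(80) + y
  s2 <- 0.5 * s1 + rnorm(80)
  d <- delong_test(y, s1, s2)
  ref <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE),
                        pROC::roc(y, s2, quiet = TRUE), method = "delong")
  expect_equal(d$p, ref$p.value, tolerance = 1e-8)
  expect_equal(abs(d$z), abs(unname(ref$statistic)), tolerance = 1e-8)
})

test_that("make_folds stratifies patients at the 4:1 ratio", {
  ids <- sprintf("P%02d", 1:60)
  labs <- rep(glioma_classes(), each = 10)
  plan <- make_folds(ids, labs, n_folds = 5, seed = 1)
  expect_equal(as.vector(table(plan$fold)), rep(12L, 5))        # 60 / 5
  per <- table(plan$label, plan$fold)
  expect_true(all(per == 2))                                    # 2 per class/fold

  # same seed -> identical plan; different seed -> different plan
  expect_identical(make_folds(ids, labs, n_folds = 5, seed = 1), plan)
  plan2 <- make_folds(ids, labs, n_folds = 5, seed = 2)
  expect_false(identical(plan2$fold, plan$fold))

  # unbalanced classes: per-fold counts within 1 of proportionality
  labs2 <- rep(glioma_classes(), times = c(23, 7, 11, 19, 8, 32))
  plan3 <- make_folds(sprintf("Q%03d", 1:100), labs2, n_folds = 5, seed = 3)
  per3 <- table(plan3$label, plan3$fold)
  for (cl in rownames(per3))
    expect_lte(max(per3[cl, ]) - min(per3[cl, ]), 1)

  expect_error(make_folds(ids[1:10], c(rep("A2", 8), "O2", "O2")), "O2")
})

test_that("early_stop_rule tracks the 10-epoch moving-average minimum", {
  # monotonically decreasing: runs to the cap, selects the last window
  hist <- seq(2, 0.5, length.out = 150)
  r <- early_stop_rule(hist)
  expect_equal(r$stop_epoch, 150L)
  expect_equal(r$selected_epoch, 150L)
  expect_equal(r$best_window, c(141L, 150L))

  # clear minimum plateau at epochs 60-69 (brute-force moving-average scan)
  set.seed(5)
  hist2 <- c(seq(2, 1, length.out = 59), rep(0.2, 11), seq(1, 1.5, length.out = 80))
  r2 <- early_stop_rule(hist2)
  ma <- sapply(10:length(hist2), function(e) mean(hist2[(e - 9):e]))
  expect_equal(r2$selected_epoch, which.min(ma) + 9L)
  expect_equal(r2$best_window[2], r2$selected_epoch)
  expect_true(r2$stopped)
  expect_lt(r2$stop_epoch, 150)                    # confirmed minimum stops early

  # shorter than the window: no selection yet
  r3 <- early_stop_rule(rep(1, 5))
  expect_true(is.na(r3$selected_epoch))
})

test_that("select_best_fold picks the highest macro AUC, first on ties", {
  mk <- function(a) structure(list(macro_auc = a), class = "eval_report")
  expect_equal(select_best_fold(lapply(c(0.91, 0.95, 0.93, 0.90, 0.94), mk)), 2L)
  expect_equal(select_best_fold(lapply(c(0.9, 0.9, 0.9), mk)), 1L)
  expect_equal(select_best_fold(list(mk(0.5))), 1L)
})
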