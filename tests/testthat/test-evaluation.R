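test_that("confusion metrics match hand-computed rates and edge cases", {
  # TP=3 FN=1 TN=2 FP=2 -> Acc 62.5, Sn 75, Sp 50
  actual <- c(rep("fatigue", 4), rep("normal", 4))
  pred <- c("fatigue", "fatigue", "fatigue", "normal",
            "fatigue", "fatigue", "normal", "normal")
  m <- confusion_metrics(pred, actual)
  expect_equal(c(m$acc, m$sn, m$sp), c(62.5, 75, 50))
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(3, 1, 2, 2))

  all_right <- confusion_metrics(actual, actual)
  expect_equal(c(all_right$acc, all_right$sn, all_right$sp), c(100, 100, 100))

  all_pos <- confusion_metrics(rep("fatigue", 8), actual)
  expect_equal(c(all_pos$sn, all_pos$sp), c(100, 0))
  expect_error(confusion_metrics(character(0), character(0)), "empty")

  # flipping the positive class exchanges Sn and Sp
  m2 <- confusion_metrics(pred, actual, positive = "normal")
  expect_equal(m2$sn, m$sp)
  expect_equal(m2$sp, m$sn)
})

test_that("ROC/PR areas agree with threshold enumeration and rank statistic", {
  labs <- c("fatigue", "normal", "fatigue", "normal")
  cv <- roc_pr_curves(c(0.9, 0.8, 0.3, 0.2), labs)
  expect_equal(cv$auc_roc, roc_auc_oracle(c(0.9, 0.8, 0.3, 0.2), labs,
                                          "fatigue"), tolerance = 1e-12)

  withr::with_seed(31, {
    for (i in 1:100) {
      n <- sample(10:60, 1)
      labels <- sample(c("normal", "fatigue"), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      scores <- round(rnorm(n), sample(0:2, 1))   # induce ties
      auc <- roc_pr_curves(scores, labels)$auc_roc
      expect_equal(auc, roc_auc_rank(scores, labels, "fatigue"),
                   tolerance = 1e-10)
      expect_equal(auc, roc_auc_oracle(scores, labels, "fatigue"),
                   tolerance = 1e-10)
    }
  })

  # cross-check against an established ROC implementation
  withr::with_seed(19, {
    labels <- sample(c("normal", "fatigue"), 80, replace = TRUE)
    scores <- rnorm(80) + (labels == "fatigue") * 0.8
  })
  expect_equal(roc_pr_curves(scores, labels)$auc_roc,
               as.numeric(pROC::auc(pROC::roc(
                 labels, scores, levels = c("normal", "fatigue"),
                 direction = "<", quiet = TRUE))),
               tolerance = 1e-10)

  perfect <- roc_pr_curves(c(5, 4, 1, 0), c("fatigue", "fatigue",
                                            "normal", "normal"))
  expect_equal(perfect$auc_roc, 1)
  expect_equal(perfect$auc_pr, 1)
  expect_error(roc_pr_curves(1:3, rep("normal", 3)), "both classes")
})

test_that("random scores give chance-level ROC area", {
  withr::with_seed(13, {
    aucs <- replicate(25, {
      labels <- rep(c("normal", "fatigue"), each = 250)
      roc_pr_curves(rnorm(500), labels)$auc_roc
    })
  })
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("stratified split halves every subject-state stratum reproducibly", {
  fm <- toy_features(n_per_class = 40, subjects = rep(c("a", "b"), 40))
  sp <- split_train_test(fm, seed = 3)
  expect_identical(nrow(sp$train), 40L)
  expect_identical(nrow(sp$test), 40L)
  tab <- table(sp$test$subject_id, sp$test$state)
  expect_true(all(tab == 10))
  sp2 <- split_train_test(fm, seed = 3)
  expect_identical(sp$test$epoch, sp2$test$epoch)
  sp3 <- split_train_test(fm, seed = 4)
  expect_false(identical(sp$test$epoch, sp3$test$epoch))
})

test_that("LOO on separable clouds is perfect and produces one prediction per unit", {
  fm <- toy_features(n_per_class = 20, sep = 4)
  rep_knn <- loo_cross_validate(fm, classifier_spec("nearest_neighbor"))
  expect_equal(rep_knn$metrics$acc, 100)
  expect_identical(nrow(rep_knn$predictions), 40L)
  expect_true(all(!is.na(rep_knn$predictions$predicted)))
  # pooled confusion counts sum to the unit count
  m <- rep_knn$metrics
  expect_identical(as.integer(m$tp + m$fp + m$tn + m$fn), 40L)

  # broom-style accessors
  expect_true(all(c("metric", "value") %in% names(tidy(rep_knn))))
  expect_identical(glance(rep_knn)$classifier, "nearest_neighbor")
})

test_that("all four classifiers learn a separable problem under LOO", {
  fm <- toy_features(n_per_class = 15, sep = 4)
  for (kind in c("rbf_svm", "feedforward_net", "random_forest",
                 "nearest_neighbor")) {
    clf <- classifier_spec(kind, n_restarts = 2)
    r <- loo_cross_validate(fm, clf)
    expect_gt(r$metrics$acc, 90)
  }
})

test_that("label-independent features give chance-level LOO accuracy", {
  withr::with_seed(17, {
    accs <- sapply(1:5, function(s) {
      fm <- toy_features(n_per_class = 50, n_feat = 4, sep = 0, seed = s)
      loo_cross_validate(fm, classifier_spec("nearest_neighbor"))$metrics$acc
    })
  })
  expect_gt(mean(accs), 40)
  expect_lt(mean(accs), 60)
})

test_that("subject-level LOO holds out whole subjects", {
  fm <- toy_features(n_per_class = 24, sep = 4,
                     subjects = rep(c("a", "b", "c"), 16))
  r <- loo_cross_validate(fm, classifier_spec("nearest_neighbor"),
                          unit = "subject")
  expect_identical(r$cv$n_units, 3L)
  expect_identical(nrow(r$predictions), 48L)
  expect_gt(r$metrics$acc, 90)
})

test_that("LOO reports are deterministic under a fixed seed", {
  fm <- toy_features(n_per_class = 10, sep = 1, seed = 6)
  clf <- classifier_spec("random_forest", n_trees = 50, seed = 99,
                         n_restarts = 2)
  r1 <- loo_cross_validate(fm, clf)
  r2 <- loo_cross_validate(fm, clf)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("grid search returns the lattice maximum with smallest-c tie-break", {
  fm <- toy_features(n_per_class = 12, sep = 4)
  gs <- grid_search_svm(fm, c_exp = c(-1, 3), g_exp = c(-5, -1))
  expect_identical(nrow(gs$surface), 4L)
  expect_true(all(gs$surface$acc >= 0 & gs$surface$acc <= 100))
  expect_equal(gs$best_acc, max(gs$surface$acc))
  best_rows <- gs$surface[gs$surface$acc == gs$best_acc, ]
  expect_identical(gs$best_c_exp, min(best_rows$c_exp))
  gs2 <- grid_search_svm(fm, c_exp = c(-1, 3), g_exp = c(-5, -1))
  expect_identical(gs[c("best_cost", "best_gamma")],
                   gs2[c("best_cost", "best_gamma")])
})

test_that("AR-order selection distinguishes AR(2)-generated classes", {
  withr::with_seed(23, {
    mk_state <- function(phi, state, n_ep) {
      sig <- t(replicate(2, as.numeric(
        stats::arima.sim(list(ar = phi), n_ep * 100))))
      rownames(sig) <- c("C3", "C4")
      segment_epochs(eeg_recording(sig, 100, c("C3", "C4"), "s1", state), 1)
    }
    ep <- dplyr::bind_rows(mk_state(c(0.4, 0.4), "normal", 30),
                           mk_state(c(0.4, -0.4), "fatigue", 30))
  })
  clf <- classifier_spec("nearest_neighbor")
  sel <- select_ar_order(ep, orders = c(1, 2, 4), clf = clf)
  expect_identical(nrow(sel$accuracy), 3L)
  acc1 <- sel$accuracy$acc[sel$accuracy$order == 1]
  acc2 <- sel$accuracy$acc[sel$accuracy$order == 2]
  expect_gt(acc2, acc1)
  expect_gte(sel$best_order, 2)
  single <- select_ar_order(ep, orders = 3, clf = clf)
  expect_identical(single$best_order, 3L)
})

test_that("entropy combination study covers all 15 subsets consistently", {
  ep <- small_epochs(dur = 8, channels = c("T6", "Cz"), effect = 0.9)
  clf <- classifier_spec("nearest_neighbor")
  comb <- entropy_combination_study(ep, clf)
  expect_identical(nrow(comb), 15L)
  expect_identical(sum(comb$n_measures == 1), 4L)

  # a singleton entry equals a direct single-measure evaluation
  fm_fe <- extract_feature_matrix(ep, measures = "FE")
  direct <- loo_cross_validate(fm_fe, clf)$metrics$acc
  expect_equal(comb$acc[comb$subset == "FE"], direct)

  # full fusion does not fall far behind the best single measure
  best_single <- max(comb$acc[comb$n_measures == 1])
  expect_gte(comb$acc[comb$subset == "PE+AE+SE+FE"], best_single - 10)
})
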