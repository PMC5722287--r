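#' Stratified 50/50 train/test split
#'
#' Randomly and equally divides epochs into training and testing halves,
#' stratified by subject and state so both halves carry the same class and
#' subject balance (an odd stratum gives its extra row to the training half).
#'
#' @param features Feature tibble from [extract_feature_matrix()].
#' @param holdout_fraction Fraction assigned to the test half (default 0.5).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(features, holdout_fraction = 0.5, seed = 1L) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1)
  states <- unique(features$state)
  if (length(states) < 2) stop("both states must be present", call. = FALSE)
  idx_test <- local_seed(seed, {
    unlist(lapply(
      split(seq_len(nrow(features)),
            interaction(features$subject_id, features$state, drop = TRUE)),
      function(rows) {
        n_test <- floor(length(rows) * holdout_fraction)
        if (n_test == 0) integer(0) else sample(rows, n_test)
      }))
  })
  list(train = features[-idx_test, , drop = FALSE],
       test = features[sort(idx_test), , drop = FALSE])
}

#' Accuracy, sensitivity and specificity from labels
#'
#' Pools predictions against truth into a confusion matrix with fatigue as
#' the positive class and reports `Acc = (TP+TN)/total`, `Sn = TP/(TP+FN)`,
#' `Sp = TN/(TN+FP)` as percentages.
#'
#' @param predicted,actual Label vectors of equal length (values `"normal"` /
#'   `"fatigue"`); `NA` predictions are counted as errors.
#' @param positive Positive-class label (default `"fatigue"`).
#' @return One-row tibble with `acc`, `sn`, `sp` (percent) and counts `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
#' @examples
#' confusion_metrics(c("fatigue", "normal"), c("fatigue", "fatigue"))
confusion_metrics <- function(predicted, actual, positive = "fatigue") {
  if (length(predicted) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(predicted) == length(actual))
  actual_pos <- as.character(actual) == positive
  pred <- as.character(predicted)
  # an NA prediction can never match truth: count it on the error diagonal
  correct <- !is.na(pred) & pred == as.character(actual)
  tp <- sum(actual_pos & correct)
  fn <- sum(actual_pos & !correct)
  tn <- sum(!actual_pos & correct)
  fp <- sum(!actual_pos & !correct)
  tibble::tibble(
    acc = 100 * (tp + tn) / length(pred),
    sn = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' ROC and precision-recall curves with trapezoidal areas
#'
#' Sweeps a decision threshold over the unique score values (ties grouped at
#' one threshold), classifying a case as positive when its score is at least
#' the threshold. The ROC curve plots true-positive rate against
#' false-positive rate from (0,0) to (1,1); the PR curve plots precision
#' against recall. Both areas are trapezoidal.
#'
#' @param scores Numeric scores, higher meaning more positive-like.
#' @param actual Label vector.
#' @param positive Positive-class label (default `"fatigue"`).
#' @return List of class `eval_curves`: tibbles `roc` and `pr` plus scalars
#'   `auc_roc` and `auc_pr`.
#' @export
#' @examples
#' cv <- roc_pr_curves(c(.9, .8, .3, .2),
#'                     c("fatigue", "normal", "fatigue", "normal"))
#' cv$auc_roc
roc_pr_curves <- function(scores, actual, positive = "fatigue") {
  stopifnot(length(scores) == length(actual), all(is.finite(scores)))
  pos <- as.character(actual) == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  pos_o <- pos[ord]
  s_o <- scores[ord]
  # group tied scores: cumulative counts evaluated at the last index of a tie
  last_of_tie <- which(!duplicated(s_o, fromLast = TRUE))
  tp <- cumsum(pos_o)[last_of_tie]
  fp <- cumsum(!pos_o)[last_of_tie]
  roc <- tibble::tibble(
    threshold = c(Inf, s_o[last_of_tie]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  prec <- tp / (tp + fp)
  pr <- tibble::tibble(
    threshold = c(Inf, s_o[last_of_tie]),
    recall = c(0, tp / n_pos),
    precision = c(prec[1], prec)
  )
  trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  structure(list(roc = roc, pr = pr,
                 auc_roc = trapezoid(roc$fpr, roc$tpr),
                 auc_pr = trapezoid(pr$recall, pr$precision)),
            class = "eval_curves")
}

#' @export
print.eval_curves <- function(x, ...) {
  cat(sprintf("<eval_curves> ROC area %.4f, PR area %.4f (%d thresholds)\n",
              x$auc_roc, x$auc_pr, nrow(x$roc) - 1))
  invisible(x)
}

loo_units <- function(features, unit) {
  if (unit == "epoch") as.list(seq_len(nrow(features)))
  else split(seq_len(nrow(features)), features$subject_id)
}

# Min-max normalise train/test row blocks of a plain feature matrix using
# statistics fitted on the training rows only (optionally per subject).
# Matrix analogue of fit_normalization() + minmax_normalize(), used on the
# cross-validation hot path.
norm_fold_matrix <- function(X, train_idx, test_idx, subj, per_subject,
                             new_min = -1, new_max = 1) {
  scale_block <- function(rows_fit, rows_apply) {
    x_min <- apply(X[rows_fit, , drop = FALSE], 2, min)
    x_max <- apply(X[rows_fit, , drop = FALSE], 2, max)
    rng <- x_max - x_min
    degen <- rng == 0
    rng[degen] <- 1
    out <- sweep(X[rows_apply, , drop = FALSE], 2, x_min)
    out <- sweep(out, 2, rng, "/") * (new_max - new_min) + new_min
    if (any(degen)) out[, degen] <- (new_min + new_max) / 2
    out
  }
  if (!per_subject) {
    list(train = scale_block(train_idx, train_idx),
         test = scale_block(train_idx, test_idx))
  } else {
    Xtr <- X[train_idx, , drop = FALSE]
    Xte <- X[test_idx, , drop = FALSE]
    for (sid in unique(subj[c(train_idx, test_idx)])) {
      fit_rows <- train_idx[subj[train_idx] == sid]
      if (!length(fit_rows)) {
        stop("no training rows for subject ", sid,
             "; use per_subject = FALSE", call. = FALSE)
      }
      tr_sel <- which(subj[train_idx] == sid)
      te_sel <- which(subj[test_idx] == sid)
      if (length(tr_sel)) Xtr[tr_sel, ] <- scale_block(fit_rows,
                                                       train_idx[tr_sel])
      if (length(te_sel)) Xte[te_sel, ] <- scale_block(fit_rows,
                                                       test_idx[te_sel])
    }
    list(train = Xtr, test = Xte)
  }
}

# Shared cross-validation engine: hold each fold out, refit (optionally with
# per-fold normalisation), pool predictions and scores. `folds` is a list of
# test-row index vectors. Returns character predictions, scores, and the
# skipped-fold count.
cv_predict <- function(features, clf, folds, normalize = TRUE,
                       per_subject = TRUE, n_restarts = 1L) {
  fcols <- feature_cols(features)
  X <- as.matrix(features[fcols])
  subj <- features$subject_id
  y <- features$state
  n_rows <- nrow(X)
  pred_mat <- matrix(NA_character_, n_rows, n_restarts)
  score_mat <- matrix(NA_real_, n_rows, n_restarts)
  n_skipped <- 0L
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(n_rows), test_idx)
    if (length(unique(y[train_idx])) < 2) {
      warning("training fold ", f, " lost a class; counted as error")
      n_skipped <- n_skipped + 1L
      next
    }
    if (normalize) {
      nf <- norm_fold_matrix(X, train_idx, test_idx, subj, per_subject)
      Xtr <- nf$train
      Xte <- nf$test
    } else {
      Xtr <- X[train_idx, , drop = FALSE]
      Xte <- X[test_idx, , drop = FALSE]
    }
    for (rs in seq_len(n_restarts)) {
      out <- fit_predict(clf, Xtr, y[train_idx], Xte,
                         seed = derive_seed(clf$seed, f, rs))
      pred_mat[test_idx, rs] <- as.character(out$label)
      score_mat[test_idx, rs] <- out$score
    }
  }
  list(pred_mat = pred_mat, score_mat = score_mat, n_skipped = n_skipped)
}

# Stratified fold assignment: k folds balanced within each state.
stratified_folds <- function(state, k, seed) {
  assign <- integer(length(state))
  local_seed(seed, {
    for (st in unique(state)) {
      rows <- which(state == st)
      assign[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
  })
  split(seq_along(state), assign)
}

#' Leave-one-out cross-validation of a classifier
#'
#' Holds each unit (epoch or whole subject) out once, refits the classifier
#' on the remainder and pools all held-out predictions into a single
#' confusion matrix. When `normalize = TRUE` (the default) the min-max
#' normalisation is refitted on each fold's training rows only and applied
#' to the held-out rows, so no information leaks from the held-out unit. A
#' training fold that has lost one of the two classes is skipped with a
#' warning and its predictions are counted as errors.
#'
#' Stochastic classifiers are run `clf$n_restarts` times with derived seeds;
#' the pooled prediction of a unit is the majority vote across restarts and
#' its score is the restart mean.
#'
#' @param features Feature tibble (raw, unnormalised, unless
#'   `normalize = FALSE`).
#' @param clf A [classifier_spec()].
#' @param unit `"epoch"` (default) or `"subject"`.
#' @param normalize Refit per-fold min-max normalisation (default `TRUE`).
#' @param per_subject Passed to [fit_normalization()]; per-subject statistics
#'   require every subject to appear in each training fold, so it is forced
#'   off for subject-level LOO.
#' @param positive Positive-class label.
#' @return An object of class `eval_report`; see [tidy()] / [glance()] /
#'   [autoplot()] methods.
#' @export
loo_cross_validate <- function(features, clf = classifier_spec(),
                               unit = c("epoch", "subject"),
                               normalize = TRUE, per_subject = TRUE,
                               positive = "fatigue") {
  unit <- match.arg(unit)
  stopifnot(inherits(clf, "classifier_spec"))
  if (length(unique(features$state)) < 2) {
    stop("both states must be present", call. = FALSE)
  }
  if (unit == "subject") per_subject <- FALSE
  folds <- loo_units(features, unit)
  if (length(folds) < 2) stop("need at least 2 units", call. = FALSE)
  fcols <- feature_cols(features)
  cvp <- cv_predict(features, clf, folds, normalize = normalize,
                    per_subject = per_subject, n_restarts = clf$n_restarts)
  pred_mat <- cvp$pred_mat
  score_mat <- cvp$score_mat
  n_skipped <- cvp$n_skipped

  majority <- apply(pred_mat, 1, function(p) {
    p <- p[!is.na(p)]
    if (!length(p)) return(NA_character_)
    names(sort(table(factor(p, state_levels)), decreasing = TRUE))[1]
  })
  score <- rowMeans(score_mat)
  metrics <- confusion_metrics(majority, features$state, positive = positive)
  curves <- if (all(is.finite(score))) {
    roc_pr_curves(score, features$state, positive = positive)
  } else NULL
  predictions <- tibble::tibble(
    subject_id = features$subject_id, epoch = features$epoch,
    actual = features$state, predicted = majority, score = score)

  structure(list(
    metrics = dplyr::bind_cols(
      metrics,
      tibble::tibble(auc_roc = if (is.null(curves)) NA_real_ else curves$auc_roc,
                     auc_pr = if (is.null(curves)) NA_real_ else curves$auc_pr)),
    predictions = predictions,
    curves = curves,
    classifier = clf,
    cv = list(scheme = "leave_one_out", unit = unit, n_units = length(folds),
              n_skipped_folds = n_skipped),
    provenance = list(n_features = length(fcols), normalize = normalize,
                      per_subject = per_subject, positive = positive,
                      seed = clf$seed)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<eval_report> %s, %s LOO over %d units\n",
              x$classifier$kind, x$cv$unit, x$cv$n_units))
  cat(sprintf("  Acc %.1f%%  Sn %.1f%%  Sp %.1f%%  (ROC area %.3f, PR area %.3f)\n",
              m$acc, m$sn, m$sp, m$auc_roc, m$auc_pr))
  invisible(x)
}

#' @describeIn loo_cross_validate Long tibble of metric/value pairs.
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @describeIn loo_cross_validate One-row tibble of the headline metrics.
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(classifier = x$classifier$kind, cv_unit = x$cv$unit,
                   n_units = x$cv$n_units),
    x$metrics)
}

#' Grid search of the RBF-SVM penalty and kernel width
#'
#' Evaluates cross-validated accuracy over a `log2` lattice of
#' `cost = 2^c_exp` by `gamma = 2^g_exp` and returns the maximising pair,
#' breaking ties towards the smallest cost and then the smallest gamma. The
#' default lattice is the conventional coarse grid (cost exponents -5..15,
#' gamma exponents -15..3, step 2) and the default protocol is leave-one-out;
#' a stratified k-fold fallback (`cv = "kfold"`) is offered for large epoch
#' counts. Per-fold normalisation refitting applies throughout.
#'
#' @param features Feature tibble.
#' @param c_exp,g_exp Integer exponent vectors of the lattice.
#' @param cv `"loo"` (default) or `"kfold"`.
#' @param k Fold count for `cv = "kfold"`.
#' @param seed Seed of the k-fold assignment.
#' @param normalize,per_subject Passed to the fold engine (see
#'   [loo_cross_validate()]).
#' @return List with `best_cost`, `best_gamma`, their exponents, `best_acc`,
#'   and the full `surface` tibble (`c_exp`, `g_exp`, `acc`).
#' @export
grid_search_svm <- function(features, c_exp = seq(-5, 15, 2),
                            g_exp = seq(-15, 3, 2), cv = c("loo", "kfold"),
                            k = 5, seed = 1L, normalize = TRUE,
                            per_subject = TRUE) {
  stopifnot(length(c_exp) > 0, length(g_exp) > 0)
  cv <- match.arg(cv)
  folds <- if (cv == "loo") as.list(seq_len(nrow(features)))
           else stratified_folds(features$state, k, seed)
  surface <- tidyr::expand_grid(c_exp = sort(c_exp), g_exp = sort(g_exp))
  surface$acc <- purrr::pmap_dbl(surface, function(c_exp, g_exp) {
    clf <- classifier_spec("rbf_svm", cost = 2^c_exp, gamma = 2^g_exp)
    cvp <- cv_predict(features, clf, folds, normalize = normalize,
                      per_subject = per_subject)
    confusion_metrics(cvp$pred_mat[, 1], features$state)$acc
  })
  best <- surface[which.max(surface$acc), ]  # which.max is first = smallest c,g
  list(best_cost = 2^best$c_exp, best_gamma = 2^best$g_exp,
       best_c_exp = best$c_exp, best_g_exp = best$g_exp,
       best_acc = best$acc, surface = surface)
}

#' Select the AR model order by cross-validated accuracy
#'
#' Extracts Yule-Walker AR features at each candidate order and evaluates
#' leave-one-out accuracy; returns the order maximising accuracy, breaking
#' ties towards the smallest order.
#'
#' @param epochs Epoch tibble from [segment_epochs()].
#' @param orders Candidate model orders.
#' @param clf A [classifier_spec()].
#' @param ... Passed to [loo_cross_validate()].
#' @return List with `best_order` and an `accuracy` tibble (order, acc).
#' @export
select_ar_order <- function(epochs, orders = c(2, 4, 6, 8, 10, 12),
                            clf = classifier_spec(), ...) {
  stopifnot(length(orders) >= 1)
  orders <- sort(unique(as.integer(orders)))
  acc <- vapply(orders, function(p) {
    fm <- extract_feature_matrix(epochs, mode = "ar", ar_order = p)
    loo_cross_validate(fm, clf, ...)$metrics$acc
  }, numeric(1))
  tab <- tibble::tibble(order = orders, acc = acc)
  list(best_order = orders[which.max(acc)], accuracy = tab)
}

measure_subsets <- function() {
  ms <- entropy_measures
  subs <- unlist(lapply(seq_along(ms), function(k) {
    apply(utils::combn(ms, k), 2, list)
  }), recursive = FALSE)
  lapply(subs, unlist)
}

#' Accuracy of every entropy-measure combination
#'
#' Evaluates all 15 non-empty subsets of `{PE, AE, SE, FE}`: the full
#' four-entropy feature table is computed once, each subset restricts to its
#' measures' columns, and leave-one-out accuracy is computed per subject and
#' averaged across subjects (each subject is evaluated on its own epochs, as
#' in a per-participant protocol).
#'
#' @param epochs Epoch tibble.
#' @param clf A [classifier_spec()].
#' @param params An [entropy_params()] set.
#' @param ... Passed to [loo_cross_validate()].
#' @return Tibble with `subset` (e.g. `"PE+FE"`), `n_measures` and mean
#'   `acc`; the per-subject accuracies are attached as attribute
#'   `"per_subject"`.
#' @export
entropy_combination_study <- function(epochs, clf = classifier_spec(),
                                      params = entropy_params(), ...) {
  full <- extract_feature_matrix(epochs, measures = entropy_measures,
                                 params = params)
  subjects <- unique(full$subject_id)
  subsets <- measure_subsets()
  per_subject <- purrr::map_dfr(subsets, function(ms) {
    suffix <- paste0("_(", paste(ms, collapse = "|"), ")$")
    keep <- c(meta_cols(), grep(suffix, names(full), value = TRUE))
    purrr::map_dfr(subjects, function(sid) {
      fm <- full[full$subject_id == sid, keep]
      rep <- loo_cross_validate(fm, clf, ...)
      tibble::tibble(subset = paste(ms, collapse = "+"),
                     n_measures = length(ms), subject_id = sid,
                     acc = rep$metrics$acc)
    })
  })
  out <- per_subject |>
    dplyr::group_by(.data$subset, .data$n_measures) |>
    dplyr::summarise(acc = mean(.data$acc), .groups = "drop") |>
    dplyr::arrange(.data$n_measures, .data$subset)
  attr(out, "per_subject") <- per_subject
  out
}
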