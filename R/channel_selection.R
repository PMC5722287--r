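#' Single- and pairwise-electrode accuracy matrix
#'
#' For every electrode `i`, the classifier is evaluated on the feature
#' columns of that electrode alone (`Acc(i)`); for every unordered pair
#' `{i, j}`, on the union of the two electrodes' feature columns
#' (`Acc(ij) = Acc(ji)`). The same classifier and cross-validation protocol
#' are used throughout, and accuracies are stored as fractions in `[0, 1]`.
#'
#' Leave-one-out is the protocol of record; a stratified holdout split
#' (`cv = "holdout"`) is offered as a faster estimate for large epoch counts.
#'
#' @param features Feature tibble from [extract_feature_matrix()]; electrode
#'   identity is read from the `<electrode>_<measure>` column names.
#' @param clf A [classifier_spec()].
#' @param cv `"loo"` (default) or `"holdout"`.
#' @param holdout_fraction,seed Holdout split parameters.
#' @param electrodes Optional subset of electrode names to evaluate.
#' @param ... Passed to [loo_cross_validate()].
#' @return An object of class `accuracy_matrix`: named vector `single`,
#'   symmetric matrix `pairwise` (diagonal `NA`), and `electrodes`.
#' @export
compute_accuracy_matrix <- function(features, clf = classifier_spec(),
                                    cv = c("loo", "holdout"),
                                    holdout_fraction = 0.5, seed = 1L,
                                    electrodes = NULL, ...) {
  cv <- match.arg(cv)
  if (length(unique(features$state)) < 2) {
    stop("both states must be present", call. = FALSE)
  }
  fcols <- feature_cols(features)
  all_el <- unique(sub("_[^_]+$", "", fcols))
  if (is.null(electrodes)) electrodes <- all_el
  missing_el <- setdiff(electrodes, all_el)
  if (length(missing_el)) stop("no feature columns for electrode(s): ",
                               paste(missing_el, collapse = ", "),
                               call. = FALSE)
  if (length(electrodes) < 2) stop("need at least 2 electrodes", call. = FALSE)

  el_cols <- lapply(electrodes, function(e) {
    fcols[sub("_[^_]+$", "", fcols) == e]
  })
  names(el_cols) <- electrodes

  acc_of <- function(cols) {
    fm <- features[c(meta_cols(), cols)]
    if (cv == "loo") {
      loo_cross_validate(fm, clf, ...)$metrics$acc / 100
    } else {
      parts <- split_train_test(fm, holdout_fraction, seed = seed)
      spec_n <- fit_normalization(parts$train)
      train <- minmax_normalize(parts$train, spec_n)
      test <- minmax_normalize(parts$test, spec_n)
      out <- fit_predict(clf, train[cols], train$state, test[cols])
      confusion_metrics(out$label, test$state)$acc / 100
    }
  }

  single <- vapply(electrodes, function(e) acc_of(el_cols[[e]]), numeric(1))
  n <- length(electrodes)
  pairwise <- matrix(NA_real_, n, n, dimnames = list(electrodes, electrodes))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- acc_of(c(el_cols[[i]], el_cols[[j]]))
      pairwise[i, j] <- a
      pairwise[j, i] <- a
    }
  }
  accuracy_matrix(single, pairwise, electrodes)
}

#' Construct an accuracy matrix object
#'
#' @param single Named numeric vector of per-electrode accuracies in
#'   `[0, 1]`.
#' @param pairwise Symmetric numeric matrix of pairwise accuracies in
#'   `[0, 1]` (diagonal ignored).
#' @param electrodes Electrode labels in montage order.
#' @return An object of class `accuracy_matrix`.
#' @export
accuracy_matrix <- function(single, pairwise, electrodes = names(single)) {
  single <- as.numeric(single)
  pairwise <- as.matrix(pairwise)
  n <- length(electrodes)
  stopifnot(length(single) == n, all(dim(pairwise) == n))
  off <- pairwise[upper.tri(pairwise) | lower.tri(pairwise)]
  if (any(single < 0 | single > 1) || any(off < 0 | off > 1, na.rm = TRUE)) {
    stop("accuracies must be fractions in [0, 1]", call. = FALSE)
  }
  if (!isTRUE(all.equal(pairwise[upper.tri(pairwise)],
                        t(pairwise)[upper.tri(pairwise)]))) {
    stop("pairwise accuracy matrix must be symmetric", call. = FALSE)
  }
  names(single) <- electrodes
  dimnames(pairwise) <- list(electrodes, electrodes)
  structure(list(single = single, pairwise = pairwise,
                 electrodes = as.character(electrodes)),
            class = "accuracy_matrix")
}

#' @export
print.accuracy_matrix <- function(x, ...) {
  cat(sprintf("<accuracy_matrix> %d electrodes\n", length(x$electrodes)))
  print(round(x$single, 3))
  invisible(x)
}

#' Accuracy-based electrode weights
#'
#' Scores each electrode by its own discriminative accuracy plus its average
#' advantage in pairwise combinations:
#' `V_i = Acc(i) + sum_{j != i} (Acc(ij) + Acc(i) - Acc(j)) / N`,
#' with `N` the electrode count. An electrode that classifies well alone and
#' whose pairings outperform its partners' solo accuracy receives a high
#' weight; the deviation terms `Acc(i) - Acc(j)` cancel pairwise when summed
#' over all electrodes.
#'
#' @param acc An [accuracy_matrix()].
#' @return A tibble of class `electrode_weights` with columns `electrode`
#'   and `weight`, in montage order.
#' @export
electrode_weights <- function(acc) {
  stopifnot(inherits(acc, "accuracy_matrix"))
  n <- length(acc$electrodes)
  v <- vapply(seq_len(n), function(i) {
    j <- setdiff(seq_len(n), i)
    acc$single[i] +
      sum(acc$pairwise[i, j] + acc$single[i] - acc$single[j]) / n
  }, numeric(1))
  out <- tibble::tibble(electrode = acc$electrodes, weight = v)
  class(out) <- c("electrode_weights", class(out))
  out
}

#' Rank electrodes by weight
#'
#' @param weights An [electrode_weights()] tibble (or any tibble with
#'   `electrode` and `weight` columns).
#' @param k Number of electrodes to return, `1 <= k <= N`.
#' @return Character vector of the top `k` electrode labels, weight
#'   descending; ties keep montage (row) order.
#' @export
rank_electrodes <- function(weights, k = nrow(weights)) {
  if (k < 1 || k > nrow(weights)) {
    stop("`k` must lie in 1..", nrow(weights), call. = FALSE)
  }
  ord <- order(-weights$weight, seq_len(nrow(weights)))
  weights$electrode[ord][seq_len(k)]
}

#' Standardise electrode weights for topographic display
#'
#' Rescales the raw weights to `[0, 1]` by min-max normalisation, zeroes
#' every value below `threshold`, subtracts `threshold` from the rest, and
#' rounds to one decimal, producing the small discrete palette used for
#' weight topographies (maximum value `1 - threshold`). If all raw weights
#' are equal they map to the range midpoint before thresholding.
#'
#' @param weights An [electrode_weights()] tibble.
#' @param threshold Cut value on the `[0, 1]` scale (default 0.8).
#' @return The input tibble with an added `standardized` column.
#' @export
standardize_weights <- function(weights, threshold = 0.8) {
  stopifnot(threshold >= 0, threshold <= 1)
  v <- weights$weight
  scaled <- apply_minmax(v, min(v), max(v), 0, 1)
  std <- ifelse(scaled < threshold, 0, scaled - threshold)
  weights$standardized <- round(std, 1)
  weights
}

#' Restrict a feature table to a scalp region
#'
#' @param features Feature tibble.
#' @param region Region label found in `region_map`, or a character vector of
#'   electrode names.
#' @param region_map Named list of electrode groups
#'   (default [default_region_map()]).
#' @return Feature tibble restricted to the region's electrodes.
#' @export
select_region <- function(features, region,
                          region_map = default_region_map()) {
  electrodes <- if (length(region) == 1 && region %in% names(region_map)) {
    region_map[[region]]
  } else {
    region
  }
  fcols <- feature_cols(features)
  keep <- fcols[sub("_[^_]+$", "", fcols) %in% electrodes]
  if (!length(keep)) stop("no feature columns match region electrodes: ",
                          paste(electrodes, collapse = ", "), call. = FALSE)
  features[c(meta_cols(), keep)]
}
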