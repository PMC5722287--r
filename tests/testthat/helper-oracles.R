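# Independent brute-force oracles, deliberately written as plain nested
# loops over template pairs so they share no code path with the package's
# compiled kernels.

cheb <- function(a, b) max(abs(a - b))

apen_oracle <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    n_tpl <- N - mm + 1
    logC <- numeric(n_tpl)
    for (i in seq_len(n_tpl)) {
      cnt <- 0
      for (j in seq_len(n_tpl)) {
        if (cheb(x[i:(i + mm - 1)], x[j:(j + mm - 1)]) <= r) cnt <- cnt + 1
      }
      logC[i] <- log(cnt / n_tpl)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1)
}

sampen_oracle <- function(x, m, r) {
  N <- length(x)
  n_tpl <- N - m
  A <- 0; B <- 0
  for (i in seq_len(n_tpl)) {
    for (j in seq_len(n_tpl)) {
      if (i == j) next
      if (cheb(x[i:(i + m - 1)], x[j:(j + m - 1)]) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0) return(0)
  if (A == 0) return(log(B / 2))
  -log(A / B)
}

fuzzyen_oracle <- function(x, m, r, n_grad) {
  N <- length(x)
  n_tpl <- N - m
  phi <- function(mm) {
    tot <- 0; cnt <- 0
    for (i in seq_len(n_tpl)) {
      for (j in seq_len(n_tpl)) {
        if (i == j) next
        u <- x[i:(i + mm - 1)]; u <- u - mean(u)
        v <- x[j:(j + mm - 1)]; v <- v - mean(v)
        tot <- tot + exp(-(cheb(u, v) / r)^n_grad)
        cnt <- cnt + 1
      }
    }
    tot / cnt
  }
  log(phi(m)) - log(phi(m + 1))
}

# ROC area by exhaustive threshold enumeration (thresholds at each unique
# score plus sentinels), trapezoidal rule.
roc_auc_oracle <- function(scores, labels, positive) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- t(vapply(ths, function(t) {
    pred_pos <- scores >= t
    pos <- labels == positive
    c(fpr = sum(pred_pos & !pos) / sum(!pos),
      tpr = sum(pred_pos & pos) / sum(pos))
  }, c(fpr = 0, tpr = 0)))
  pts <- pts[order(pts[, "fpr"], pts[, "tpr"]), ]
  sum(diff(pts[, "fpr"]) * (head(pts[, "tpr"], -1) + pts[-1, "tpr"]) / 2)
}

# ROC area via the rank-statistic (Mann-Whitney) identity with midranks.
roc_auc_rank <- function(scores, labels, positive) {
  pos <- labels == positive
  r <- rank(scores)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

# Yule-Walker solved directly from biased autocovariances.
yw_oracle <- function(x, p) {
  n <- length(x)
  xc <- x - mean(x)
  g <- vapply(0:p, function(k) {
    sum(xc[1:(n - k)] * xc[(1 + k):n]) / n
  }, numeric(1))
  solve(toeplitz(g[1:p]), g[2:(p + 1)])
}

# Small deterministic synthetic feature table for classifier tests: two
# Gaussian clouds separated by `sep` in every feature.
toy_features <- function(n_per_class = 20, n_feat = 4, sep = 3, seed = 1,
                         subjects = "s1") {
  withr::with_seed(seed, {
    states <- rep(c("normal", "fatigue"), each = n_per_class)
    shift <- ifelse(states == "fatigue", sep, 0)
    X <- matrix(rnorm(2 * n_per_class * n_feat), 2 * n_per_class) + shift
    colnames(X) <- paste0("E", rep(seq_len(n_feat / 2), each = 2), "_",
                          c("SE", "FE"))[seq_len(n_feat)]
    dplyr::bind_cols(
      tibble::tibble(
        subject_id = rep_len(subjects, 2 * n_per_class),
        state = states,
        epoch = seq_len(2 * n_per_class)),
      tibble::as_tibble(X))
  })
}

small_epochs <- function(n_sub = 1, dur = 10, fs = 100, effect = 0.8,
                         seed = 1, channels = c("T6", "P3", "Cz", "F3")) {
  spec <- cohort_spec(n_subjects = n_sub, channel_names = channels,
                      fs = fs, duration_s = dur, effect_size = effect,
                      planted_electrodes = intersect(c("T6", "P3"), channels),
                      seed = seed)
  segment_cohort(generate_cohort(spec))
}
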