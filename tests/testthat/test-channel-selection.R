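uniform_acc <- function(n = 3, val = 0.9) {
  els <- paste0("E", seq_len(n))
  pw <- matrix(val, n, n); diag(pw) <- NA
  accuracy_matrix(stats::setNames(rep(val, n), els), pw, els)
}

test_that("electrode weights reproduce the accuracy-weight formula", {
  # uniform 0.9 accuracies, N = 3: V = 0.9 + 2 * 0.9 / 3 = 1.5 everywhere
  w <- electrode_weights(uniform_acc())
  expect_equal(w$weight, rep(1.5, 3))

  # toy matrix against a direct summation oracle
  els <- c("A", "B", "C")
  single <- c(A = 0.9, B = 0.8, C = 0.7)
  pw <- matrix(NA, 3, 3, dimnames = list(els, els))
  pw["A", "B"] <- pw["B", "A"] <- 0.92
  pw["A", "C"] <- pw["C", "A"] <- 0.91
  pw["B", "C"] <- pw["C", "B"] <- 0.85
  w2 <- electrode_weights(accuracy_matrix(single, pw, els))
  oracle <- vapply(els, function(i) {
    js <- setdiff(els, i)
    single[i] + sum(vapply(js, function(j) {
      pw[i, j] + single[i] - single[j]
    }, numeric(1))) / 3
  }, numeric(1))
  expect_equal(w2$weight, as.numeric(oracle))

  # raising Acc(i) raises V_i and lowers every other V_j
  single_up <- single; single_up["B"] <- 0.88
  w3 <- electrode_weights(accuracy_matrix(single_up, pw, els))
  expect_gt(w3$weight[2], w2$weight[2])
  expect_lt(w3$weight[1], w2$weight[1])
  expect_lt(w3$weight[3], w2$weight[3])

  # deviation terms cancel when summed over all electrodes
  n <- 3
  expect_equal(sum(w2$weight), sum(single) + sum(pw[upper.tri(pw)] * 2) / n,
               tolerance = 1e-12)
})

test_that("accuracy matrix validation enforces symmetry and range", {
  els <- c("A", "B")
  pw <- matrix(c(NA, 0.6, 0.7, NA), 2, 2)
  expect_error(accuracy_matrix(c(A = 0.5, B = 0.5), pw, els), "symmetric")
  pw2 <- matrix(c(NA, 1.4, 1.4, NA), 2, 2)
  expect_error(accuracy_matrix(c(A = 0.5, B = 0.5), pw2, els), "fractions")
})

test_that("electrode ranking is a stable descending permutation", {
  w <- tibble::tibble(electrode = c("E1", "E2", "E3"),
                      weight = c(0.5, 0.9, 0.7))
  class(w) <- c("electrode_weights", class(w))
  expect_identical(rank_electrodes(w, 2), c("E2", "E3"))
  expect_identical(sort(rank_electrodes(w, 3)), sort(w$electrode))
  expect_error(rank_electrodes(w, 0), "k")
  expect_error(rank_electrodes(w, 4), "k")

  ties <- tibble::tibble(electrode = c("Fz", "Cz", "Pz"),
                         weight = c(0.8, 0.9, 0.8))
  expect_identical(rank_electrodes(ties, 3), c("Cz", "Fz", "Pz"))
})

test_that("weight standardisation rescales, thresholds and rounds to one decimal", {
  w <- tibble::tibble(electrode = paste0("E", 1:5),
                      weight = c(1.0, 1.4, 1.87, 1.95, 2.0))
  out <- standardize_weights(w, threshold = 0.8)
  scaled <- (w$weight - 1) / 1
  expect_equal(out$standardized,
               round(ifelse(scaled < 0.8, 0, scaled - 0.8), 1))
  expect_equal(max(out$standardized), 0.2)   # 1 - 0.8 at the top electrode
  expect_equal(out$standardized[3], 0.1)     # 0.87 - 0.8 = 0.07 -> 0.1
  expect_true(all(out$standardized >= 0 & out$standardized <= 0.2))

  low <- standardize_weights(
    tibble::tibble(electrode = c("a", "b"), weight = c(0, 1)), threshold = 1)
  expect_equal(low$standardized, c(0, 0))
})

test_that("accuracy matrix computation separates informative electrodes", {
  # separable toy problem: both electrodes carry full class separation
  fm <- toy_features(n_per_class = 12, n_feat = 4, sep = 4)
  am <- compute_accuracy_matrix(fm, classifier_spec("nearest_neighbor"))
  expect_identical(am$electrodes, c("E1", "E2"))
  expect_equal(as.numeric(am$single), c(1, 1))
  expect_equal(am$pairwise["E1", "E2"], 1)
  expect_equal(am$pairwise["E1", "E2"], am$pairwise["E2", "E1"])

  expect_error(compute_accuracy_matrix(fm, electrodes = c("E1", "ZZ")),
               "no feature columns")
  one_class <- fm[fm$state == "normal", ]
  expect_error(compute_accuracy_matrix(one_class), "both states")
})

test_that("permuted labels give chance-level accuracy entries", {
  withr::with_seed(41, {
    entries <- unlist(lapply(1:4, function(s) {
      fm <- toy_features(n_per_class = 50, n_feat = 6, sep = 0, seed = s)
      fm$state <- sample(fm$state)
      am <- compute_accuracy_matrix(fm, classifier_spec("nearest_neighbor"),
                                    cv = "holdout", seed = s)
      c(am$single, am$pairwise[upper.tri(am$pairwise)])
    }))
  })
  expect_gt(mean(entries), 0.35)
  expect_lt(mean(entries), 0.65)
})

test_that("region restriction keeps only the region's feature columns", {
  ep <- small_epochs(dur = 4, channels = c("TP7", "T5", "P3", "CP3", "T4"))
  fm <- extract_feature_matrix(ep)
  regA <- select_region(fm, "A")
  expect_identical(sort(unique(sub("_[^_]+$", "", feature_cols(regA)))),
                   sort(default_region_map()$A))
  regC <- select_region(fm, "C")
  expect_identical(feature_cols(regC), paste0("T4_", c("PE", "AE", "SE", "FE")))
  expect_error(select_region(fm, c("O9", "O10")), "no feature columns")
})
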