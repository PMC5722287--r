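test_that("template entropies vanish on constant series", {
  x <- rep(3.7, 60)
  expect_identical(approximate_entropy(x), 0)
  expect_identical(sample_entropy(x), 0)
  expect_identical(fuzzy_entropy(x), 0)
  # constant series with an absolute tolerance: all templates match
  expect_equal(approximate_entropy(x, r = 0.5), 0)
  expect_equal(sample_entropy(x, r = 0.5), 0)
})

test_that("template entropies match brute-force enumeration on short series", {
  p <- entropy_params(m = 2, r_factor = 0.2, n_grad = 2)
  withr::with_seed(42, {
    for (rep in 1:40) {
      n <- sample(15:50, 1)
      x <- rnorm(n)
      r <- 0.2 * sd(x)
      expect_equal(approximate_entropy(x, p), apen_oracle(x, 2, r),
                   tolerance = 1e-10)
      expect_equal(sample_entropy(x, p), sampen_oracle(x, 2, r),
                   tolerance = 1e-10)
      expect_equal(fuzzy_entropy(x, p), fuzzyen_oracle(x, 2, r, 2),
                   tolerance = 1e-10)
    }
  })
  # the spec example series: periodic ramp with an absolute tolerance
  x <- rep(c(1, 2, 3), 10)
  expect_equal(approximate_entropy(x, r = 0.5), apen_oracle(x, 2, 0.5),
               tolerance = 1e-10)
})

test_that("entropies order noise above periodic signals", {
  withr::with_seed(11, {
    diffs <- replicate(25, {
      noise <- rnorm(300)
      tone <- sin(2 * pi * 7 * seq_len(300) / 300) * sd(noise) / 0.707
      c(ae = approximate_entropy(noise) - approximate_entropy(tone),
        fe = fuzzy_entropy(noise) - fuzzy_entropy(tone))
    })
  })
  expect_gt(mean(diffs["ae", ] > 0), 0.95)
  expect_gt(mean(diffs["fe", ] > 0), 0.95)
})

test_that("sample entropy grows with noise amplitude on a tone", {
  withr::with_seed(5, {
    base <- sin(2 * pi * 5 * seq_len(400) / 400)
    mean_se <- vapply(c(0.1, 0.5, 1.5), function(amp) {
      mean(replicate(20, sample_entropy(base + amp * rnorm(400), r = 0.25)))
    }, numeric(1))
  })
  expect_true(all(diff(mean_se) > 0))
})

test_that("template entropies are offset-invariant and scale-invariant with relative r", {
  withr::with_seed(3, x <- rnorm(120))
  for (f in list(approximate_entropy, sample_entropy, fuzzy_entropy)) {
    expect_equal(f(x + 100), f(x), tolerance = 1e-9)
    expect_equal(f(x * 37), f(x), tolerance = 1e-9)
  }
})

test_that("spectral entropy is bounded, amplitude-invariant, and matches constructed spectra", {
  fs <- 1000
  t <- (0:999) / fs
  # single line -> nearly zero
  tone <- sin(2 * pi * 10 * t)
  expect_lt(spectral_entropy(tone, fs), 0.3)
  # two equal-power lines at exact DFT bins -> log(2) / log(n_bins);
  # the 0.15-45 Hz band of a 1 s epoch at 1000 Hz holds bins 1..45 Hz
  two <- sin(2 * pi * 10 * t) + sin(2 * pi * 30 * t)
  expect_equal(spectral_entropy(two, fs), log(2) / log(45), tolerance = 1e-8)
  # white noise -> high
  withr::with_seed(21, {
    se_noise <- replicate(30, spectral_entropy(rnorm(1000), fs))
  })
  expect_gt(mean(se_noise), 0.85)
  expect_true(all(se_noise >= 0 & se_noise <= 1))
  # amplitude scaling is a no-op; constant input maps to 0
  withr::with_seed(2, x <- rnorm(500))
  expect_equal(spectral_entropy(x, fs), spectral_entropy(1e4 * x, fs),
               tolerance = 1e-9)
  expect_identical(spectral_entropy(rep(2, 100), fs), 0)
  expect_error(spectral_entropy(c(1, NA, 3), fs), "non-finite")
})

test_that("Yule-Walker coefficients match the direct Toeplitz solve and recover AR(2)", {
  withr::with_seed(8, x <- as.numeric(stats::arima.sim(list(ar = 0.6), 400)))
  expect_equal(ar_coefficients(x, 3), as.numeric(yw_oracle(x, 3)),
               tolerance = 1e-8)

  withr::with_seed(9, {
    y <- as.numeric(stats::arima.sim(list(ar = c(0.5, -0.3)), 5000))
    w <- rnorm(5000)
  })
  expect_equal(ar_coefficients(y, 2), c(0.5, -0.3), tolerance = 0.05)
  expect_equal(ar_coefficients(w, 2), c(0, 0), tolerance = 0.05)
  expect_warning(z <- ar_coefficients(rep(1, 100), 4), "constant")
  expect_identical(z, numeric(4))
})
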