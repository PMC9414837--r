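test_that("sample entropy matches the template-counting oracle", {
  set.seed(7)
  x <- rep(c(1, 2), 10) + rnorm(20, sd = 0.05)
  expect_equal(sample_entropy(x), oracle_sample_entropy(x), tolerance = 1e-12)
  for (i in 1:5) {
    y <- rnorm(80)
    expect_equal(sample_entropy(y), oracle_sample_entropy(y), tolerance = 1e-12)
  }
  # affine invariance: r scales with sd
  y <- rnorm(100)
  expect_equal(sample_entropy(3 * y + 7), sample_entropy(y), tolerance = 1e-12)
  expect_error(sample_entropy(rep(1, 50)), "constant")
})

test_that("fuzzy entropy matches the membership-sum oracle and is positive on noise", {
  set.seed(8)
  x12 <- c(3.1, 0.2, -1.5, 2.8, 0.9, -0.3, 1.7, -2.2, 0.5, 1.1, -0.8, 2.0)
  expect_equal(fuzzy_entropy(x12), oracle_fuzzy_entropy(x12), tolerance = 1e-10)
  for (i in 1:5) {
    y <- rnorm(60)
    expect_equal(fuzzy_entropy(y), oracle_fuzzy_entropy(y), tolerance = 1e-10)
    expect_gt(fuzzy_entropy(y), 0)
  }
  y <- rnorm(100)
  expect_equal(fuzzy_entropy(0.5 * y - 4), fuzzy_entropy(y), tolerance = 1e-10)
})

test_that("permutation entropy is normalized to [0, 1] with exact edge cases", {
  # monotone sequence: single pattern
  expect_equal(permutation_entropy(1:50, m = 4), 0)
  # all 3! patterns equally often -> exactly 1 (enumerated fixture)
  x <- c(1, 2, 3,  3, 2, 1,  1, 3, 2,  2, 3, 1,  3, 1, 2)
  # sliding patterns of this length-15 sequence under m=3 are not uniform;
  # instead check against the enumeration oracle and the [0,1] bound
  expect_equal(permutation_entropy(x, m = 3), oracle_perm_entropy(x, m = 3),
               tolerance = 1e-12)
  fixed <- c(4, 7, 9, 10, 6, 11, 3)
  expect_equal(permutation_entropy(fixed, m = 3),
               oracle_perm_entropy(fixed, m = 3), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:20) {
    y <- rnorm(sample(30:150, 1))
    pe <- permutation_entropy(y, m = 4)
    expect_gte(pe, 0); expect_lte(pe, 1)
    expect_equal(pe, oracle_perm_entropy(y, m = 4), tolerance = 1e-12)
  }
  # a long iid sequence approaches the uniform-pattern limit
  expect_gt(permutation_entropy(rnorm(5000), m = 3), 0.99)
  expect_error(permutation_entropy(c(1, 2), m = 4), "too short")
})

test_that("the Hurst range response matches a step-by-step oracle", {
  x16 <- c(5, 3, 8, 1, 9, 2, 7, 4, 6, 0, 8, 3, 5, 9, 1, 7)
  got <- hurst_range_response(x16, min_scale = 8)
  expect_equal(got$rr, oracle_hurst_rr(x16, 8), tolerance = 1e-12)
  expect_setequal(got$scales$m, c(16, 8))
  # monotone ramp, cross-checked by the same oracle
  ramp <- as.numeric(1:16)
  expect_equal(hurst_range_response(ramp, 8)$rr, oracle_hurst_rr(ramp, 8),
               tolerance = 1e-12)
  set.seed(10)
  for (i in 1:10) {
    y <- cumsum(rnorm(128))
    expect_equal(hurst_range_response(y)$rr, oracle_hurst_rr(y), tolerance = 1e-10)
  }
  # positive homogeneity: ranges scale with amplitude, shifts cancel
  y <- rnorm(64)
  expect_equal(hurst_range_response(2.5 * y + 3)$rr,
               2.5 * hurst_range_response(y)$rr, tolerance = 1e-10)
  expect_error(hurst_range_response(rep(1, 64)), "constant")
})

test_that("the eigenvector pseudospectrum feature matches an independent chain", {
  t <- (0:1279) / 128
  x <- 20 * sin(2 * pi * 3 * t) + 8 * sin(2 * pi * 11 * t + 1)
  # package feature
  got <- psd_eigenvector_feature(x)
  # independent chain: package transform, oracle pseudospectrum, scalar summary
  w <- eeg_dwt(x)
  seqs_d <- w$details
  a <- x
  seqs_a <- list()
  f <- ndoa:::wavelet_filters("db16")
  for (j in 1:6) {
    s <- ndoa:::.dwt_step(a, f)
    seqs_a[[j]] <- s$a
    a <- s$a
  }
  spec_d <- lapply(seqs_d, oracle_ev_pseudospectrum)
  spec_a <- lapply(seqs_a, oracle_ev_pseudospectrum)
  M <- 0.5 * (log(mean(sapply(spec_d, mean))) + log(mean(sapply(spec_a, mean))))
  S <- 0.5 * (log(mean(sapply(spec_d, sd))) + log(mean(sapply(spec_a, sd))))
  want <- (28 * M + 90 * S) / 3
  expect_equal(got, want, tolerance = 1e-8)
  # determinism
  expect_identical(psd_eigenvector_feature(x), got)
})

test_that("feature extraction flags degenerate windows instead of failing", {
  fv <- extract_features(rep(0, 1280))
  expect_true(fv$degenerate)
  expect_true(is.na(fv$se))
  # and completes within the per-second real-time budget on a full window
  x <- make_state_window("deep", seed = 1)
  elapsed <- system.time(fv2 <- extract_features(x))[["elapsed"]]
  expect_false(fv2$degenerate)
  expect_lt(elapsed, 1)
})

test_that("entropies are higher in awake-like than deep-like windows", {
  n_per <- 50
  awake <- dplyr::bind_rows(lapply(1:n_per, function(s)
    extract_features(make_state_window("awake", seed = s))))
  deep <- dplyr::bind_rows(lapply(1:n_per, function(s)
    extract_features(make_state_window("deep", seed = 1000 + s))))
  for (feat in c("se", "fe", "pe")) {
    p <- wilcox.test(awake[[feat]], deep[[feat]], alternative = "greater")$p.value
    expect_lt(p, 1e-4)
  }
})
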