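# Synthetic feature table with a known smooth index surface.
make_gp_synth <- function(n, seed, noise_sd = 5) {
  set.seed(seed)
  X <- matrix(runif(n * 5, -1, 1), ncol = 5,
              dimnames = list(NULL, c("se", "fe", "pe", "hurst_rr", "psd_fea")))
  g <- 55 + 20 * sin(pi * X[, 1]) + 12 * X[, 2] - 8 * X[, 3]^2 +
    6 * X[, 4] * X[, 5]
  d <- tibble::as_tibble(as.data.frame(X))
  d$bis <- pmin(100, pmax(0, g + rnorm(n, sd = noise_sd)))
  d$subject_id <- "SYN"
  d
}

test_that("fit metrics follow their defining arithmetic", {
  m <- compute_metrics(c(0, 100), c(10, 90))
  expect_equal(m$mse, 100)
  expect_equal(m$mae, 10)
  expect_equal(m$r2, 1 - 200 / 5000)
  y <- rnorm(50, 50, 10)
  perfect <- compute_metrics(y, y)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$mse, 0)
  # the mean predictor scores exactly zero
  expect_equal(compute_metrics(y, rep(mean(y), 50))$r2, 0)
  expect_error(compute_metrics(rep(1, 10), rnorm(10)), "zero-variance")
  # identities: rmse^2 = mse, mae <= rmse
  set.seed(12)
  for (i in 1:20) {
    f <- y + rnorm(50, sd = runif(1, 0.1, 20))
    mm <- compute_metrics(y, f)
    expect_equal(mm$rmse^2, mm$mse, tolerance = 1e-12)
    expect_lte(mm$mae, mm$rmse + 1e-12)
  }
})

test_that("every model kind regresses a constant target to the constant", {
  d <- make_gp_synth(60, seed = 1)
  d$bis <- 50
  for (kind in c("sq_exp_gp", "linear_robust", "tree", "svm_rbf")) {
    m <- ndoa_fit(d, kind, seed = 1)
    expect_equal(unname(predict(m, d)), rep(50, 60), tolerance = 1e-6,
                 label = kind)
  }
})

test_that("the GP interpolates noise-free targets and is seeded-deterministic", {
  d <- make_gp_synth(200, seed = 2, noise_sd = 0)
  m1 <- ndoa_fit(d, "sq_exp_gp", seed = 3)
  m2 <- ndoa_fit(d, "sq_exp_gp", seed = 3)
  expect_identical(tidy(m1), tidy(m2))
  expect_gte(compute_metrics(d$bis, predict(m1, d))$r2, 0.99)
})

test_that("GP prediction agrees with the closed-form posterior on tiny sets", {
  # 3 points, direct kernel-matrix solve with the fitted hyperparameters
  d <- make_gp_synth(25, seed = 4, noise_sd = 0.01)
  m <- ndoa_fit(d, "sq_exp_gp", seed = 1)
  Z <- scale(as.matrix(d[, 1:5]), center = m$center, scale = m$scale)
  gp <- m$fit
  K <- matrix(0, nrow(gp$X), nrow(gp$X))
  for (i in seq_len(nrow(gp$X))) for (j in seq_len(nrow(gp$X))) {
    K[i, j] <- gp$sf2 * exp(-0.5 * sum((gp$X[i, ] - gp$X[j, ])^2) / gp$ell^2)
  }
  ks <- sapply(seq_len(nrow(gp$X)), function(j)
    gp$sf2 * exp(-0.5 * sum((Z[1, ] - gp$X[j, ])^2) / gp$ell^2))
  want <- gp$ybar + drop(ks %*% solve(K + diag(gp$sn2 + 1e-8, nrow(K)),
                                      d$bis[seq_len(nrow(gp$X))] - gp$ybar))
  expect_equal(unname(predict(m, d[1, ])), unname(min(100, max(0, want))),
               tolerance = 1e-6)
})

test_that("the GP posterior interpolates as the noise variance vanishes", {
  # <= 10 points; hyperparameters fixed, noise forced towards zero, posterior
  # solved directly from the kernel matrix
  d <- make_gp_synth(10, seed = 20, noise_sd = 0)
  m <- ndoa_fit(rbind(d, d[1:10, ]), "sq_exp_gp", seed = 1)  # >=20-row contract
  gp <- m$fit
  Z <- scale(as.matrix(d[, 1:5]), center = m$center, scale = m$scale)
  K <- ndoa:::.sqexp_kernel(Z, Z, gp$ell, gp$sf2)
  alpha <- solve(K + diag(1e-10, 10), d$bis - mean(d$bis))
  interp <- drop(K %*% alpha) + mean(d$bis)
  expect_equal(interp, d$bis, tolerance = 1e-4)
})

test_that("predictions are clamped, vectorized, and robust to bad rows", {
  d <- make_gp_synth(60, seed = 5)
  m <- ndoa_fit(d, "linear_robust", seed = 1)
  expect_identical(predict(m, d[0, ]), numeric(0))
  extreme <- d[1:2, ]
  extreme$se <- c(1e4, -1e4)  # force raw predictions far outside [0, 100]
  p <- predict(m, extreme)
  expect_true(all(p >= 0 & p <= 100))
  bad <- d[1:3, ]
  bad$fe[2] <- NA
  p2 <- predict(m, bad)
  expect_true(is.na(p2[2]) && !anyNA(p2[-2]))
  # degenerate feature column is refused with its name
  dz <- d; dz$pe <- 1
  expect_error(ndoa_fit(dz, "sq_exp_gp"), "pe")
})

test_that("GP recovery approaches the noise floor as n grows", {
  test <- make_gp_synth(200, seed = 99, noise_sd = 5)
  rmse_at <- sapply(c(100, 400), function(n) {
    m <- ndoa_fit(make_gp_synth(n, seed = n, noise_sd = 5), "sq_exp_gp", seed = 1)
    compute_metrics(test$bis, predict(m, test))$rmse
  })
  expect_lt(rmse_at[2], rmse_at[1] + 0.5)  # no degradation with more data
  expect_lt(rmse_at[2], 8)                  # close to the sd-5 noise floor
})

test_that("cross-validation is seeded and near-perfect on clean data", {
  # an easy noiseless smooth surface that the GP can learn essentially
  # perfectly from 200 rows
  set.seed(6)
  X <- matrix(runif(200 * 5, -1, 1), ncol = 5,
              dimnames = list(NULL, c("se", "fe", "pe", "hurst_rr", "psd_fea")))
  d <- tibble::as_tibble(as.data.frame(X))
  d$bis <- 50 + 15 * X[, 1] + 8 * X[, 2] - 5 * X[, 3]
  d$subject_id <- "SYN"
  cv1 <- ndoa_crossvalidate(d, "sq_exp_gp", folds = 5, seed = 11)
  cv2 <- ndoa_crossvalidate(d, "sq_exp_gp", folds = 5, seed = 11)
  expect_identical(cv1, cv2)
  expect_gte(cv1$r2, 0.98)
  expect_lt(cv1$rmse, 2)
})

test_that("the GP cross-validates better than the robust linear baseline", {
  fx <- ndoa_benchmark()
  pool <- dplyr::bind_rows(fx$train_tbls[fx$bm$manifest$role == "train"])
  for (seed in 1:5) {
    cv_gp <- ndoa_crossvalidate(pool, "sq_exp_gp", folds = 5, seed = seed)
    cv_lin <- ndoa_crossvalidate(pool, "linear_robust", folds = 5, seed = seed)
    expect_gt(cv_gp$r2, cv_lin$r2)
  }
})

test_that("model serialization round-trips predictions exactly", {
  d <- make_gp_synth(80, seed = 7)
  m <- ndoa_fit(d, "sq_exp_gp", seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  ndoa_save_model(m, path)
  m2 <- ndoa_load_model(path)
  expect_equal(predict(m2, d), predict(m, d), tolerance = 1e-9)
})

test_that("the in-package GP agrees with an independent GP library", {
  skip_if_not_installed("kernlab")
  d <- make_gp_synth(150, seed = 8, noise_sd = 2)
  m <- ndoa_fit(d, "sq_exp_gp", seed = 1)
  Z <- scale(as.matrix(d[, 1:5]), center = m$center, scale = m$scale)
  # same kernel family and the fitted hyperparameters; kernlab solves the
  # identical posterior mean system
  kl <- kernlab::gausspr(Z, d$bis, kernel = "rbfdot",
                         kpar = list(sigma = 1 / (2 * m$fit$ell^2)),
                         var = max(m$fit$sn2, 1e-3) / m$fit$sf2, scaled = FALSE,
                         variance.model = FALSE)
  p_kl <- as.numeric(kernlab::predict(kl, Z))
  expect_gt(pearson_r(predict(m, d), p_kl), 0.999)
})
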